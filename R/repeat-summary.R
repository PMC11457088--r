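# Multi-run repeat-library consensus, lineage-specific family detection,
# and repeat-content accounting with per-base multiclass resolution.

# per-scaffold disjoint accounting; returns c(per-class bp, Multiclass, Total)
.classifyScaffold <- function(ann) {
  out <- setNames(numeric(length(.REPEAT_CLASSES) + 2),
                  c(.REPEAT_CLASSES, "Multiclass", "Total"))
  if (!nrow(ann)) return(out)
  perClass <- lapply(split(ann, ann$rclass), function(d)
    IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end)))
  dj <- IRanges::disjoin(unlist(IRanges::IRangesList(perClass)))
  hit <- vapply(perClass, function(ir) IRanges::overlapsAny(dj, ir),
                logical(length(dj)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = length(dj))
  nCls <- rowSums(hit)
  w <- BiocGenerics::width(dj)
  for (ci in seq_along(perClass)) {
    cls <- names(perClass)[ci]
    out[cls] <- sum(w[hit[, ci] & nCls == 1])
  }
  out["Multiclass"] <- sum(w[nCls >= 2])
  out["Total"] <- sum(w)
  out
}

#' Repeat-content accounting with multiclass overlap resolution
#'
#' Assigns every genomic base covered by repeat annotations to exactly one
#' accounting row: bases annotated with a single distinct repeat class
#' count toward that class (overlapping annotations of the same class are
#' merged first); bases annotated with two or more distinct classes count
#' only toward `Multiclass`. `Total` is the size of the union of all
#' repeat intervals, so the class rows plus `Multiclass` always sum to
#' `Total`.
#'
#' @param annotations Repeat annotation data.frame (internal half-open
#'   0-based coordinates, `rclass` in the accounting vocabulary).
#' @param genomeLens Named vector of scaffold lengths in bp.
#' @return A [RepeatSummary-class]; percentages are of the summed genome
#'   length.
#' @export
classifyBases <- function(annotations, genomeLens) {
  stopifnot(!is.null(names(genomeLens)))
  if (nrow(annotations)) {
    unknown <- setdiff(unique(annotations$seqid), names(genomeLens))
    if (length(unknown))
      stop("repeat annotation on unknown scaffold(s): ",
           paste(unknown, collapse = ", "))
    over <- annotations$end > genomeLens[annotations$seqid]
    if (any(over))
      stop("repeat annotation beyond scaffold bounds on ",
           annotations$seqid[which(over)[1]])
    bad <- setdiff(unique(annotations$rclass), .REPEAT_CLASSES)
    if (length(bad))
      stop("repeat class(es) outside the accounting vocabulary: ",
           paste(bad, collapse = ", "))
  }
  acc <- setNames(numeric(length(.REPEAT_CLASSES) + 2),
                  c(.REPEAT_CLASSES, "Multiclass", "Total"))
  for (sc in unique(annotations$seqid))
    acc <- acc + .classifyScaffold(
      annotations[annotations$seqid == sc, , drop = FALSE])
  genomeBp <- sum(as.numeric(genomeLens))
  tab <- data.frame(rclass = names(acc), masked_bp = as.numeric(acc),
                    pct = 100 * as.numeric(acc) / genomeBp,
                    stringsAsFactors = FALSE)
  new("RepeatSummary", table = tab, genomeBp = genomeBp)
}

#' Per-scaffold repeat-content profiles
#'
#' [classifyBases()] applied scaffold by scaffold; one row per scaffold
#' (length-descending) with the percentage of the scaffold in each class
#' plus `Multiclass` and `Total`.
#'
#' @param annotations Repeat annotation data.frame.
#' @param assembly Named `DNAStringSet`.
#' @return data.frame with columns `seqid`, `seq_len`, one column per
#'   class, `Multiclass` and `Total` (percentages of the scaffold).
#' @export
perScaffoldProfiles <- function(annotations, assembly) {
  lens <- setNames(Biostrings::width(assembly), names(assembly))
  rows <- lapply(names(lens), function(sc) {
    acc <- .classifyScaffold(
      annotations[annotations$seqid == sc, , drop = FALSE])
    as.data.frame(c(list(seqid = sc, seq_len = unname(lens[sc])),
                    as.list(100 * acc / lens[sc])),
                  stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$seq_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# sequence-level family match: identity >= identityMin over an alignment
# spanning >= coverageMin of the shorter consensus
.familiesMatch <- function(a, b, identityMin = 0.8, coverageMin = 0.8) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -3)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "local",
                                       substitutionMatrix = submat,
                                       gapOpening = 5, gapExtension = 2)
  alnLen <- nchar(aln)
  if (alnLen == 0) return(FALSE)
  identity <- Biostrings::nmatch(aln) / alnLen
  coverage <- alnLen / min(nchar(a), nchar(b))
  identity >= identityMin && coverage >= coverageMin
}

#' Consensus repeat families across independent discovery runs
#'
#' De novo repeat discovery is stochastic; families found by several
#' independent runs are clustered into consensus families by reciprocal
#' sequence match (default: >= 80% identity over >= 80% of the shorter
#' consensus). The cluster class is the majority class across member
#' entries (ties become `Unknown`) and `run_support` counts the distinct
#' runs represented.
#'
#' @param runLibraries Named list (names are run ids) of data.frames with
#'   columns `family`, `rclass`, `consensus`.
#' @param identityMin,coverageMin Match-rule thresholds.
#' @return data.frame with one row per consensus family: `family`
#'   (representative name), `rclass`, `run_support`, `n_members`,
#'   `members` (comma-joined `run:family`), `low_support`.
#' @export
consensusFamilies <- function(runLibraries, identityMin = 0.8,
                              coverageMin = 0.8) {
  if (!length(runLibraries)) stop("at least one run library is required")
  if (is.null(names(runLibraries)))
    names(runLibraries) <- paste0("run", seq_along(runLibraries))
  all <- do.call(rbind, lapply(names(runLibraries), function(r) {
    d <- runLibraries[[r]]
    data.frame(run_id = r, family = d$family, rclass = d$rclass,
               consensus = d$consensus, stringsAsFactors = FALSE)
  }))
  n <- nrow(all)
  uf <- .unionFind(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (all$run_id[i] == all$run_id[j]) next
        if (.familiesMatch(all$consensus[i], all$consensus[j],
                           identityMin, coverageMin))
          uf$union(i, j)
      }
    }
  }
  comp <- uf$components()
  rows <- lapply(split(seq_len(n), comp), function(idx) {
    cls <- table(all$rclass[idx])
    top <- names(cls)[cls == max(cls)]
    rclass <- if (length(top) == 1) top else "Unknown"
    fam <- table(all$family[idx])
    famTop <- sort(names(fam)[fam == max(fam)])[1]
    support <- length(unique(all$run_id[idx]))
    data.frame(family = famTop, rclass = rclass,
               run_support = support, n_members = length(idx),
               members = paste(sort(paste0(all$run_id[idx], ":",
                                           all$family[idx])),
                               collapse = ","),
               low_support = support == 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$run_support, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag lineage-specific repeat families
#'
#' A focal family is lineage-specific when it has zero sequence matches
#' (same match rule as [consensusFamilies()]) in every comparator library.
#' Families supported by a single discovery run carry a low-support caveat:
#' their lineage specificity rests on one observation.
#'
#' @param focal data.frame of focal families (`family`, `rclass`,
#'   `consensus`, optionally `run_support`).
#' @param comparators Named list (species -> data.frame with `consensus`)
#'   of comparator libraries; an empty list flags everything specific, with
#'   a warning.
#' @param identityMin,coverageMin Match-rule thresholds.
#' @return `focal` with added columns `lineage_specific`, `matched_in`
#'   (comma-joined comparator names) and `evidence_caveat`.
#' @export
lineageSpecific <- function(focal, comparators, identityMin = 0.8,
                            coverageMin = 0.8) {
  if (!length(comparators))
    warning("no comparator libraries supplied; ",
            "every family is flagged lineage-specific")
  matched <- lapply(seq_len(nrow(focal)), function(i) {
    hit <- vapply(names(comparators), function(sp) {
      any(vapply(comparators[[sp]]$consensus, function(cs)
        .familiesMatch(focal$consensus[i], cs, identityMin, coverageMin),
        logical(1)))
    }, logical(1))
    names(hit)[hit]
  })
  focal$lineage_specific <- lengths(matched) == 0
  focal$matched_in <- vapply(matched, paste, character(1), collapse = ",")
  support <- if ("run_support" %in% names(focal)) focal$run_support
             else NA_integer_
  focal$evidence_caveat <- ifelse(
    focal$lineage_specific & !is.na(support) & support == 1,
    "single run support; further evidence required", "")
  focal
}
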