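# Duplicate-scaffold procedure: profile benchmark-gene duplication per
# scaffold, pick candidates, verify full duplication by merged alignment
# coverage against partner scaffolds, and split assembly + annotation.

#' Profile benchmark-gene duplication per scaffold
#'
#' Tallies benchmark-gene placements per scaffold and links scaffolds that
#' share a Duplicated benchmark gene ("partners"). Every assembly scaffold
#' gets a profile, including zero-benchmark scaffolds. The output is sorted
#' by the percentage of duplicated benchmark genes (descending), ties by
#' scaffold length ascending.
#'
#' @param busco Benchmark full table as returned by [readBuscoTable()].
#' @param assembly Named `DNAStringSet`.
#' @param includeFragmented Count Fragmented placements in the denominator
#'   (default TRUE); set FALSE to restrict to Complete + Duplicated.
#' @return data.frame with columns `seqid`, `seq_len`, `n_busco`, `n_dup`,
#'   `pct_dup` and a list column `partners`.
#' @export
profileScaffolds <- function(busco, assembly, includeFragmented = TRUE) {
  ids <- names(assembly)
  placed <- busco[busco$status != "Missing" & nzchar(busco$seqid), ,
                  drop = FALSE]
  unknown <- setdiff(unique(placed$seqid), ids)
  if (length(unknown))
    stop("benchmark gene placed on unknown scaffold(s): ",
         paste(unknown, collapse = ", "))
  counted <- placed
  if (!includeFragmented)
    counted <- counted[counted$status %in% c("Complete", "Duplicated"), ,
                       drop = FALSE]
  nBusco <- table(factor(counted$seqid, levels = ids))
  dup <- placed[placed$status == "Duplicated", , drop = FALSE]
  nDup <- table(factor(dup$seqid, levels = ids))
  # partners: scaffolds carrying the alternate copies of this scaffold's
  # duplicated benchmark genes
  partners <- setNames(vector("list", length(ids)), ids)
  if (nrow(dup)) {
    byGene <- split(dup$seqid, dup$busco_id)
    for (sc in unique(dup$seqid)) {
      genes <- dup$busco_id[dup$seqid == sc]
      p <- setdiff(unique(unlist(byGene[genes])), sc)
      partners[[sc]] <- p
    }
  }
  prof <- data.frame(seqid = ids,
                     seq_len = Biostrings::width(assembly),
                     n_busco = as.integer(nBusco[ids]),
                     n_dup = as.integer(nDup[ids]),
                     stringsAsFactors = FALSE)
  prof$pct_dup <- ifelse(prof$n_busco > 0,
                         100 * prof$n_dup / prof$n_busco, 0)
  prof$partners <- unname(partners[ids])
  prof <- prof[order(-prof$pct_dup, prof$seq_len), , drop = FALSE]
  rownames(prof) <- NULL
  prof
}

#' Select duplicate-scaffold candidates
#'
#' Exactly the profiles with at least one duplicated benchmark gene, order
#' preserved.
#'
#' @param profiles Output of [profileScaffolds()].
#' @return Subset of `profiles`.
#' @export
selectCandidates <- function(profiles) {
  profiles[profiles$n_dup >= 1, , drop = FALSE]
}

# total order used for keeper designation within a covered pair:
# longer scaffold wins, ties by more Complete benchmark placements,
# then lexicographically smaller id
.keeperRank <- function(seqids, profiles, busco) {
  len <- profiles$seq_len[match(seqids, profiles$seqid)]
  comp <- busco[busco$status == "Complete", , drop = FALSE]
  nComplete <- as.integer(table(factor(comp$seqid, levels = seqids)))
  order(order(-len, -nComplete, seqids))  # rank: 1 = strongest keeper
}

#' Decide whether one candidate scaffold is fully duplicated
#'
#' Pools the supplied partner alignments, computes merged coverage of the
#' candidate, and calls `remove` when the covered fraction reaches
#' `threshold` and the candidate is not the designated keeper of its pair;
#' `keep` when coverage falls short; `candidate_unresolved` when no partner
#' alignment is available.
#'
#' @param candidate One-row profile (from [profileScaffolds()]).
#' @param blocks Alignment blocks with the candidate on the qry side and a
#'   partner on the ref side; blocks mentioning non-partner scaffolds are
#'   an error.
#' @param threshold Coverage fraction for "complete alignment"
#'   (default 0.95).
#' @param isKeeper Whether the candidate is the designated keeper of its
#'   partner pair (see [screenDuplicates()]); keepers are never removed.
#' @return One-row decision data.frame with columns `seqid`, `status`,
#'   `coverage`, `partner`, `reason`.
#' @export
decideDuplicate <- function(candidate, blocks, threshold = 0.95,
                            isKeeper = FALSE) {
  stopifnot(nrow(candidate) == 1)
  .checkBlocks(blocks)
  seqid <- candidate$seqid
  partners <- candidate$partners[[1]]
  if (nrow(blocks)) {
    if (!all(blocks$qry_id == seqid))
      stop("blocks must carry candidate ", seqid, " on the qry side")
    alien <- setdiff(unique(blocks$ref_id), partners)
    if (length(alien))
      stop("blocks mention non-partner scaffold(s): ",
           paste(alien, collapse = ", "))
  }
  if (!nrow(blocks)) {
    return(data.frame(seqid = seqid, status = "candidate_unresolved",
                      coverage = 0, partner = "",
                      reason = "no partner alignments available",
                      stringsAsFactors = FALSE))
  }
  cov <- alignmentCoverage(seqid, candidate$seq_len, blocks, side = "qry")
  # partner contributing the most covered bp
  perPartner <- vapply(unique(blocks$ref_id), function(p) {
    alignmentCoverage(seqid, candidate$seq_len,
                      blocks[blocks$ref_id == p, , drop = FALSE],
                      side = "qry")$covered_bp
  }, numeric(1))
  partnerUsed <- names(perPartner)[which.max(perPartner)]
  if (cov$fraction >= threshold && !isKeeper) {
    status <- "remove"
    reason <- sprintf("coverage %.4f >= %.2f by %s", cov$fraction,
                      threshold, partnerUsed)
  } else if (cov$fraction >= threshold) {
    status <- "keep"
    reason <- sprintf("coverage %.4f but designated keeper of its pair",
                      cov$fraction)
  } else {
    status <- "keep"
    reason <- sprintf("coverage %.4f < %.2f", cov$fraction, threshold)
  }
  data.frame(seqid = seqid, status = status, coverage = cov$fraction,
             partner = partnerUsed, reason = reason,
             stringsAsFactors = FALSE)
}

#' Screen an assembly for fully duplicated scaffolds
#'
#' The complete duplicate-scaffold procedure: profile benchmark-gene
#' duplication, select candidates, align each candidate against its
#' partners (internally with the anchor aligner, or using a supplied block
#' table), and decide removal by merged coverage. Candidates are processed
#' in keeper order (longer scaffold first, ties by Complete benchmark count
#' then id), partner alignments are pooled over partners that are still
#' kept, and a keeper is never removed -- so both members of a partner pair
#' can never be removed.
#'
#' @param assembly Named `DNAStringSet`.
#' @param busco Benchmark full table.
#' @param blocks Optional externally computed alignment blocks (PAF or
#'   coords, read with [readAlignments()]); when supplied, the internal
#'   aligner is bypassed entirely.
#' @param params [anchorParams()] for the internal aligner.
#' @param threshold Coverage fraction for "complete alignment"
#'   (default 0.95).
#' @param includeFragmented Passed to [profileScaffolds()].
#' @return A [DedupResult-class] with one decision row per scaffold.
#' @export
screenDuplicates <- function(assembly, busco, blocks = NULL,
                             params = anchorParams(), threshold = 0.95,
                             includeFragmented = TRUE) {
  profiles <- profileScaffolds(busco, assembly, includeFragmented)
  candidates <- selectCandidates(profiles)
  external <- !is.null(blocks)
  if (external) .checkBlocks(blocks)

  # process in keeper order so partners are adjudicated before dependents
  rank <- .keeperRank(candidates$seqid, profiles, busco)
  candOrder <- candidates$seqid[order(rank)]
  removed <- character(0)
  decRows <- list()
  for (sc in candOrder) {
    cand <- candidates[candidates$seqid == sc, , drop = FALSE]
    partners <- setdiff(cand$partners[[1]], removed)
    if (!length(partners)) {
      decRows[[sc]] <- data.frame(
        seqid = sc, status = "candidate_unresolved", coverage = 0,
        partner = "", reason = "no partner scaffolds remain",
        stringsAsFactors = FALSE)
      next
    }
    if (external) {
      b <- blocks[blocks$qry_id == sc & blocks$ref_id %in% partners, ,
                  drop = FALSE]
    } else {
      b <- alignScaffolds(assembly[partners], assembly[sc], params)
    }
    isKeeper <- all(.keeperRank(c(sc, partners), profiles, busco)[1] == 1)
    decRows[[sc]] <- decideDuplicate(cand, b, threshold, isKeeper)
    if (decRows[[sc]]$status == "remove") removed <- c(removed, sc)
  }

  nonCand <- setdiff(profiles$seqid, candidates$seqid)
  for (sc in nonCand)
    decRows[[sc]] <- data.frame(
      seqid = sc, status = "keep", coverage = NA_real_, partner = "",
      reason = "no duplicated benchmark genes", stringsAsFactors = FALSE)

  dec <- do.call(rbind, decRows[profiles$seqid])
  dec <- cbind(profiles[match(dec$seqid, profiles$seqid),
                        c("seq_len", "n_busco", "n_dup", "pct_dup")],
               dec)[, c("seqid", "seq_len", "n_busco", "n_dup", "pct_dup",
                        "coverage", "status", "partner", "reason")]
  rownames(dec) <- NULL
  new("DedupResult", profiles = profiles, decisions = dec,
      threshold = threshold)
}

#' Split an assembly and its annotation by dedup decisions
#'
#' Partitions scaffolds and features into kept and removed sets; every
#' scaffold and every feature appears in exactly one of the two.
#'
#' @param assembly Named `DNAStringSet`.
#' @param features `GRanges` annotation (may be empty).
#' @param decisions A [DedupResult-class] or its decisions data.frame; must
#'   cover every scaffold of the assembly.
#' @return list with elements `kept`, `keptFeatures`, `removed`,
#'   `removedFeatures`.
#' @export
splitAssembly <- function(assembly, features, decisions) {
  if (is(decisions, "DedupResult")) decisions <- decisions(decisions)
  ids <- names(assembly)
  uncovered <- setdiff(ids, decisions$seqid)
  if (length(uncovered))
    stop("decisions missing for scaffold(s): ",
         paste(uncovered, collapse = ", "))
  removeIds <- decisions$seqid[decisions$status == "remove"]
  keepIds <- setdiff(ids, removeIds)
  featSeq <- as.character(GenomicRanges::seqnames(features))
  orphan <- setdiff(unique(featSeq), ids)
  if (length(orphan))
    stop("feature(s) on scaffold(s) absent from the assembly: ",
         paste(orphan, collapse = ", "))
  list(kept = assembly[keepIds],
       keptFeatures = features[featSeq %in% keepIds],
       removed = assembly[removeIds],
       removedFeatures = features[featSeq %in% removeIds])
}

#' Update a benchmark full table after scaffold removal
#'
#' Restricts placements to kept scaffolds and re-derives statuses: a
#' Duplicated benchmark gene left with a single placement becomes Complete;
#' one left with no placement becomes Missing.
#'
#' @param busco Benchmark full table.
#' @param keptIds Ids of the kept scaffolds.
#' @return Updated full-table data.frame.
#' @export
updateBuscoStatus <- function(busco, keptIds) {
  placed <- busco$status != "Missing" & nzchar(busco$seqid)
  keep <- !placed | busco$seqid %in% keptIds
  out <- busco[keep, , drop = FALSE]
  dupIds <- unique(out$busco_id[out$status == "Duplicated"])
  for (b in dupIds) {
    rows <- which(out$busco_id == b & out$status == "Duplicated")
    if (length(rows) == 1) out$status[rows] <- "Complete"
  }
  lost <- setdiff(unique(busco$busco_id), unique(out$busco_id))
  if (length(lost)) {
    out <- rbind(out, data.frame(
      busco_id = lost, status = "Missing", seqid = "",
      start = NA_integer_, end = NA_integer_, strand = NA_character_,
      score = NA_real_, length = NA_integer_, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
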