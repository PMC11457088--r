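# Duplicate-gene labeling: extract strand-oriented gene regions, aggregate
# similarity scores, and pair focal genes that match each other better than
# anything in the outgroup.

#' Extract strand-oriented gene regions
#'
#' One region per `gene` feature; minus-strand regions are
#' reverse-complemented so every region reads in gene orientation.
#'
#' @param assembly Named `DNAStringSet`.
#' @param features `GRanges` annotation; only `type == "gene"` rows are
#'   used.
#' @return Named `DNAStringSet` (names are gene ids) with metadata columns
#'   `seqid`, `start`, `end` (half-open 0-based) and `strand`.
#' @export
extractGeneRegions <- function(assembly, features) {
  mc <- S4Vectors::mcols(features)
  genes <- features[mc$type == "gene"]
  if (!length(genes)) {
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      seqid = character(), start = integer(), end = integer(),
      strand = character())
    return(out)
  }
  ids <- S4Vectors::mcols(genes)$ID
  if (anyNA(ids) || anyDuplicated(ids))
    stop("gene features need unique, non-missing ID attributes")
  seqid <- as.character(GenomicRanges::seqnames(genes))
  bad <- !(seqid %in% names(assembly))
  if (any(bad))
    stop("gene ", ids[which(bad)[1]], " lies on unknown scaffold ",
         seqid[which(bad)[1]])
  ends <- BiocGenerics::end(genes)
  over <- ends > Biostrings::width(assembly)[match(seqid, names(assembly))]
  if (any(over))
    stop("gene ", ids[which(over)[1]], " extends beyond the end of ",
         seqid[which(over)[1]])
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(genes), function(i) {
    s <- as.character(Biostrings::subseq(
      assembly[[seqid[i]]], start = BiocGenerics::start(genes)[i],
      end = ends[i]))
    if (as.character(BiocGenerics::strand(genes)[i]) == "-")
      .revcomp(s)
    else s
  }, character(1)))
  names(seqs) <- ids
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    seqid = seqid, start = BiocGenerics::start(genes) - 1L, end = ends,
    strand = as.character(BiocGenerics::strand(genes)))
  seqs
}

#' Score gene regions with the internal anchor-match surrogate
#'
#' A stand-in scorer for environments without an external similarity search
#' tool: each query/subject pair is anchor-aligned ([findExactMatches()] +
#' [chainBlocks()]) and scored as 2 x matched bp, reported in the 12-column
#' tabular hit dialect. This is a non-BLAST surrogate intended for testing
#' and synthetic data; bit scores are comparable only within one run.
#'
#' @param queries,subjects Named `DNAStringSet`s of gene regions.
#' @param params [anchorParams()]; the default uses a 50 bp match floor
#'   suitable for gene-scale regions.
#' @return Hit data.frame in the layout of [readHits()]. Self-comparisons
#'   (identical ids) are skipped.
#' @export
scoreRegions <- function(queries, subjects,
                         params = anchorParams(minMatch = 50,
                                               maxGap = 1000)) {
  qchr <- as.character(queries)
  qrc <- .revcomp(qchr)
  schr <- as.character(subjects)
  rows <- list()
  for (qi in seq_along(queries)) {
    qid <- names(queries)[qi]
    qlen <- nchar(qchr[qi])
    for (si in seq_along(subjects)) {
      sid <- names(subjects)[si]
      if (identical(qid, sid)) next
      # cheap anchor pass first; most region pairs share no anchor at all
      sense <- .mem_sense(schr[si], qchr[qi], params$seedK, params$minMatch)
      anti <- .mem_sense(schr[si], qrc[qi], params$seedK, params$minMatch)
      if (!nrow(sense) && !nrow(anti)) next
      mk <- function(d, strand) {
        if (!nrow(d)) return(.emptyBlocks())
        if (strand == "antisense") {
          qs <- qlen - d$qry_end
          d$qry_end <- qlen - d$qry_start
          d$qry_start <- qs
        }
        data.frame(ref_id = sid, qry_id = qid, ref_start = d$ref_start,
                   ref_end = d$ref_end, qry_start = d$qry_start,
                   qry_end = d$qry_end, strand = strand,
                   match_len = d$match_len, identity = 1,
                   stringsAsFactors = FALSE)
      }
      b <- rbind(mk(sense, "sense"), mk(anti, "antisense"))
      ch <- chainBlocks(b, params)
      best <- ch[which.max(ch$match_len), , drop = FALSE]
      matched <- sum(ch$match_len)
      span <- max(best$qry_end - best$qry_start,
                  best$ref_end - best$ref_start)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, subject_id = sid,
        identity = round(100 * best$identity, 2),
        aln_len = span, mismatch = span - best$match_len, gapopen = 0L,
        qstart = best$qry_start + 1L, qend = best$qry_end,
        sstart = best$ref_start + 1L, send = best$ref_end,
        evalue = 0, bitscore = 2 * matched, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(as.data.frame(setNames(
      c(list(character(0), character(0)), rep(list(numeric(0)), 10)),
      .HIT_COLS)))
  do.call(rbind, rows)
}

#' Best focal and outgroup scores per focal gene
#'
#' Collapses similarity hits to, per focal gene: the best-scoring non-self
#' focal subject with its bit score, and the best outgroup bit score (0
#' when there is no outgroup hit). Multiple hits to one subject collapse to
#' the maximum bit score. Bit-score ties for the best focal subject break
#' by greater alignment length, then lexicographic subject id.
#'
#' @param hits Hit data.frame ([readHits()] / [scoreRegions()]).
#' @param focalIds Ids of the focal gene set; every hit query must be
#'   focal.
#' @param outgroupIds Ids of the outgroup gene set; every subject must be
#'   focal or outgroup.
#' @return data.frame with one row per focal gene: `gene_id`,
#'   `best_focal`, `score_focal`, `aln_len_focal`, `best_outgroup`.
#'   Pairwise collapsed focal-vs-focal scores are attached as attribute
#'   `"focal_scores"` for the relaxed classifier mode.
#' @export
bestScores <- function(hits, focalIds, outgroupIds) {
  badQ <- setdiff(unique(hits$query_id), focalIds)
  if (length(badQ))
    stop("hit query id(s) outside the focal set: ",
         paste(utils::head(badQ, 5), collapse = ", "))
  badS <- setdiff(unique(hits$subject_id), c(focalIds, outgroupIds))
  if (length(badS))
    stop("hit subject id(s) in neither focal nor outgroup set: ",
         paste(utils::head(badS, 5), collapse = ", "))
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  isOut <- h$subject_id %in% outgroupIds

  collapse <- function(d) {
    if (!nrow(d)) return(d)
    key <- paste(d$query_id, d$subject_id, sep = "\r")
    keep <- unlist(lapply(split(seq_len(nrow(d)), key), function(i) {
      i[order(-d$bitscore[i], -d$aln_len[i])[1]]
    }), use.names = FALSE)
    d[keep, , drop = FALSE]
  }
  foc <- collapse(h[!isOut, , drop = FALSE])
  out <- collapse(h[isOut, , drop = FALSE])

  tab <- data.frame(gene_id = focalIds, best_focal = NA_character_,
                    score_focal = 0, aln_len_focal = 0,
                    best_outgroup = 0, stringsAsFactors = FALSE)
  if (nrow(foc)) {
    for (g in unique(foc$query_id)) {
      d <- foc[foc$query_id == g, , drop = FALSE]
      i <- order(-d$bitscore, -d$aln_len, d$subject_id)[1]
      r <- match(g, tab$gene_id)
      tab$best_focal[r] <- d$subject_id[i]
      tab$score_focal[r] <- d$bitscore[i]
      tab$aln_len_focal[r] <- d$aln_len[i]
    }
  }
  if (nrow(out)) {
    bo <- tapply(out$bitscore, out$query_id, max)
    r <- match(names(bo), tab$gene_id)
    tab$best_outgroup[r] <- as.numeric(bo)
  }
  attr(tab, "focal_scores") <- foc[, c("query_id", "subject_id",
                                       "bitscore", "aln_len")]
  tab
}

#' Classify duplicate gene pairs against an outgroup
#'
#' Default (`mode = "reciprocal"`): pair (A, B) is emitted iff A's best
#' focal subject is B with a score strictly above A's best outgroup score,
#' and symmetrically for B -- reciprocal best hits that both beat the
#' outgroup. Ties with the best outgroup score never qualify. Each pair is
#' emitted once in canonical (lexicographic) order and a gene appears in at
#' most one pair.
#'
#' `mode = "mutual"` relaxes reciprocity: (A, B) qualifies whenever the
#' collapsed scores in both directions exist and each strictly beats the
#' respective best outgroup score; a gene may then appear in several pairs.
#'
#' @param scoreTable Output of [bestScores()].
#' @param mode `"reciprocal"` (default) or `"mutual"`.
#' @return data.frame with columns `gene_a`, `gene_b`, `score_ab`,
#'   `score_ba`, `best_outgroup_a`, `best_outgroup_b`.
#' @export
classifyDuplicates <- function(scoreTable, mode = c("reciprocal", "mutual")) {
  mode <- match.arg(mode)
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      score_ab = numeric(), score_ba = numeric(),
                      best_outgroup_a = numeric(),
                      best_outgroup_b = numeric(), stringsAsFactors = FALSE)
  t <- scoreTable
  if (mode == "reciprocal") {
    rows <- list()
    for (i in seq_len(nrow(t))) {
      a <- t$gene_id[i]; b <- t$best_focal[i]
      if (is.na(b) || a >= b) next  # canonical order; skip when no focal hit
      j <- match(b, t$gene_id)
      if (is.na(j) || is.na(t$best_focal[j]) || t$best_focal[j] != a) next
      if (!(t$score_focal[i] > t$best_outgroup[i] &&
              t$score_focal[j] > t$best_outgroup[j])) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b,
        score_ab = t$score_focal[i], score_ba = t$score_focal[j],
        best_outgroup_a = t$best_outgroup[i],
        best_outgroup_b = t$best_outgroup[j], stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
  } else {
    fs <- attr(scoreTable, "focal_scores")
    if (is.null(fs))
      stop("mutual mode needs the focal_scores attribute from bestScores()")
    key <- paste(fs$query_id, fs$subject_id, sep = "\r")
    rows <- list()
    cand <- fs[fs$query_id < fs$subject_id, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      a <- cand$query_id[i]; b <- cand$subject_id[i]
      back <- match(paste(b, a, sep = "\r"), key)
      if (is.na(back)) next
      boA <- t$best_outgroup[match(a, t$gene_id)]
      boB <- t$best_outgroup[match(b, t$gene_id)]
      if (!(cand$bitscore[i] > boA && fs$bitscore[back] > boB)) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b,
        score_ab = cand$bitscore[i], score_ba = fs$bitscore[back],
        best_outgroup_a = boA, best_outgroup_b = boB,
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Summarize duplicate-gene classification
#'
#' Duplicate genes are counted as genes (each member of a pair), the
#' reported fraction is `100 * n_dup_genes / n_genes`.
#'
#' @param pairs Output of [classifyDuplicates()].
#' @param focalIds All focal gene ids.
#' @return list with `pairs`, `genes` (sorted duplicate gene ids),
#'   `n_genes`, `n_dup_genes`, `fraction_pct`.
#' @export
dupGeneReport <- function(pairs, focalIds) {
  genes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  list(pairs = pairs, genes = genes, n_genes = length(focalIds),
       n_dup_genes = length(genes),
       fraction_pct = if (length(focalIds))
         100 * length(genes) / length(focalIds) else 0)
}
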