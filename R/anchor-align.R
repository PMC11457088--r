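# Minimal nucmer-like anchor aligner: maximal exact matches above a length
# floor on both strands, collinear chaining, and merged coverage.  Used when
# no external alignment table (PAF / show-coords) is supplied.

#' Anchor alignment parameters
#'
#' @param minMatch Exact-match length floor in bp. The default, 500 bp,
#'   mirrors the minimum exact match commonly used for within-genus whole
#'   genome alignment; cross-species comparisons at larger scale typically
#'   use 1000 bp, while slightly diverged haplotype pairs need a smaller
#'   floor (see the methods vignette).
#' @param maxGap Maximum ref- and qry-side gap bridged when chaining
#'   collinear matches, in bp.
#' @param seedK k-mer size used to seed match detection; must not exceed
#'   `minMatch`.
#' @return Validated parameter list of class `anchor_params`.
#' @export
anchorParams <- function(minMatch = 500, maxGap = 5000, seedK = 21) {
  if (seedK > minMatch)
    stop("seedK (", seedK, ") must not exceed minMatch (", minMatch, ")")
  if (seedK < 1 || seedK > 31) stop("seedK must lie in [1, 31]")
  if (maxGap < 0) stop("maxGap must be >= 0")
  structure(list(minMatch = as.integer(minMatch),
                 maxGap = as.integer(maxGap),
                 seedK = as.integer(seedK)),
            class = "anchor_params")
}

.seqAsChar <- function(x, default) {
  id <- default
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1) stop("expected a single sequence")
    if (!is.null(names(x))) id <- names(x)
    x <- x[[1]]
  }
  if (is(x, "DNAString")) x <- as.character(x)
  if (!is.character(x) || length(x) != 1)
    stop("sequence must be a DNAString(Set) or single character string")
  list(id = id, seq = toupper(x))
}

#' Find maximal exact matches between two sequences
#'
#' Reports every maximal exact match of length >= `minMatch` between `ref`
#' and `qry`, on both strands. Matches are seeded on shared k-mers and
#' extended in both directions; co-extended seeds are de-duplicated, so
#' each maximal match is reported once. `N` never matches anything
#' (including another `N`): seeds containing `N` are skipped and extension
#' stops at `N` on either sequence. Antisense matches are found against the
#' reverse complement of `qry` and reported with coordinates mapped back to
#' the forward strand of `qry` (so `qry_start < qry_end` always holds).
#'
#' @param ref,qry Sequences (`DNAString`, single-sequence `DNAStringSet`,
#'   or character). Ids default to `"ref"`/`"qry"` or the set names.
#' @param params [anchorParams()].
#' @param refId,qryId Optional id overrides.
#' @return data.frame of alignment blocks (half-open 0-based coordinates,
#'   strand `sense`/`antisense`, `identity` = 1 for exact matches).
#' @export
findExactMatches <- function(ref, qry, params = anchorParams(),
                             refId = NULL, qryId = NULL) {
  stopifnot(inherits(params, "anchor_params"))
  r <- .seqAsChar(ref, "ref"); q <- .seqAsChar(qry, "qry")
  if (!is.null(refId)) r$id <- refId
  if (!is.null(qryId)) q$id <- qryId
  qlen <- nchar(q$seq)

  sense <- .mem_sense(r$seq, q$seq, params$seedK, params$minMatch)
  rcq <- .revcomp(q$seq)
  anti <- .mem_sense(r$seq, rcq, params$seedK, params$minMatch)

  mk <- function(d, strand) {
    if (!nrow(d)) return(.emptyBlocks())
    if (strand == "antisense") {
      qs <- qlen - d$qry_end
      qe <- qlen - d$qry_start
      d$qry_start <- qs; d$qry_end <- qe
    }
    data.frame(ref_id = r$id, qry_id = q$id,
               ref_start = d$ref_start, ref_end = d$ref_end,
               qry_start = d$qry_start, qry_end = d$qry_end,
               strand = strand, match_len = d$match_len,
               identity = 1, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(sense, "sense"), mk(anti, "antisense"))
  out[order(out$strand != "sense", out$ref_start, out$qry_start), ,
      drop = FALSE]
}

# chain one strand-homogeneous, sorted group greedily
.chainGroup <- function(g, maxGap) {
  anti <- g$strand[1] == "antisense"
  ord <- order(g$ref_start, if (anti) -g$qry_start else g$qry_start)
  g <- g[ord, , drop = FALSE]
  out <- list()
  cur <- g[1, , drop = FALSE]
  matched <- cur$match_len
  flush <- function(cur, matched) {
    span <- max(cur$ref_end - cur$ref_start, cur$qry_end - cur$qry_start)
    cur$match_len <- min(matched, span)
    cur$identity <- cur$match_len / span
    cur
  }
  for (i in seq_len(nrow(g))[-1]) {
    b <- g[i, , drop = FALSE]
    refGap <- b$ref_start - cur$ref_end
    qryGap <- if (anti) cur$qry_start - b$qry_end
              else b$qry_start - cur$qry_end
    if (refGap <= maxGap && qryGap <= maxGap) {
      cur$ref_start <- min(cur$ref_start, b$ref_start)
      cur$ref_end <- max(cur$ref_end, b$ref_end)
      cur$qry_start <- min(cur$qry_start, b$qry_start)
      cur$qry_end <- max(cur$qry_end, b$qry_end)
      matched <- matched + b$match_len
    } else {
      out[[length(out) + 1L]] <- flush(cur, matched)
      cur <- b
      matched <- b$match_len
    }
  }
  out[[length(out) + 1L]] <- flush(cur, matched)
  do.call(rbind, out)
}

#' Chain collinear alignment blocks
#'
#' Merges same-strand blocks between one (ref, qry) pair whose ref-side and
#' qry-side gaps are each at most `maxGap` and that are collinear: both
#' coordinates increasing for sense blocks; ref increasing while the
#' (forward-strand-normalized) qry interval decreases for antisense blocks.
#' A merged block spans the union of its members; its `match_len` is the
#' summed matched bp (capped at the span) and its identity is matched bp
#' over the larger of the two spans.
#'
#' @param blocks Alignment block data.frame.
#' @param params [anchorParams()]; only `maxGap` is used.
#' @return data.frame of chained blocks.
#' @export
chainBlocks <- function(blocks, params = anchorParams()) {
  .checkBlocks(blocks)
  if (!nrow(blocks)) return(.emptyBlocks())
  key <- paste(blocks$ref_id, blocks$qry_id, blocks$strand, sep = "\r")
  groups <- split(blocks, key)
  out <- do.call(rbind, lapply(groups, .chainGroup, maxGap = params$maxGap))
  rownames(out) <- NULL
  out[order(out$ref_id, out$qry_id, out$strand != "sense", out$ref_start), ,
      drop = FALSE]
}

#' Merged alignment coverage of one sequence
#'
#' Unions the intervals that `blocks` cover on the chosen side of `seqid`
#' (overlaps merged) and reports the covered fraction of the sequence.
#'
#' @param seqid Sequence id whose coverage is assessed.
#' @param seqLen Its length in bp.
#' @param blocks Alignment block data.frame; every row must mention
#'   `seqid` on the given side.
#' @param side `"qry"` or `"ref"`: which side of the blocks `seqid` is on.
#' @return list with `seqid`, `covered_bp`, `seq_len`, `fraction`, and
#'   `blocks` (data.frame of merged disjoint intervals, half-open 0-based).
#' @export
alignmentCoverage <- function(seqid, seqLen, blocks, side = c("qry", "ref")) {
  side <- match.arg(side)
  .checkBlocks(blocks)
  idc <- paste0(side, "_id")
  if (nrow(blocks) && !all(blocks[[idc]] == seqid))
    stop("all blocks must mention ", seqid, " on the ", side, " side")
  sc <- paste0(side, "_start"); ec <- paste0(side, "_end")
  if (nrow(blocks) && any(blocks[[ec]] > seqLen))
    stop("alignment block exceeds the length of ", seqid)
  if (!nrow(blocks)) {
    merged <- data.frame(start = integer(), end = integer())
  } else {
    ir <- IRanges::reduce(IRanges::IRanges(start = blocks[[sc]] + 1L,
                                           end = blocks[[ec]]))
    merged <- data.frame(start = BiocGenerics::start(ir) - 1L,
                         end = BiocGenerics::end(ir))
  }
  covered <- sum(merged$end - merged$start)
  list(seqid = seqid, covered_bp = covered, seq_len = seqLen,
       fraction = covered / seqLen, blocks = merged)
}

#' Align two scaffold sets and chain the anchors
#'
#' Convenience wrapper running [findExactMatches()] for every (ref, qry)
#' scaffold pair followed by [chainBlocks()].
#'
#' @param refs,qrys Named `DNAStringSet`s.
#' @param params [anchorParams()].
#' @param chain Chain the raw matches (default TRUE).
#' @return data.frame of alignment blocks.
#' @export
alignScaffolds <- function(refs, qrys, params = anchorParams(),
                           chain = TRUE) {
  out <- list()
  for (ri in seq_along(refs)) {
    for (qi in seq_along(qrys)) {
      b <- findExactMatches(refs[ri], qrys[qi], params)
      if (nrow(b)) out[[length(out) + 1L]] <- b
    }
  }
  blocks <- if (length(out)) do.call(rbind, out) else .emptyBlocks()
  if (chain && nrow(blocks)) blocks <- chainBlocks(blocks, params)
  blocks
}

#' Dotplot table from alignment blocks
#'
#' Midpoints of each block on both sequences with strand, the minimal data
#' needed for a whole-genome dotplot (sense matches along positive-slope
#' lines, antisense along negative-slope lines).
#'
#' @param blocks Alignment block data.frame.
#' @return data.frame with `ref_id`, `qry_id`, `ref_mid`, `qry_mid`,
#'   `strand`.
#' @export
dotplotTable <- function(blocks) {
  .checkBlocks(blocks)
  data.frame(ref_id = blocks$ref_id, qry_id = blocks$qry_id,
             ref_mid = (blocks$ref_start + blocks$ref_end) / 2,
             qry_mid = (blocks$qry_start + blocks$qry_end) / 2,
             strand = blocks$strand, stringsAsFactors = FALSE)
}
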