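# Independent oracles and fixture builders used across the suite.

randDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# brute-force Nx/Lx: walk the descending lengths and accumulate
oracleNxLx <- function(lengths, x) {
  sl <- sort(lengths, decreasing = TRUE)
  target <- x / 100 * sum(as.numeric(sl))
  acc <- 0
  for (i in seq_along(sl)) {
    acc <- acc + sl[i]
    if (acc >= target) return(list(nx = sl[i], lx = i))
  }
}

# quadratic-time maximal-common-substring enumeration on one strand;
# N matches nothing, including N
oracleMemsOneStrand <- function(ref, qry, minLen) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  q <- strsplit(qry, "", fixed = TRUE)[[1]]
  M <- outer(r, q, "==")
  M[r == "N", ] <- FALSE
  M[, q == "N"] <- FALSE
  idx <- which(M, arr.ind = TRUE)
  out <- list()
  if (nrow(idx)) {
    d <- idx[, 2] - idx[, 1]
    for (dd in unique(d)) {
      rows <- sort(idx[d == dd, 1])
      br <- c(0L, which(diff(rows) != 1L), length(rows))
      for (k in seq_len(length(br) - 1L)) {
        s <- rows[br[k] + 1L]
        e <- rows[br[k + 1L]]
        len <- e - s + 1L
        if (len >= minLen)
          out[[length(out) + 1L]] <- data.frame(
            ref_start = s - 1L, ref_end = e,
            qry_start = s - 1L + dd, qry_end = e + dd,
            match_len = len)
      }
    }
  }
  if (!length(out))
    return(data.frame(ref_start = integer(), ref_end = integer(),
                      qry_start = integer(), qry_end = integer(),
                      match_len = integer()))
  do.call(rbind, out)
}

# both strands, mapped back to the forward strand of qry like the aligner
oracleMems <- function(ref, qry, minLen) {
  qlen <- nchar(qry)
  sense <- oracleMemsOneStrand(ref, qry, minLen)
  anti <- oracleMemsOneStrand(ref, revcompChr(qry), minLen)
  if (nrow(anti)) {
    qs <- qlen - anti$qry_end
    anti$qry_end <- qlen - anti$qry_start
    anti$qry_start <- qs
  }
  sense$strand <- rep("sense", nrow(sense))
  anti$strand <- rep("antisense", nrow(anti))
  rbind(sense, anti)
}

canonBlocks <- function(b) {
  b <- b[, c("ref_start", "ref_end", "qry_start", "qry_end", "strand",
             "match_len")]
  b <- b[order(b$strand, b$ref_start, b$qry_start), , drop = FALSE]
  rownames(b) <- NULL
  b
}

# per-base bitmap accounting of repeat classes
bitmapRepeatSummary <- function(ann, genomeLens) {
  classes <- c("Tandem", "Simple", "Satellite", "DNA", "RC", "LINE",
               "LTR", "rRNA", "snRNA", "tRNA", "Unknown")
  acc <- setNames(numeric(length(classes) + 2),
                  c(classes, "Multiclass", "Total"))
  for (sc in names(genomeLens)) {
    L <- genomeLens[[sc]]
    byClass <- matrix(FALSE, nrow = L, ncol = length(classes),
                      dimnames = list(NULL, classes))
    d <- ann[ann$seqid == sc, , drop = FALSE]
    for (i in seq_len(nrow(d)))
      byClass[(d$start[i] + 1L):d$end[i], d$rclass[i]] <- TRUE
    n <- rowSums(byClass)
    for (cl in classes)
      acc[cl] <- acc[cl] + sum(byClass[, cl] & n == 1)
    acc["Multiclass"] <- acc["Multiclass"] + sum(n >= 2)
    acc["Total"] <- acc["Total"] + sum(n >= 1)
  }
  acc
}

# brute-force duplicate-pair classification straight from a raw hit table:
# per-gene bests are found by naive loops, then every focal pair is tested
oracleDupPairs <- function(hits, focalIds, outgroupIds) {
  h <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  bestSubject <- function(g) {
    d <- h[h$query_id == g & h$subject_id %in% focalIds, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    agg <- list()
    for (s in unique(d$subject_id)) {
      rows <- d[d$subject_id == s, , drop = FALSE]
      best <- rows[order(-rows$bitscore, -rows$aln_len)[1], , drop = FALSE]
      agg[[s]] <- best
    }
    agg <- do.call(rbind, agg)
    agg[order(-agg$bitscore, -agg$aln_len, agg$subject_id)[1], ,
        drop = FALSE]
  }
  bestOut <- function(g) {
    d <- h[h$query_id == g & h$subject_id %in% outgroupIds, , drop = FALSE]
    if (!nrow(d)) 0 else max(d$bitscore)
  }
  bests <- lapply(setNames(focalIds, focalIds), bestSubject)
  outs <- vapply(setNames(focalIds, focalIds), bestOut, numeric(1))
  pairs <- list()
  for (a in focalIds) for (b in focalIds) {
    if (a >= b) next
    ba <- bests[[a]]; bb <- bests[[b]]
    if (is.null(ba) || is.null(bb)) next
    if (ba$subject_id != b || bb$subject_id != a) next
    if (!(ba$bitscore > outs[[a]] && bb$bitscore > outs[[b]])) next
    pairs[[length(pairs) + 1L]] <- data.frame(gene_a = a, gene_b = b)
  }
  if (!length(pairs))
    return(data.frame(gene_a = character(), gene_b = character()))
  do.call(rbind, pairs)
}

# random hit tables for classifier property tests
randomHitTable <- function(nFocal, nOutgroup, nHits) {
  focal <- sprintf("f%02d", seq_len(nFocal))
  outg <- sprintf("o%02d", seq_len(nOutgroup))
  data.frame(
    query_id = sample(focal, nHits, replace = TRUE),
    subject_id = sample(c(focal, outg), nHits, replace = TRUE),
    identity = round(runif(nHits, 70, 100), 2),
    aln_len = sample(100:2000, nHits, replace = TRUE),
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
    sstart = 1L, send = 100L, evalue = 0,
    bitscore = sample(seq(50, 1000, by = 25), nHits, replace = TRUE),
    stringsAsFactors = FALSE)
}

# scaled-down repeat spec for miniature genomes
tinyRepeatSpec <- function(scale = 0.15) {
  s <- hapcull:::.defaultRepeatSpec()
  s$n_copies <- pmax(1L, as.integer(round(s$n_copies * scale)))
  s
}

# small shared synthetic fixture + pipeline run, built once per session
.fixtureEnv <- new.env(parent = emptyenv())

sharedSim <- function() {
  if (is.null(.fixtureEnv$sim))
    .fixtureEnv$sim <- simulateGenome(simConfig())
  .fixtureEnv$sim
}

sharedRun <- function() {
  if (is.null(.fixtureEnv$run)) {
    dir <- file.path(tempdir(), "hapcull-shared-run")
    .fixtureEnv$run <- runPipeline(simConfig(), outDir = dir, quiet = TRUE)
    .fixtureEnv$runDir <- dir
  }
  .fixtureEnv$run
}

sharedRunDir <- function() {
  sharedRun()
  .fixtureEnv$runDir
}

writeLinesTmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
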