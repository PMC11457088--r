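# Maximal-exact-match aligner, chaining and coverage.

test_that("parameter validation enforces seed/minMatch ordering", {
  expect_error(anchorParams(minMatch = 10, seedK = 21), "seedK")
  expect_error(anchorParams(seedK = 0))
  expect_silent(anchorParams(minMatch = 21, seedK = 21))
})

test_that("identical sequences give one full-length sense match", {
  set.seed(7)
  a <- randDna(3000)
  b <- findExactMatches(a, a, anchorParams(minMatch = 500))
  expect_equal(nrow(b), 1L)
  expect_identical(b$strand, "sense")
  expect_equal(b$ref_start, 0L); expect_equal(b$ref_end, 3000L)
  expect_equal(b$qry_start, 0L); expect_equal(b$qry_end, 3000L)
  expect_equal(b$match_len, 3000L)
})

test_that("a reverse-complement query yields one full antisense match", {
  set.seed(8)
  a <- randDna(2500)
  b <- findExactMatches(a, revcompChr(a), anchorParams(minMatch = 500))
  expect_equal(nrow(b), 1L)
  expect_identical(b$strand, "antisense")
  expect_equal(b$match_len, 2500L)
  expect_equal(b$qry_start, 0L); expect_equal(b$qry_end, 2500L)
})

test_that("a planted shared segment is recovered exactly once", {
  set.seed(9)
  seg <- randDna(600)
  ref <- paste0(randDna(700), seg, randDna(700))
  qry <- paste0(randDna(300), seg, randDna(1100))
  b <- findExactMatches(ref, qry, anchorParams(minMatch = 500))
  oc <- oracleMems(ref, qry, 500)
  expect_equal(canonBlocks(b), canonBlocks(oc))
  expect_equal(nrow(b), 1L)
  expect_gte(b$match_len, 600L)  # flanks may extend the match by chance
})

test_that("the aligner matches the quadratic oracle on small inputs", {
  set.seed(10)
  params <- anchorParams(minMatch = 25, seedK = 15)
  for (i in 1:25) {
    n <- sample(200:1500, 1)
    ref <- randDna(n)
    qry <- ref
    # derived query: mutated copy, inverted middle, or unrelated
    mode <- i %% 3
    if (mode == 0) {
      v <- strsplit(ref, "")[[1]]
      hit <- which(runif(n) < 0.02)
      v[hit] <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
      qry <- paste(v, collapse = "")
    } else if (mode == 1) {
      s <- floor(n / 3); e <- floor(2 * n / 3)
      qry <- paste0(substr(ref, 1, s),
                    revcompChr(substr(ref, s + 1, e)),
                    substr(ref, e + 1, n))
    } else {
      qry <- paste0(substr(ref, 1, floor(n / 2)), randDna(ceiling(n / 2)))
    }
    expect_equal(canonBlocks(findExactMatches(ref, qry, params)),
                 canonBlocks(oracleMems(ref, qry, 25)))
  }
})

test_that("N never matches anything, including another N", {
  withN <- paste0(randDna(300), strrep("N", 50), randDna(300))
  b <- findExactMatches(withN, withN, anchorParams(minMatch = 100,
                                                   seedK = 21))
  # self-alignment splits at the N run: no block crosses it
  expect_true(all(b$ref_end <= 300 | b$ref_start >= 350))
  onlyN <- strrep("N", 200)
  expect_equal(nrow(findExactMatches(onlyN, onlyN,
                                     anchorParams(minMatch = 21))), 0L)
})

test_that("chaining merges collinear same-strand blocks only", {
  p <- anchorParams(minMatch = 21, maxGap = 500)
  two <- data.frame(
    ref_id = "r", qry_id = "q",
    ref_start = c(0L, 300L), ref_end = c(200L, 500L),
    qry_start = c(0L, 300L), qry_end = c(200L, 500L),
    strand = "sense", match_len = c(200L, 200L), identity = 1)
  ch <- chainBlocks(two, p)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$ref_start, 0L); expect_equal(ch$ref_end, 500L)
  expect_equal(ch$match_len, 400L)
  expect_equal(ch$identity, 400 / 500)

  # gap above maxGap stays split
  two$ref_start[2] <- 900L; two$ref_end[2] <- 1100L
  two$qry_start[2] <- 900L; two$qry_end[2] <- 1100L
  expect_equal(nrow(chainBlocks(two, p)), 2L)

  # opposite strands never merge
  mixed <- two
  mixed$ref_start[2] <- 300L; mixed$ref_end[2] <- 500L
  mixed$qry_start[2] <- 300L; mixed$qry_end[2] <- 500L
  mixed$strand <- c("sense", "antisense")
  expect_equal(nrow(chainBlocks(mixed, p)), 2L)

  expect_equal(nrow(chainBlocks(hapcull:::.emptyBlocks(), p)), 0L)
})

test_that("antisense chains require anti-diagonal collinearity", {
  p <- anchorParams(minMatch = 21, maxGap = 500)
  anti <- data.frame(
    ref_id = "r", qry_id = "q",
    ref_start = c(0L, 300L), ref_end = c(200L, 500L),
    qry_start = c(800L, 500L), qry_end = c(1000L, 700L),
    strand = "antisense", match_len = c(200L, 200L), identity = 1)
  ch <- chainBlocks(anti, p)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$qry_start, 500L)
  expect_equal(ch$qry_end, 1000L)
})

test_that("coverage unions intervals and respects bounds", {
  mkb <- function(s, e) data.frame(
    ref_id = "r", qry_id = "q", ref_start = s, ref_end = e,
    qry_start = s, qry_end = e, strand = "sense",
    match_len = e - s, identity = 1)
  b <- rbind(mkb(0L, 60L), mkb(40L, 100L))
  cov <- alignmentCoverage("q", 100, b, side = "qry")
  expect_equal(cov$fraction, 1.0)
  expect_equal(cov$covered_bp, 100)
  expect_equal(alignmentCoverage("q", 100, mkb(0L, 40L), "qry")$fraction,
               0.4)
  none <- alignmentCoverage("q", 100, hapcull:::.emptyBlocks(), "qry")
  expect_equal(none$fraction, 0)
  expect_error(alignmentCoverage("q", 50, mkb(0L, 60L), "qry"), "exceeds")
  expect_error(alignmentCoverage("zz", 100, mkb(0L, 10L), "qry"),
               "mention")
  # invariant to order and duplication of identical blocks
  shuffled <- rbind(mkb(40L, 100L), mkb(0L, 60L), mkb(0L, 60L))
  expect_equal(alignmentCoverage("q", 100, shuffled, "qry")$fraction, 1.0)
})

test_that("self-alignment of an N-free sequence covers it fully", {
  set.seed(11)
  a <- Biostrings::DNAStringSet(c(sA = randDna(2000)))
  blocks <- alignScaffolds(a, a, anchorParams(minMatch = 500))
  cov <- alignmentCoverage("sA", 2000, blocks, side = "qry")
  expect_equal(cov$fraction, 1.0)
})

test_that("chained coverage recovers simulated haplotype pairs", {
  # haplotype pairs at ~1% divergence: exact stretches average ~100 bp, so
  # a 30 bp floor with moderate gap bridging recovers nearly everything
  set.seed(12)
  params <- anchorParams(minMatch = 30, maxGap = 2000, seedK = 21)
  for (i in 1:3) {
    hap1 <- randDna(20000)
    v <- strsplit(hap1, "")[[1]]
    hit <- which(runif(20000) < 0.01)
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    hap2 <- paste(v, collapse = "")
    blocks <- chainBlocks(findExactMatches(hap1, hap2, params), params)
    cov <- alignmentCoverage("qry", 20000, blocks, side = "qry")
    expect_gte(cov$fraction, 0.90)
  }
})

test_that("dotplot table reports block midpoints with strand", {
  a <- randDna(1000)
  b <- findExactMatches(a, a, anchorParams(minMatch = 500))
  dp <- dotplotTable(b)
  expect_equal(dp$ref_mid, 500)
  expect_identical(dp$strand, "sense")
})
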