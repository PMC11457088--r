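# Duplicate-scaffold screening: profiling, decisions, splitting.

mkBusco <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(busco_id = r[[1]], status = r[[2]],
               seqid = if (r[[2]] == "Missing") "" else r[[3]],
               start = if (r[[2]] == "Missing") NA_integer_ else 100L,
               end = if (r[[2]] == "Missing") NA_integer_ else 900L,
               strand = "+", score = 500, length = 800L,
               stringsAsFactors = FALSE)))
}

mkAsm <- function(lens) {
  Biostrings::DNAStringSet(setNames(vapply(lens, randDna, ""), names(lens)))
}

test_that("profiles tally duplication and link partner scaffolds", {
  asm <- mkAsm(c(s1 = 1000, s2 = 800))
  busco <- mkBusco(list("b1", "Complete", "s1"),
                   list("b2", "Duplicated", "s1"),
                   list("b2", "Duplicated", "s2"),
                   list("b3", "Fragmented", "s2"))
  prof <- profileScaffolds(busco, asm)
  s1 <- prof[prof$seqid == "s1", ]; s2 <- prof[prof$seqid == "s2", ]
  expect_equal(s1$pct_dup, 50)   # Fragmented counts toward the denominator
  expect_equal(s2$pct_dup, 50)
  expect_identical(s1$partners[[1]], "s2")
  expect_identical(s2$partners[[1]], "s1")
  # ties on pct_dup sort by ascending length
  expect_identical(prof$seqid, c("s2", "s1"))

  # denominator configurable to Complete + Duplicated only
  prof2 <- profileScaffolds(busco, asm, includeFragmented = FALSE)
  expect_equal(prof2$pct_dup[prof2$seqid == "s2"], 100)
})

test_that("zero-benchmark and all-Complete scaffolds profile cleanly", {
  asm <- mkAsm(c(s1 = 1000, s2 = 500))
  busco <- mkBusco(list("b1", "Complete", "s1"))
  prof <- profileScaffolds(busco, asm)
  expect_equal(nrow(prof), 2L)
  s2 <- prof[prof$seqid == "s2", ]
  expect_equal(s2$n_busco, 0L)
  expect_equal(s2$pct_dup, 0)
  expect_true(all(lengths(prof$partners) == 0))
  expect_error(
    profileScaffolds(mkBusco(list("b1", "Complete", "nope")), asm),
    "unknown scaffold")
})

test_that("candidate selection keeps exactly the duplicated profiles", {
  asm <- mkAsm(c(s1 = 1000, s2 = 900, s3 = 800))
  busco <- mkBusco(list("b1", "Complete", "s1"),
                   list("b2", "Duplicated", "s2"),
                   list("b2", "Duplicated", "s3"),
                   list("b3", "Duplicated", "s3"),
                   list("b3", "Duplicated", "s2"))
  prof <- profileScaffolds(busco, asm)
  cand <- selectCandidates(prof)
  expect_setequal(cand$seqid, c("s2", "s3"))
  expect_equal(nrow(selectCandidates(prof[prof$n_dup == 0, ])), 0L)
})

test_that("decisions follow coverage, keeper status and partner checks", {
  cand <- data.frame(seqid = "s2", seq_len = 100L, n_busco = 1L,
                     n_dup = 1L, pct_dup = 100)
  cand$partners <- list("s1")
  mkb <- function(s, e) data.frame(
    ref_id = "s1", qry_id = "s2", ref_start = s, ref_end = e,
    qry_start = s, qry_end = e, strand = "sense",
    match_len = e - s, identity = 1)
  d <- decideDuplicate(cand, mkb(0L, 100L))
  expect_identical(d$status, "remove")
  expect_identical(d$partner, "s1")

  d2 <- decideDuplicate(cand, mkb(0L, 40L))
  expect_identical(d2$status, "keep")
  expect_match(d2$reason, "0.4")

  d3 <- decideDuplicate(cand, hapcull:::.emptyBlocks())
  expect_identical(d3$status, "candidate_unresolved")

  d4 <- decideDuplicate(cand, mkb(0L, 100L), isKeeper = TRUE)
  expect_identical(d4$status, "keep")
  expect_match(d4$reason, "keeper")

  alien <- mkb(0L, 100L); alien$ref_id <- "s9"
  expect_error(decideDuplicate(cand, alien), "non-partner")
})

test_that("splitting partitions scaffolds and features exactly", {
  asm <- mkAsm(c(s1 = 400, s2 = 300, s3 = 200))
  gff <- writeLinesTmp(c(
    "s1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1",
    "s2\tsrc\tgene\t10\t100\t.\t+\t.\tID=g2",
    "s3\tsrc\tgene\t10\t100\t.\t+\t.\tID=g3"), ".gff3")
  feat <- readAnnotation(gff)
  dec <- data.frame(seqid = c("s1", "s2", "s3"),
                    status = c("keep", "remove", "keep"),
                    coverage = c(NA, 1, NA), partner = c("", "s1", ""),
                    stringsAsFactors = FALSE)
  parts <- splitAssembly(asm, feat, dec)
  expect_identical(names(parts$kept), c("s1", "s3"))
  expect_identical(names(parts$removed), "s2")
  expect_identical(S4Vectors::mcols(parts$removedFeatures)$ID, "g2")
  # conservation of scaffolds, bases and features
  expect_equal(length(parts$kept) + length(parts$removed), length(asm))
  expect_equal(sum(Biostrings::width(parts$kept)) +
                 sum(Biostrings::width(parts$removed)),
               sum(Biostrings::width(asm)))
  expect_equal(length(parts$keptFeatures) + length(parts$removedFeatures),
               length(feat))

  # empty removal set: kept is identical to the input
  dec$status <- "keep"
  same <- splitAssembly(asm, feat, dec)
  expect_identical(names(same$kept), names(asm))
  expect_equal(length(same$removed), 0L)

  ghost <- readAnnotation(writeLinesTmp(
    "sX\tsrc\tgene\t1\t10\t.\t+\t.\tID=gX", ".gff3"))
  expect_error(splitAssembly(asm, ghost, dec), "absent")
})

test_that("screening the synthetic assembly removes exactly the haplotigs", {
  sim <- sharedSim()
  truth <- truthSet(sim)$haplotigs
  res <- screenDuplicates(assemblySeqs(sim), buscoTable(sim),
                          params = anchorParams(minMatch = 30,
                                                maxGap = 2000),
                          threshold = 0.95)
  expect_setequal(removedScaffolds(res), truth$seqid)
  d <- decisions(res)
  # a removed scaffold's partner is never itself removed
  rm <- d[d$status == "remove", ]
  expect_false(any(rm$partner %in% rm$seqid))
  # every removal is justified by coverage above the threshold
  expect_true(all(rm$coverage >= coverageThreshold(res)))
})

test_that("re-profiling the kept assembly shows no duplicated benchmarks", {
  sim <- sharedSim()
  res <- screenDuplicates(assemblySeqs(sim), buscoTable(sim),
                          params = anchorParams(minMatch = 30,
                                                maxGap = 2000))
  kept <- setdiff(names(assemblySeqs(sim)), removedScaffolds(res))
  updated <- updateBuscoStatus(buscoTable(sim), kept)
  expect_equal(sum(updated$status == "Duplicated"), 0L)
  prof <- profileScaffolds(updated, assemblySeqs(sim)[kept])
  expect_true(all(prof$n_dup == 0))
  # every benchmark gene still has exactly one row or a Missing row
  expect_setequal(unique(updated$busco_id), unique(buscoTable(sim)$busco_id))
})
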