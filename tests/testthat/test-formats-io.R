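# Readers/writers: dialect handling, coordinate normalization, round-trips.

test_that("FASTA reading folds case, keeps order and catches bad input", {
  f <- writeLinesTmp(c(">s1 first scaffold", "acgt", ">s2", "GGcc"), ".fa")
  seqs <- readAssembly(f)
  expect_identical(names(seqs), c("s1", "s2"))
  expect_identical(as.character(seqs[["s1"]]), "ACGT")
  expect_identical(as.character(seqs[["s2"]]), "GGCC")
  expect_identical(S4Vectors::mcols(seqs)$description[1], "first scaffold")

  dupf <- writeLinesTmp(c(">s1", "ACGT", ">s1", "TTTT"), ".fa")
  expect_error(readAssembly(dupf), "s1")
  emptyf <- writeLinesTmp(character(0), ".fa")
  expect_error(readAssembly(emptyf))
})

test_that("FASTA write/read round-trips records exactly", {
  seqs <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "TTTTGGGG"))
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(description = c("x y", ""))
  f <- tempfile(fileext = ".fa")
  writeAssembly(seqs, f)
  back <- readAssembly(f)
  expect_identical(as.character(back), as.character(seqs))
  expect_identical(names(back), names(seqs))
  expect_identical(S4Vectors::mcols(back)$description,
                   S4Vectors::mcols(seqs)$description)
})

test_that("GFF3 parsing keeps 1-based coordinates and resolves parents", {
  f <- writeLinesTmp(c(
    "##gff-version 3",
    "s1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1",
    "s1\tsrc\tmRNA\t10\t100\t.\t+\t.\tID=g1.t1;Parent=g1",
    "s1\tsrc\tweird_feature\t5\t7\t.\t.\t.\tID=w1"), ".gff3")
  gr <- readAnnotation(f)
  expect_equal(length(gr), 3L)
  expect_equal(BiocGenerics::start(gr)[1], 10)
  expect_equal(BiocGenerics::end(gr)[1], 100)
  mc <- S4Vectors::mcols(gr)
  expect_identical(mc$ID[2], "g1.t1")
  expect_identical(mc$Parent[2], "g1")
  expect_true(mc$Parent[2] %in% mc$ID)  # parent link resolvable
  expect_identical(mc$type[3], "weird_feature")  # unknown types retained
})

test_that("GFF3 reader reports malformed lines and bad coordinates", {
  bad <- writeLinesTmp(c("# c", "s1\tsrc\tgene\t10\t100\t.\t+\t."), ".gff3")
  expect_error(readAnnotation(bad), "line 2")
  rev <- writeLinesTmp("s1\tsrc\tgene\t100\t10\t.\t+\t.\tID=g1", ".gff3")
  expect_error(readAnnotation(rev), "end < start at GFF line 1")
  over <- writeLinesTmp("s1\tsrc\tgene\t10\t100\t.\t+\t.\tID=g1", ".gff3")
  expect_error(readAnnotation(over, seqLens = c(s1 = 50)), "beyond")
})

test_that("GFF3 write/read round-trips, including attribute strings", {
  f <- writeLinesTmp(c(
    "s1\tsrc\tgene\t10\t100\t.\t-\t.\tID=g1;Name=foo",
    "s1\tsrc\tCDS\t12\t60\t.\t-\t0\tID=c1;Parent=g1.t1"), ".gff3")
  gr <- readAnnotation(f)
  f2 <- tempfile(fileext = ".gff3")
  writeAnnotation(gr, f2)
  gr2 <- readAnnotation(f2)
  expect_identical(S4Vectors::mcols(gr)$attributes,
                   S4Vectors::mcols(gr2)$attributes)
  expect_equal(BiocGenerics::start(gr), BiocGenerics::start(gr2))
  expect_identical(as.character(BiocGenerics::strand(gr)),
                   as.character(BiocGenerics::strand(gr2)))
})

test_that("benchmark full tables parse in both dialects", {
  f <- writeLinesTmp(c(
    "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength",
    "b1\tComplete\ts1\t100\t900\t+\t500\t800",
    "b2\tDuplicated\ts1\t100\t900\t+\t450\t800",
    "b2\tDuplicated\ts2\t5\t805\t-\t445\t800",
    "b3\tMissing"), ".tsv")
  b <- readBuscoTable(f)
  expect_equal(nrow(b), 4L)
  expect_identical(b$status[1], "Complete")
  expect_equal(sum(b$busco_id == "b2" & b$status == "Duplicated"), 2L)
  expect_identical(b$seqid[b$status == "Missing"], "")
  expect_true(is.na(b$start[b$status == "Missing"]))

  # 7-column layout without strand
  f4 <- writeLinesTmp("b1\tComplete\ts1\t100\t900\t500\t800", ".tsv")
  b4 <- readBuscoTable(f4)
  expect_equal(b4$score, 500)
  expect_equal(b4$length, 800L)
  expect_true(is.na(b4$strand))

  badf <- writeLinesTmp("b1\tPartial\ts1\t1\t2\t+\t5\t2", ".tsv")
  expect_error(readBuscoTable(badf), "Partial")
})

test_that("benchmark table write/read round-trips", {
  sim <- sharedSim()
  f <- tempfile(fileext = ".tsv")
  writeBuscoTable(buscoTable(sim), f)
  back <- readBuscoTable(f)
  expect_equal(back, buscoTable(sim))
})

test_that("PAF alignments normalize to half-open 0-based blocks", {
  f <- writeLinesTmp(c(
    "q1\t1000\t100\t600\t+\tr1\t2000\t200\t700\t480\t500\t60",
    "q1\t1000\t0\t400\t-\tr1\t2000\t900\t1300\t390\t400\t60"), ".paf")
  b <- readAlignments(f, "paf")
  expect_equal(nrow(b), 2L)
  expect_identical(b$strand, c("sense", "antisense"))
  expect_equal(b$qry_start[2], 0L)
  expect_equal(b$qry_end[2], 400L)
  expect_equal(b$match_len, c(480L, 390L))
  # qry interval length matches dialect-implied length
  expect_equal(b$qry_end - b$qry_start, c(500L, 400L))

  badf <- writeLinesTmp(
    "q1\t300\t100\t600\t+\tr1\t2000\t200\t700\t480\t500\t60", ".paf")
  expect_error(readAlignments(badf, "paf"), "outside declared")
  expect_equal(nrow(readAlignments(writeLinesTmp(character(0)), "paf")), 0L)
})

test_that("show-coords rows shift to the internal convention", {
  f <- writeLinesTmp(c(
    "NUCMER", "", "[S1]\t[E1]\t[S2]\t[E2]",
    "1\t100\t1\t100\t100\t100\t98.5\trefA\tqryA",
    "201\t300\t400\t301\t100\t100\t95.0\trefA\tqryA"), ".coords")
  b <- readAlignments(f, "coords")
  expect_equal(b$ref_start[1], 0L)  # 1-based inclusive 1..100 -> 0..100
  expect_equal(b$ref_end[1], 100L)
  expect_identical(b$strand, c("sense", "antisense"))
  expect_equal(b$qry_start[2], 300L)
  expect_equal(b$qry_end[2], 400L)
  expect_equal(b$identity[1], 0.985)
})

test_that("alignment blocks round-trip through PAF", {
  ref <- randDna(500); qry <- paste0(substr(ref, 1, 300), randDna(200))
  blocks <- findExactMatches(ref, qry, anchorParams(minMatch = 50,
                                                    seedK = 21))
  f <- tempfile(fileext = ".paf")
  writeAlignments(blocks, f, qryLens = c(qry = 500), refLens = c(ref = 500))
  back <- readAlignments(f, "paf")
  expect_equal(back[, c("ref_start", "ref_end", "qry_start", "qry_end")],
               blocks[, c("ref_start", "ref_end", "qry_start", "qry_end")])
  expect_equal(back$match_len, blocks$match_len)
})

test_that("similarity hits parse the 12-column dialect", {
  f <- writeLinesTmp(c(
    "gA\tgB\t98.5\t500\t5\t0\t1\t500\t1\t500\t1e-100\t500",
    "gA\tgA\t100\t600\t0\t0\t1\t600\t1\t600\t0\t1200"), ".tsv")
  h <- readHits(f)
  expect_equal(nrow(h), 2L)  # self-hits retained on read
  expect_identical(h$bitscore, c(500, 1200))
  expect_type(h$bitscore, "double")
  f2 <- tempfile(fileext = ".tsv")
  writeHits(h, f2)
  expect_equal(readHits(f2), h)
})

test_that("RepeatMasker .out classes map onto the accounting vocabulary", {
  f <- writeLinesTmp(c(
    "   SW   perc perc perc  query  position in query  matching repeat",
    "score   div. del. ins.  sequence begin end (left) repeat class/family",
    "",
    " 250 5.0 0.0 0.0 s1 101 200 (0) + R1 LINE/R1 1 100 (0) 1",
    " 250 5.0 0.0 0.0 s1 301 400 (0) + Gypsy LTR/Gypsy 1 100 (0) 2",
    " 250 5.0 0.0 0.0 s2 11 40 (0) + weird Bizarre/X 1 30 (0) 3"), ".out")
  expect_warning(ann <- readRepeatTable(f, "rmout", runId = "r1"),
                 "Bizarre")
  expect_equal(nrow(ann), 3L)  # unmappable recorded, never dropped
  expect_identical(ann$rclass, c("LINE", "LTR", "Unknown"))
  expect_identical(ann$family[1], "R1")
  expect_equal(ann$start[1], 100L)  # 1-based inclusive -> half-open 0-based
  expect_equal(ann$end[1], 200L)
  expect_equal(ann$end[1] - ann$start[1], 100L)
  expect_identical(unique(ann$run_id), "r1")
})

test_that("TRF dat tables become Tandem annotations", {
  f <- writeLinesTmp(c(
    "Tandem Repeats Finder Program",
    "Sequence: s1 some description",
    "101 400 50 6.0 50 95 0 500",
    "Sequence: s2",
    "11 110 25 4.0 25 90 0 200"), ".dat")
  ann <- readRepeatTable(f, "trf")
  expect_equal(nrow(ann), 2L)
  expect_identical(unique(ann$rclass), "Tandem")
  expect_identical(ann$seqid, c("s1", "s2"))
  expect_equal(ann$end - ann$start, c(300L, 100L))
})

test_that("repeat table writer round-trips through the rmout reader", {
  sim <- sharedSim()
  rep <- repeatAnnotations(sim)
  te <- rep[rep$rclass != "Tandem", , drop = FALSE]
  f <- tempfile(fileext = ".out")
  writeRepeatTable(te, f)
  back <- readRepeatTable(f, "rmout", runId = "truth")
  expect_equal(back[, c("seqid", "start", "end", "rclass", "family")],
               te[, c("seqid", "start", "end", "rclass", "family")],
               ignore_attr = TRUE)
})

test_that("generic TSV writer/reader is the identity on pipeline tables", {
  d <- data.frame(seqid = c("s1", "s2"), n = c(1L, 2L),
                  x = c(0.5, 1.25), lab = c("a,b", ""),
                  stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  writeTsv(d, f)
  expect_equal(readTsv(f), d)
})
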