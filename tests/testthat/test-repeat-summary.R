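# Repeat accounting, consensus families, lineage specificity.

mkAnn <- function(seqid, start, end, rclass, family = "fam") {
  data.frame(seqid = seqid, start = start, end = end, rclass = rclass,
             family = family, run_id = "r", stringsAsFactors = FALSE)
}

test_that("overlaps of distinct classes become Multiclass, same-class merge", {
  ann <- rbind(mkAnn("s1", 0L, 100L, "LTR"), mkAnn("s1", 50L, 150L, "LINE"))
  summ <- classifyBases(ann, c(s1 = 1000))
  tab <- repeatTable(summ)
  get <- function(cl) tab$masked_bp[tab$rclass == cl]
  expect_equal(get("LTR"), 50)
  expect_equal(get("LINE"), 50)
  expect_equal(get("Multiclass"), 50)
  expect_equal(get("Total"), 150)
  expect_equal(tab$pct[tab$rclass == "Total"], 15)

  sameClass <- rbind(mkAnn("s1", 0L, 100L, "LTR"),
                     mkAnn("s1", 50L, 150L, "LTR"))
  tab2 <- repeatTable(classifyBases(sameClass, c(s1 = 1000)))
  expect_equal(tab2$masked_bp[tab2$rclass == "LTR"], 150)
  expect_equal(tab2$masked_bp[tab2$rclass == "Multiclass"], 0)

  zero <- repeatTable(classifyBases(mkAnn("s1", 1L, 1L, "LTR")[0, ],
                                    c(s1 = 1000)))
  expect_true(all(zero$masked_bp == 0))
})

test_that("bad annotations are rejected with clear errors", {
  expect_error(classifyBases(mkAnn("sX", 0L, 10L, "LTR"), c(s1 = 100)),
               "unknown scaffold")
  expect_error(classifyBases(mkAnn("s1", 0L, 200L, "LTR"), c(s1 = 100)),
               "beyond")
  expect_error(classifyBases(mkAnn("s1", 0L, 10L, "SINE"), c(s1 = 100)),
               "vocabulary")
})

test_that("accounting matches the per-base bitmap oracle", {
  set.seed(30)
  classes <- c("Tandem", "DNA", "RC", "LINE", "LTR", "Unknown")
  for (i in 1:30) {
    nScaf <- sample(1:3, 1)
    lens <- setNames(sample(2000:10000, nScaf), paste0("s", seq_len(nScaf)))
    nAnn <- sample(0:40, 1)
    ann <- if (nAnn) do.call(rbind, lapply(seq_len(nAnn), function(j) {
      sc <- sample(names(lens), 1)
      s <- sample(0:(lens[[sc]] - 200), 1)
      mkAnn(sc, s, s + sample(50:200, 1), sample(classes, 1))
    })) else mkAnn("s1", 1L, 2L, "LTR")[0, ]
    summ <- classifyBases(ann, lens)
    tab <- repeatTable(summ)
    want <- bitmapRepeatSummary(ann, as.list(lens))
    got <- setNames(tab$masked_bp, tab$rclass)[names(want)]
    expect_equal(unname(got), unname(want))
    # disjointness: class rows + Multiclass == Total == union size
    expect_equal(sum(tab$masked_bp[!tab$rclass %in% "Total"]),
                 tab$masked_bp[tab$rclass == "Total"])
  }
})

test_that("genome summary equals length-weighted per-scaffold aggregation", {
  sim <- sharedSim()
  ann <- repeatAnnotations(sim)
  asm <- assemblySeqs(sim)
  lens <- setNames(Biostrings::width(asm), names(asm))
  summ <- repeatTable(classifyBases(ann, lens))
  prof <- perScaffoldProfiles(ann, asm)
  for (cl in summ$rclass) {
    weighted <- sum(prof[[cl]] * prof$seq_len) / 100
    expect_equal(summ$masked_bp[summ$rclass == cl], weighted,
                 tolerance = 1e-9)
  }
  # profiles are sorted by scaffold length, descending
  expect_true(!is.unsorted(rev(prof$seq_len)))
})

test_that("per-scaffold profiles expose repeat-rich small scaffolds", {
  full <- mkAnn("tiny", 0L, 1000L, "LTR")
  asm <- Biostrings::DNAStringSet(c(tiny = randDna(1000),
                                    big = randDna(5000)))
  prof <- perScaffoldProfiles(full, asm)
  expect_equal(prof$LTR[prof$seqid == "tiny"], 100)
  expect_equal(prof$Total[prof$seqid == "big"], 0)

  # the synthetic genome plants a repeat-rich smallest primary scaffold
  sim <- sharedSim()
  primaries <- setdiff(names(assemblySeqs(sim)),
                       truthSet(sim)$haplotigs$seqid)
  prof2 <- perScaffoldProfiles(repeatAnnotations(sim),
                               assemblySeqs(sim)[primaries])
  smallest <- prof2$seqid[which.min(prof2$seq_len)]
  expect_gt(prof2$Total[prof2$seqid == smallest],
            max(prof2$Total[prof2$seqid != smallest]))
})

mkLib <- function(families, consensi, rclass = "LTR") {
  data.frame(family = families, rclass = rclass, consensus = consensi,
             stringsAsFactors = FALSE)
}

test_that("families recur across runs cluster with full support", {
  set.seed(31)
  base <- randDna(400)
  libs <- setNames(lapply(1:5, function(i)
    mkLib("famA", hapcull:::.mutateSeq(base, 0.01))), paste0("run", 1:5))
  fams <- consensusFamilies(libs)
  expect_equal(nrow(fams), 1L)
  expect_equal(fams$run_support, 5L)
  expect_false(fams$low_support)

  # a model found by a single run stays support 1, flagged
  libs$run3 <- rbind(libs$run3, mkLib("lonely", randDna(350), "LINE"))
  fams2 <- consensusFamilies(libs)
  lonely <- fams2[fams2$family == "lonely", ]
  expect_equal(lonely$run_support, 1L)
  expect_true(lonely$low_support)

  # disjoint models across two runs: two clusters of support 1
  d <- consensusFamilies(list(r1 = mkLib("x", randDna(300)),
                              r2 = mkLib("y", randDna(300))))
  expect_equal(d$run_support, c(1L, 1L))
  expect_error(consensusFamilies(list()), "at least one")
})

test_that("consensus clustering is invariant to run order", {
  set.seed(32)
  a <- randDna(400); b <- randDna(300)
  libs <- list(run1 = mkLib(c("fA", "fB"), c(a, b), c("LTR", "LINE")),
               run2 = mkLib("fA2", hapcull:::.mutateSeq(a, 0.02), "LTR"),
               run3 = mkLib("fB2", hapcull:::.mutateSeq(b, 0.02), "LINE"))
  f1 <- consensusFamilies(libs)
  f2 <- consensusFamilies(rev(libs))
  expect_equal(f1[order(f1$family), c("rclass", "run_support", "n_members")],
               f2[order(f2$family), c("rclass", "run_support", "n_members")],
               ignore_attr = TRUE)
  expect_true(all(f1$run_support <= 3))
})

test_that("majority class wins within a cluster; ties become Unknown", {
  set.seed(33)
  a <- randDna(400)
  libs <- list(r1 = mkLib("f", a, "LTR"),
               r2 = mkLib("f", hapcull:::.mutateSeq(a, 0.01), "LTR"),
               r3 = mkLib("f", hapcull:::.mutateSeq(a, 0.01), "LINE"))
  expect_identical(consensusFamilies(libs)$rclass, "LTR")
  tie <- consensusFamilies(libs[c("r1", "r3")])
  expect_identical(tie$rclass, "Unknown")
})

test_that("lineage-specific flags need absence from every comparator", {
  set.seed(34)
  shared <- randDna(400); private <- randDna(400)
  focal <- mkLib(c("shared", "private"), c(shared, private))
  focal$run_support <- c(5L, 1L)
  comp <- list(spA = mkLib("sharedA", hapcull:::.mutateSeq(shared, 0.05)))
  out <- lineageSpecific(focal, comp)
  expect_false(out$lineage_specific[out$family == "shared"])
  expect_identical(out$matched_in[out$family == "shared"], "spA")
  expect_true(out$lineage_specific[out$family == "private"])
  expect_match(out$evidence_caveat[out$family == "private"], "single run")
  expect_warning(all <- lineageSpecific(focal, list()), "comparator")
  expect_true(all(all$lineage_specific))
})

test_that("the planted lineage-specific families are recovered end to end", {
  sim <- sharedSim()
  fams <- consensusFamilies(sim@runLibraries)
  cons <- do.call(rbind, sim@runLibraries)
  fams$consensus <- cons$consensus[match(fams$family, cons$family)]
  out <- lineageSpecific(fams, sim@comparators)
  planted <- truthSet(sim)$lineage_specific_families
  expect_setequal(out$family[out$lineage_specific], planted)
  # the planted specific families have single-run support, as in real
  # low-confidence calls
  expect_true(all(out$run_support[out$family %in% planted] == 1))
})
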