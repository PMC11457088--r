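# Deterministic generator of toy assemblies with planted ground truth:
# haplotypic duplicate scaffolds from residual heterozygosity (optionally
# spanning an inversion), benchmark-gene placements, tandem duplicate gene
# pairs, a diverged outgroup, and repeat families.  One integer seed drives
# all randomness; identical seed means byte-identical emitted files.

.defaultRepeatSpec <- function() {
  data.frame(
    rclass   = c("LTR", "LTR", "LINE", "LINE", "DNA", "DNA", "RC",
                 "Unknown", "Tandem"),
    family   = c("Gypsy-1", "Copia-1", "R1-1", "BovB-like", "Mariner-1",
                 "Crypton-like", "Helitron-1", "Unk-1", "TandA"),
    n_copies = c(40L, 30L, 35L, 3L, 25L, 3L, 18L, 15L, 15L),
    unit_len = c(400L, 350L, 300L, 300L, 250L, 250L, 300L, 200L, 50L),
    # Tandem arrays repeat the unit this many times per copy
    n_units  = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 8L),
    # families absent from every comparator library (planted as
    # lineage-specific) are also only discovered by a single run
    lineage_specific = c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE,
                         FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Synthetic-genome configuration
#'
#' Defines the study conditions the generator emulates: an inbred-line
#' assembly in which residual heterozygosity left `nHaplotigScaffolds`
#' regions assembled twice -- once inside a primary scaffold and once as a
#' separate haplotig diverged by `haplotigDivergence` substitutions/bp,
#' optionally spanning an inversion -- plus genuine tandem gene
#' duplications, a diverged outgroup, and planted repeat families.
#'
#' @param seed Integer driving all randomness.
#' @param nScaffolds Total scaffolds emitted (primaries + haplotigs).
#' @param nHaplotigScaffolds Number of planted haplotypic duplicate
#'   scaffolds.
#' @param scaffoldLenRange Primary scaffold length range in bp.
#' @param haplotigLenRange Length range of the duplicated region in bp.
#' @param nBenchmarkGenes Single-copy benchmark genes planted (1 kb tags;
#'   benchmark semantics are emulated at the table level).
#' @param benchmarkLen Benchmark tag length in bp.
#' @param nFragmented,nMissing Benchmark genes reported Fragmented /
#'   Missing.
#' @param haplotigDivergence Substitutions/bp between haplotypes
#'   (default 0.01).
#' @param inversionProb Probability that a haplotig spans an internal
#'   inversion (default 1).
#' @param inversionFrac Fraction of the haplotig covered by the inversion.
#' @param nGenes Ordinary gene loci planted on primary scaffolds.
#' @param nDupGenePairs Gene loci that receive a tandem duplicate.
#' @param dupGeneDivergence Divergence between tandem duplicates.
#' @param geneLenRange Gene length range in bp.
#' @param outgroupDivergence Substitutions/bp to the outgroup orthologs
#'   (must exceed `haplotigDivergence`; default 0.08).
#' @param repeatSpec data.frame of planted repeat families (`rclass`,
#'   `family`, `n_copies`, `unit_len`, `n_units`, `lineage_specific`).
#' @param indelRate Optional per-bp indel rate for stress tests
#'   (default 0: substitution-only, which keeps exact-match coverage
#'   analyzable).
#' @return Validated configuration list of class `sim_config`.
#' @export
simConfig <- function(seed = 42L,
                      nScaffolds = 10L,
                      nHaplotigScaffolds = 3L,
                      scaffoldLenRange = c(70000L, 100000L),
                      haplotigLenRange = c(40000L, 50000L),
                      nBenchmarkGenes = 60L,
                      benchmarkLen = 1000L,
                      nFragmented = 2L,
                      nMissing = 2L,
                      haplotigDivergence = 0.01,
                      inversionProb = 1.0,
                      inversionFrac = 0.3,
                      nGenes = 30L,
                      nDupGenePairs = 8L,
                      dupGeneDivergence = 0.01,
                      geneLenRange = c(1200L, 2000L),
                      outgroupDivergence = 0.08,
                      repeatSpec = .defaultRepeatSpec(),
                      indelRate = 0) {
  cfg <- list(seed = as.integer(seed), nScaffolds = as.integer(nScaffolds),
              nHaplotigScaffolds = as.integer(nHaplotigScaffolds),
              scaffoldLenRange = as.integer(scaffoldLenRange),
              haplotigLenRange = as.integer(haplotigLenRange),
              nBenchmarkGenes = as.integer(nBenchmarkGenes),
              benchmarkLen = as.integer(benchmarkLen),
              nFragmented = as.integer(nFragmented),
              nMissing = as.integer(nMissing),
              haplotigDivergence = haplotigDivergence,
              inversionProb = inversionProb,
              inversionFrac = inversionFrac,
              nGenes = as.integer(nGenes),
              nDupGenePairs = as.integer(nDupGenePairs),
              dupGeneDivergence = dupGeneDivergence,
              geneLenRange = as.integer(geneLenRange),
              outgroupDivergence = outgroupDivergence,
              repeatSpec = repeatSpec, indelRate = indelRate)
  counts <- c(cfg$nScaffolds, cfg$nHaplotigScaffolds, cfg$nBenchmarkGenes,
              cfg$nFragmented, cfg$nMissing, cfg$nGenes, cfg$nDupGenePairs)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (cfg$nHaplotigScaffolds >= cfg$nScaffolds)
    stop("need at least one primary scaffold")
  if (cfg$outgroupDivergence <= cfg$haplotigDivergence)
    stop("outgroupDivergence must exceed haplotigDivergence")
  if (cfg$haplotigLenRange[2] > cfg$scaffoldLenRange[1])
    stop("haplotig region longer than its source scaffold")
  if (cfg$nGenes < cfg$nHaplotigScaffolds + cfg$nDupGenePairs)
    stop("nGenes must cover haplotig-region genes and duplicate pairs")
  if (cfg$nBenchmarkGenes < 3 * cfg$nHaplotigScaffolds +
        cfg$nFragmented + cfg$nMissing)
    stop("too few benchmark genes for the requested statuses")
  structure(cfg, class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

# fly-like background composition, about 40% GC
.randSeq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3)),
        collapse = "")
}

# substitution-only mutation; each base changes with probability d to one
# of the three other bases; optional indels for stress tests
.mutateSeq <- function(seq, d, indelRate = 0) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < d)
  if (length(hit)) {
    repl <- vapply(v[hit], function(b)
      sample(setdiff(.BASES, b), 1), character(1))
    v[hit] <- repl
  }
  if (indelRate > 0) {
    ind <- which(stats::runif(length(v)) < indelRate)
    for (i in rev(ind)) {
      if (stats::runif(1) < 0.5) v <- v[-i]
      else v <- append(v, sample(.BASES, 1), after = i)
    }
  }
  paste(v, collapse = "")
}

# non-overlapping slot allocator over [0, len) with a small guard gap
.makeAllocator <- function(len, gap = 20L) {
  occupied <- matrix(numeric(0), ncol = 2)
  list(
    reserve = function(s, e) {
      occupied <<- rbind(occupied, c(s - gap, e + gap))
      invisible(NULL)
    },
    allocate = function(width, lo = 0L, hi = len, tries = 2000L,
                        avoid = NULL) {
      if (hi - lo < width) return(NA_integer_)
      for (t in seq_len(tries)) {
        s <- floor(stats::runif(1, lo, hi - width))
        e <- s + width
        if (!is.null(avoid) && e > avoid[1] && s < avoid[2]) next
        if (!nrow(occupied) ||
            all(e <= occupied[, 1] | s >= occupied[, 2])) {
          occupied <<- rbind(occupied, c(s - gap, e + gap))
          return(as.integer(s))
        }
      }
      NA_integer_
    })
}

.alloc <- function(allocator, width, lo, hi, what, avoid = NULL) {
  s <- allocator$allocate(width, lo, hi, avoid = avoid)
  if (is.na(s)) stop("could not place ", what, "; scaffold too crowded")
  s
}

#' Generate a synthetic genome with planted truth
#'
#' Builds the toy study system described by [simConfig()]: seeded random
#' primary scaffolds; haplotig scaffolds copied from a region of a primary
#' and mutated at the haplotype divergence, with an internal inversion with
#' probability `inversionProb`; benchmark tags whose full-table status
#' follows the planted geometry (tags inside duplicated regions are
#' Duplicated on both copies); tandem duplicate gene pairs at low mutual
#' divergence; an outgroup carrying single orthologous copies; and repeat
#' families written into the sequence and recorded as annotations.
#'
#' @param config A [simConfig()].
#' @return A [SyntheticGenome-class].
#' @export
simulateGenome <- function(config = simConfig()) {
  stopifnot(inherits(config, "sim_config"))
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(config$seed)

  nHap <- config$nHaplotigScaffolds
  nPrim <- config$nScaffolds - nHap
  primIds <- sprintf("scaffold_%02d", seq_len(nPrim))
  hapIds <- if (nHap) sprintf("scaffold_%02d", nPrim + seq_len(nHap))
            else character(0)

  # primary scaffold lengths, descending so small scaffolds sort last
  primLens <- sort(as.integer(round(stats::runif(
    nPrim, config$scaffoldLenRange[1], config$scaffoldLenRange[2]))),
    decreasing = TRUE)
  primSeq <- lapply(primLens, .randSeq)
  names(primSeq) <- primIds
  alloc <- lapply(primLens, .makeAllocator)
  names(alloc) <- primIds

  # haplotig source regions live on the first nHap primaries
  hapSrc <- data.frame(seqid = hapIds,
                       partner = primIds[seq_len(nHap)],
                       src_start = rep(NA_integer_, nHap),
                       src_end = rep(NA_integer_, nHap),
                       inverted = logical(nHap),
                       inv_start = rep(NA_integer_, nHap),
                       inv_end = rep(NA_integer_, nHap),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nHap)) {
    L <- primLens[i]
    regLen <- as.integer(round(stats::runif(1, config$haplotigLenRange[1],
                                            config$haplotigLenRange[2])))
    s <- as.integer(floor(stats::runif(1, 0, L - regLen)))
    hapSrc$src_start[i] <- s
    hapSrc$src_end[i] <- s + regLen
  }
  # placement weights follow the length still free for planting, i.e.
  # excluding each partner scaffold's duplicated region
  freeLens <- primLens
  for (i in seq_len(nHap)) {
    j <- match(hapSrc$partner[i], primIds)
    freeLens[j] <- freeLens[j] - (hapSrc$src_end[i] - hapSrc$src_start[i])
  }
  srcOf <- function(p) {
    i <- match(p, hapSrc$partner)
    if (is.na(i)) NULL else c(hapSrc$src_start[i], hapSrc$src_end[i])
  }

  # ---- gene loci -----------------------------------------------------
  # placed before the benchmark tags so the narrow pre-inversion window of
  # each duplicated region is still free
  nG <- config$nGenes
  geneIds <- sprintf("gene%03d", seq_len(nG))
  genes <- data.frame(gene_id = geneIds, seqid = NA_character_,
                      start = NA_integer_, len = NA_integer_,
                      strand = sample(c("+", "-"), nG, replace = TRUE),
                      role = "single", stringsAsFactors = FALSE)
  glen <- function() as.integer(round(stats::runif(
    1, config$geneLenRange[1], config$geneLenRange[2])))
  # one gene inside each duplicated region (outside the inversion zone,
  # which starts at 55% of the region)
  for (i in seq_len(nHap)) {
    p <- hapSrc$partner[i]
    L <- glen()
    s <- .alloc(alloc[[p]], L, hapSrc$src_start[i] + 200L,
                hapSrc$src_start[i] +
                  as.integer(0.45 * (hapSrc$src_end[i] -
                                       hapSrc$src_start[i])),
                "haplotig-region gene")
    genes$seqid[i] <- p; genes$start[i] <- s; genes$len[i] <- L
    genes$role[i] <- "in_dup_region"
  }
  dupIdx <- nHap + seq_len(config$nDupGenePairs)
  genes$role[dupIdx] <- "tandem_parent"
  for (g in seq((nHap + 1L), nG)) {
    p <- sample(primIds, 1, prob = freeLens)
    L <- glen()
    s <- .alloc(alloc[[p]], L, 0L, primLens[match(p, primIds)],
                "gene outside duplicated regions", avoid = srcOf(p))
    genes$seqid[g] <- p; genes$start[g] <- s; genes$len[g] <- L
  }
  # tandem duplicates sit on the same scaffold as their parent, same strand
  dupCopies <- do.call(rbind, lapply(dupIdx, function(g) {
    p <- genes$seqid[g]; L <- genes$len[g]
    s <- .alloc(alloc[[p]], L, 0L, primLens[match(p, primIds)],
                "tandem duplicate", avoid = srcOf(p))
    data.frame(gene_id = paste0(genes$gene_id[g], "d"), seqid = p,
               start = s, len = L, strand = genes$strand[g],
               role = "tandem_copy", parent = genes$gene_id[g],
               stringsAsFactors = FALSE)
  }))

  # ---- benchmark tags ------------------------------------------------
  nB <- config$nBenchmarkGenes
  buscoIds <- sprintf("busco%04d", seq_len(nB))
  tagLen <- config$benchmarkLen
  tags <- data.frame(busco_id = buscoIds, seqid = NA_character_,
                     start = NA_integer_, status = "Complete",
                     stringsAsFactors = FALSE)
  k <- 0L
  for (i in seq_len(nHap)) {           # guarantee >= 3 duplicated tags/region
    for (j in 1:3) {
      k <- k + 1L
      p <- hapSrc$partner[i]
      s <- .alloc(alloc[[p]], tagLen, hapSrc$src_start[i] + 200L,
                  hapSrc$src_end[i] - 200L, "benchmark tag")
      tags$seqid[k] <- p; tags$start[k] <- s
    }
  }
  nMiss <- config$nMissing
  missingIdx <- if (nMiss) (nB - nMiss + 1L):nB else integer(0)
  for (k2 in if (k < nB) seq(k + 1L, nB) else integer(0)) {
    if (k2 %in% missingIdx) { tags$status[k2] <- "Missing"; next }
    p <- sample(primIds, 1, prob = freeLens)
    # remaining tags go outside duplicated regions
    s <- .alloc(alloc[[p]], tagLen, 0L, primLens[match(p, primIds)],
                "benchmark tag outside regions", avoid = srcOf(p))
    tags$seqid[k2] <- p; tags$start[k2] <- s
  }
  fragIdx <- if (config$nFragmented)
    setdiff(seq((k + 1L), nB), missingIdx)[seq_len(config$nFragmented)]
  else integer(0)
  tags$status[fragIdx] <- "Fragmented"
  inRegion <- function(row) {
    reg <- srcOf(tags$seqid[row])
    !is.null(reg) && !is.na(tags$start[row]) &&
      tags$start[row] >= reg[1] && tags$start[row] + tagLen <= reg[2]
  }
  dupTag <- vapply(seq_len(nB), inRegion, logical(1)) &
    tags$status == "Complete"
  tags$status[dupTag] <- "Duplicated"

  # ---- repeats -------------------------------------------------------
  spec <- config$repeatSpec
  consensi <- setNames(vapply(spec$unit_len, .randSeq, character(1)),
                       spec$family)
  # the smallest primary scaffold is repeat-enriched, as intermediate-size
  # scaffolds of real assemblies often are
  wts <- freeLens
  wts[nPrim] <- wts[nPrim] * 2
  repAnn <- list()
  for (fi in seq_len(nrow(spec))) {
    fam <- spec$family[fi]
    insLen <- spec$unit_len[fi] * spec$n_units[fi]
    for (cp in seq_len(spec$n_copies[fi])) {
      p <- sample(primIds, 1, prob = wts)
      s <- alloc[[p]]$allocate(insLen, avoid = srcOf(p))
      if (is.na(s)) stop("could not place repeat copy for ", fam)
      unit <- .mutateSeq(consensi[[fam]], 0.02)
      ins <- paste(rep(unit, spec$n_units[fi]), collapse = "")
      substr(primSeq[[p]], s + 1L, s + insLen) <- ins
      repAnn[[length(repAnn) + 1L]] <- data.frame(
        seqid = p, start = s, end = s + insLen,
        rclass = spec$rclass[fi], family = fam, run_id = "truth",
        stringsAsFactors = FALSE)
    }
  }
  repAnn <- do.call(rbind, repAnn)
  # designed multiclass overlaps: a tandem annotation over the tail of the
  # first two LTR copies (as tandem-repeat detectors produce in practice)
  ltr <- which(repAnn$rclass == "LTR")[1:2]
  ltr <- ltr[!is.na(ltr)]
  if (length(ltr)) {
    extra <- data.frame(
      seqid = repAnn$seqid[ltr],
      start = repAnn$end[ltr] - 40L,
      end = repAnn$end[ltr] + 80L,
      rclass = "Tandem", family = "trf-overlap", run_id = "truth",
      stringsAsFactors = FALSE)
    extra$end <- pmin(extra$end, primLens[match(extra$seqid, primIds)])
    repAnn <- rbind(repAnn, extra)
  }

  # ---- haplotig sequences -------------------------------------------
  hapSeq <- list()
  for (i in seq_len(nHap)) {
    src <- substr(primSeq[[hapSrc$partner[i]]], hapSrc$src_start[i] + 1L,
                  hapSrc$src_end[i])
    mut <- .mutateSeq(src, config$haplotigDivergence, config$indelRate)
    regLen <- nchar(mut)
    if (stats::runif(1) < config$inversionProb) {
      ivLen <- as.integer(round(config$inversionFrac * regLen))
      ivS <- as.integer(round(0.55 * regLen))          # second half
      ivE <- min(ivS + ivLen, regLen)
      inv <- .revcomp(substr(mut, ivS + 1L, ivE))
      mut <- paste0(substr(mut, 1, ivS), inv,
                    substr(mut, ivE + 1L, regLen))
      hapSrc$inverted[i] <- TRUE
      hapSrc$inv_start[i] <- ivS
      hapSrc$inv_end[i] <- ivE
    }
    hapSeq[[hapIds[i]]] <- mut
  }

  assembly <- Biostrings::DNAStringSet(c(unlist(primSeq), unlist(hapSeq)))
  S4Vectors::mcols(assembly) <- S4Vectors::DataFrame(
    description = rep("", length(assembly)))

  # ---- benchmark full table -----------------------------------------
  buscoRows <- list()
  mapThroughHap <- function(i, s0, e0) {
    # map a [s0,e0) interval of the source region into haplotig coords
    ivS <- hapSrc$inv_start[i]; ivE <- hapSrc$inv_end[i]
    if (hapSrc$inverted[i] && !is.na(ivS) && s0 >= ivS && e0 <= ivE)
      c(ivS + ivE - e0, ivS + ivE - s0)
    else c(s0, e0)
  }
  for (r in seq_len(nB)) {
    st <- tags$status[r]
    if (st == "Missing") {
      buscoRows[[length(buscoRows) + 1L]] <- data.frame(
        busco_id = tags$busco_id[r], status = "Missing", seqid = "",
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        score = NA_real_, length = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    s <- tags$start[r]; e <- s + tagLen
    score <- round(1500 + stats::runif(1, -100, 100), 1)
    buscoRows[[length(buscoRows) + 1L]] <- data.frame(
      busco_id = tags$busco_id[r], status = st, seqid = tags$seqid[r],
      start = s + 1L, end = e, strand = "+", score = score,
      length = tagLen, stringsAsFactors = FALSE)
    if (st == "Duplicated") {
      i <- match(tags$seqid[r], hapSrc$partner)
      rel <- mapThroughHap(i, s - hapSrc$src_start[i],
                           e - hapSrc$src_start[i])
      buscoRows[[length(buscoRows) + 1L]] <- data.frame(
        busco_id = tags$busco_id[r], status = "Duplicated",
        seqid = hapSrc$seqid[i], start = rel[1] + 1L, end = rel[2],
        strand = "+", score = score, length = tagLen,
        stringsAsFactors = FALSE)
    }
  }
  busco <- do.call(rbind, buscoRows)

  # ---- tandem duplicate gene sequences ------------------------------
  for (r in seq_len(nrow(dupCopies))) {
    g <- match(dupCopies$parent[r], genes$gene_id)
    src <- substr(primSeq[[genes$seqid[g]]], genes$start[g] + 1L,
                  genes$start[g] + genes$len[g])
    mut <- .mutateSeq(src, config$dupGeneDivergence)
    p <- dupCopies$seqid[r]
    substr(primSeq[[p]], dupCopies$start[r] + 1L,
           dupCopies$start[r] + dupCopies$len[r]) <- mut
  }
  # refresh assembly after in-place edits
  assembly <- Biostrings::DNAStringSet(c(unlist(primSeq), unlist(hapSeq)))
  S4Vectors::mcols(assembly) <- S4Vectors::DataFrame(
    description = rep("", length(assembly)))

  # ---- annotation ----------------------------------------------------
  allGenes <- rbind(
    cbind(genes, parent = NA_character_)[,
      c("gene_id", "seqid", "start", "len", "strand", "role", "parent")],
    dupCopies)
  # haplotig copies of duplicated-region genes
  hapGeneRows <- list()
  for (i in seq_len(nHap)) {
    g <- i  # gene i sits in region i by construction
    rel <- c(genes$start[g], genes$start[g] + genes$len[g]) -
      hapSrc$src_start[i]
    hapGeneRows[[i]] <- data.frame(
      gene_id = paste0(genes$gene_id[g], "h"), seqid = hapIds[i],
      start = rel[1], len = genes$len[g], strand = genes$strand[g],
      role = "haplotig_copy", parent = genes$gene_id[g],
      stringsAsFactors = FALSE)
  }
  if (nHap) allGenes <- rbind(allGenes, do.call(rbind, hapGeneRows))

  featRows <- list()
  for (r in seq_len(nrow(allGenes))) {
    gid <- allGenes$gene_id[r]; sc <- allGenes$seqid[r]
    s1 <- allGenes$start[r] + 1L
    e1 <- allGenes$start[r] + allGenes$len[r]
    st <- allGenes$strand[r]
    tid <- paste0(gid, ".t1")
    ex2s <- s1 + 600L
    featRows[[length(featRows) + 1L]] <- data.frame(
      seqid = sc,
      type = c("gene", "mRNA", "exon", "exon", "CDS"),
      start = c(s1, s1, s1, ex2s, s1 + 50L),
      end = c(e1, e1, s1 + 400L, e1, s1 + 400L),
      strand = st,
      ID = c(gid, tid, paste0(tid, ".e1"), paste0(tid, ".e2"),
             paste0(tid, ".c1")),
      Parent = c(NA, gid, tid, tid, tid),
      stringsAsFactors = FALSE)
  }
  feat <- do.call(rbind, featRows)
  attrs <- ifelse(is.na(feat$Parent), paste0("ID=", feat$ID),
                  paste0("ID=", feat$ID, ";Parent=", feat$Parent))
  annotation <- GenomicRanges::GRanges(
    seqnames = feat$seqid,
    ranges = IRanges::IRanges(start = feat$start, end = feat$end),
    strand = feat$strand,
    source = "hapcull_sim", type = feat$type, score = ".", phase = ".",
    ID = feat$ID, Parent = feat$Parent, attributes = attrs)

  # ---- outgroup ------------------------------------------------------
  focalRegions <- vapply(seq_len(nG), function(g) {
    s <- substr(primSeq[[genes$seqid[g]]], genes$start[g] + 1L,
                genes$start[g] + genes$len[g])
    if (genes$strand[g] == "-") .revcomp(s) else s
  }, character(1))
  ogParts <- character(nG)
  ogStrand <- sample(c("+", "-"), nG, replace = TRUE)
  for (g in seq_len(nG))
    ogParts[g] <- .mutateSeq(focalRegions[g], config$outgroupDivergence)
  spacers <- vapply(seq_len(nG + 1L),
                    function(i) .randSeq(sample(300:800, 1)), character(1))
  ogSeq <- spacers[1]
  ogRows <- list()
  for (g in seq_len(nG)) {
    embed <- if (ogStrand[g] == "-") .revcomp(ogParts[g]) else ogParts[g]
    s1 <- nchar(ogSeq) + 1L
    ogSeq <- paste0(ogSeq, embed, spacers[g + 1L])
    ogid <- paste0("og_", genes$gene_id[g])
    ogRows[[g]] <- data.frame(
      seqid = "og_scaffold_1", type = "gene", start = s1,
      end = s1 + nchar(embed) - 1L, strand = ogStrand[g], ID = ogid,
      stringsAsFactors = FALSE)
  }
  ogFeat <- do.call(rbind, ogRows)
  outgroup <- Biostrings::DNAStringSet(c(og_scaffold_1 = ogSeq))
  S4Vectors::mcols(outgroup) <- S4Vectors::DataFrame(description = "")
  outgroupAnnotation <- GenomicRanges::GRanges(
    seqnames = ogFeat$seqid,
    ranges = IRanges::IRanges(start = ogFeat$start, end = ogFeat$end),
    strand = ogFeat$strand,
    source = "hapcull_sim", type = "gene", score = ".", phase = ".",
    ID = ogFeat$ID, Parent = NA_character_,
    attributes = paste0("ID=", ogFeat$ID))

  # ---- run libraries and comparator libraries -----------------------
  teSpec <- spec[spec$rclass != "Tandem", , drop = FALSE]
  runIds <- sprintf("run%d", 1:5)
  singleRun <- setNames(sample(runIds, nrow(teSpec), replace = TRUE),
                        teSpec$family)
  runLibraries <- setNames(lapply(runIds, function(r) {
    keep <- !teSpec$lineage_specific | singleRun[teSpec$family] == r
    d <- teSpec[keep, c("family", "rclass"), drop = FALSE]
    d$consensus <- vapply(d$family, function(f)
      .mutateSeq(consensi[[f]], 0.01), character(1))
    rownames(d) <- NULL
    d
  }), runIds)
  comparators <- setNames(lapply(1:2, function(ci) {
    keep <- !teSpec$lineage_specific
    d <- teSpec[keep, c("family", "rclass"), drop = FALSE]
    d$consensus <- vapply(d$family, function(f)
      .mutateSeq(consensi[[f]], 0.05), character(1))
    rownames(d) <- NULL
    d
  }), c("comparatorA", "comparatorB"))

  truth <- list(
    haplotigs = hapSrc,
    dup_gene_pairs = data.frame(
      gene_a = genes$gene_id[dupIdx],
      gene_b = paste0(genes$gene_id[dupIdx], "d"),
      stringsAsFactors = FALSE),
    repeat_truth = repAnn,
    benchmark_truth = stats::aggregate(
      seqid ~ busco_id + status,
      data = transform(busco, seqid = ifelse(nzchar(seqid), seqid, "-")),
      FUN = function(v) paste(sort(unique(v)), collapse = ","))[,
        c("busco_id", "status", "seqid")],
    lineage_specific_families = teSpec$family[teSpec$lineage_specific])

  new("SyntheticGenome", assembly = assembly, annotation = annotation,
      busco = busco, outgroup = outgroup,
      outgroupAnnotation = outgroupAnnotation, repeats = repAnn,
      runLibraries = runLibraries, comparators = comparators,
      truth = truth, config = unclass(config))
}

#' Write a synthetic genome to disk
#'
#' Emits every artifact through the package's own writers so the files
#' parse back through `formats_io` unchanged: assembly and outgroup FASTA,
#' GFF3 annotations, benchmark full table, RepeatMasker-style `.out` and
#' TRF-style `.dat` repeat tables, per-run library TSVs, and truth TSVs.
#' Identical seeds give byte-identical files.
#'
#' @param sim A [SyntheticGenome-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeSyntheticGenome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeAssembly(assemblySeqs(sim), p("assembly.fa"))
  writeAnnotation(annotationFeatures(sim), p("annotation.gff3"))
  writeBuscoTable(buscoTable(sim), p("busco_full_table.tsv"))
  writeAssembly(outgroupSeqs(sim), p("outgroup.fa"))
  writeAnnotation(outgroupFeatures(sim), p("outgroup.gff3"))
  rep <- repeatAnnotations(sim)
  writeRepeatTable(rep[rep$rclass != "Tandem", , drop = FALSE],
                   p("repeats_rm.out"))
  trf <- rep[rep$rclass == "Tandem", , drop = FALSE]
  trfLines <- unlist(lapply(split(trf, trf$seqid), function(d) {
    c(paste("Sequence:", d$seqid[1]),
      sprintf("%d %d %d %.1f", d$start + 1L, d$end, 50L,
              (d$end - d$start) / 50))
  }), use.names = FALSE)
  writeLines(if (length(trfLines)) trfLines else character(0),
             p("repeats_trf.dat"))
  for (r in names(sim@runLibraries))
    writeTsv(sim@runLibraries[[r]], p(paste0("runlib_", r, ".tsv")))
  for (s in names(sim@comparators))
    writeTsv(sim@comparators[[s]], p(paste0("comparator_", s, ".tsv")))
  tr <- truthSet(sim)
  writeTsv(tr$haplotigs, p("truth_haplotigs.tsv"))
  writeTsv(tr$dup_gene_pairs, p("truth_dup_gene_pairs.tsv"))
  writeTsv(tr$repeat_truth, p("truth_repeats.tsv"))
  writeTsv(tr$benchmark_truth, p("truth_benchmark.tsv"))
  out <- c(assembly = p("assembly.fa"), annotation = p("annotation.gff3"),
           busco = p("busco_full_table.tsv"), outgroup = p("outgroup.fa"),
           outgroup_annotation = p("outgroup.gff3"),
           rmout = p("repeats_rm.out"), trf = p("repeats_trf.dat"))
  invisible(out)
}

#' Emit a similarity-hit table for a synthetic genome
#'
#' Scores focal gene regions against each other and against the outgroup
#' regions with the internal surrogate scorer ([scoreRegions()]), producing
#' the 12-column tabular hit dialect consumed by [bestScores()]. Planted
#' duplicate pairs score above their outgroup hits by construction (their
#' mutual divergence is well below the focal-outgroup divergence).
#'
#' @param focalRegions Named `DNAStringSet` from [extractGeneRegions()].
#' @param outgroupRegions Named `DNAStringSet` of outgroup gene regions.
#' @param params [anchorParams()] for the surrogate scorer.
#' @return Hit data.frame in the layout of [readHits()].
#' @export
emitHits <- function(focalRegions, outgroupRegions,
                     params = anchorParams(minMatch = 50, maxGap = 1000)) {
  rbind(scoreRegions(focalRegions, focalRegions, params),
        scoreRegions(focalRegions, outgroupRegions, params))
}
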