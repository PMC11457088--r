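# S4 result containers. Tabular currencies (alignment blocks, similarity
# hits, repeat annotations, BUSCO tables) stay plain data.frames; the S4
# layer holds the derived results users carry between pipeline stages.

#' Assembly contiguity and composition metrics
#'
#' Holds total length, scaffold count, Nx/Lx contiguity statistics and GC
#' content of an assembly. Nx is the scaffold length at which the descending
#' cumulative length first reaches x% of the total; Lx is the number of
#' scaffolds up to and including that one.
#'
#' @slot totalLength total assembly span in bp.
#' @slot nScaffolds number of scaffolds.
#' @slot nx named numeric, Nx in bp per x (names are the x percentages).
#' @slot lx named integer, Lx counts per x.
#' @slot gcPct GC percentage over unambiguous bases.
#' @aliases AssemblyMetrics
#' @exportClass AssemblyMetrics
setClass("AssemblyMetrics",
         representation(totalLength = "numeric", nScaffolds = "integer",
                        nx = "numeric", lx = "integer", gcPct = "numeric"))

setValidity("AssemblyMetrics", function(object) {
  msg <- character(0)
  if (!identical(names(object@nx), names(object@lx)))
    msg <- c(msg, "nx and lx must be indexed by the same x values")
  if (length(object@gcPct) && (object@gcPct < 0 || object@gcPct > 100))
    msg <- c(msg, "gcPct must lie in [0, 100]")
  xs <- as.numeric(names(object@nx))
  if (length(xs) > 1) {
    o <- order(xs)
    if (is.unsorted(rev(object@nx[o])))
      msg <- c(msg, "nx must be non-increasing in x")
    if (is.unsorted(object@lx[o]))
      msg <- c(msg, "lx must be non-decreasing in x")
  }
  if (any(object@lx > object@nScaffolds))
    msg <- c(msg, "lx cannot exceed the scaffold count")
  if (length(msg)) msg else TRUE
})

#' Annotation completeness metrics
#'
#' Gene, protein-coding gene and exon counts plus transcript length summaries
#' computed from a gene/mRNA/exon/CDS feature hierarchy.
#'
#' @slot nGenes number of gene features.
#' @slot nProteinCoding genes with at least one CDS-bearing mRNA.
#' @slot nExons number of exon features.
#' @slot medianTranscriptLen median mRNA genomic span in bp.
#' @slot longestTranscriptLen longest mRNA genomic span in bp.
#' @aliases AnnotationMetrics
#' @exportClass AnnotationMetrics
setClass("AnnotationMetrics",
         representation(nGenes = "integer", nProteinCoding = "integer",
                        nExons = "integer", medianTranscriptLen = "numeric",
                        longestTranscriptLen = "numeric"))

setValidity("AnnotationMetrics", function(object) {
  msg <- character(0)
  if (object@nProteinCoding > object@nGenes)
    msg <- c(msg, "protein-coding genes cannot outnumber genes")
  if (object@nGenes > 0 && object@longestTranscriptLen <
      object@medianTranscriptLen)
    msg <- c(msg, "longest transcript shorter than the median")
  if (length(msg)) msg else TRUE
})

#' Duplicate-scaffold screening result
#'
#' Per-scaffold benchmark-gene duplication profiles together with the
#' remove/keep decision for every scaffold and the coverage threshold used.
#' The `decisions` table has one row per scaffold with columns `seqid`,
#' `seq_len`, `n_busco`, `n_dup`, `pct_dup`, `coverage`, `status`
#' (`remove`, `keep` or `candidate_unresolved`), `partner` and `reason`.
#'
#' @slot profiles data.frame of per-scaffold duplication profiles.
#' @slot decisions data.frame of per-scaffold decisions.
#' @slot threshold coverage fraction above which a candidate counts as fully
#'   duplicated.
#' @aliases DedupResult
#' @exportClass DedupResult
setClass("DedupResult",
         representation(profiles = "data.frame", decisions = "data.frame",
                        threshold = "numeric"))

setValidity("DedupResult", function(object) {
  msg <- character(0)
  need <- c("seqid", "status", "coverage", "partner")
  if (!all(need %in% names(object@decisions)))
    msg <- c(msg, "decisions table lacks required columns")
  else {
    bad <- object@decisions$status == "remove" &
      (object@decisions$coverage < object@threshold |
         !nzchar(object@decisions$partner))
    if (any(bad))
      msg <- c(msg, "removals require coverage >= threshold and a partner")
  }
  if (object@threshold <= 0 || object@threshold > 1)
    msg <- c(msg, "threshold must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Repeat-content summary
#'
#' Per-class masked base counts and percentages with disjoint accounting:
#' bases annotated with two or more distinct repeat classes are counted only
#' in the `Multiclass` row, and `Total` is the size of the union of all
#' repeat intervals.
#'
#' @slot table data.frame with columns `rclass`, `masked_bp`, `pct`, one row
#'   per class plus `Multiclass` and `Total`.
#' @slot genomeBp genome size used as the percentage denominator.
#' @aliases RepeatSummary
#' @exportClass RepeatSummary
setClass("RepeatSummary",
         representation(table = "data.frame", genomeBp = "numeric"))

setValidity("RepeatSummary", function(object) {
  msg <- character(0)
  tab <- object@table
  if (!all(c("rclass", "masked_bp", "pct") %in% names(tab)))
    msg <- c(msg, "summary table needs rclass/masked_bp/pct columns")
  else {
    if (any(tab$masked_bp < 0)) msg <- c(msg, "negative masked_bp")
    tot <- tab$masked_bp[tab$rclass == "Total"]
    parts <- sum(tab$masked_bp[tab$rclass != "Total"])
    if (length(tot) == 1 && abs(parts - tot) > 1e-6)
      msg <- c(msg, "class rows (incl. Multiclass) must sum to Total")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic genome with planted ground truth
#'
#' The output of [simulateGenome()]: a toy assembly carrying planted
#' haplotypic duplicate scaffolds, benchmark-gene placements, tandem
#' duplicate gene pairs, repeat families, a diverged outgroup, and the truth
#' tables needed to score every downstream stage.
#'
#' @slot assembly named `DNAStringSet` of scaffolds.
#' @slot annotation `GRanges` gene/mRNA/exon/CDS features.
#' @slot busco data.frame in the benchmark full-table layout.
#' @slot outgroup named `DNAStringSet` of outgroup scaffolds.
#' @slot outgroupAnnotation `GRanges` outgroup gene features.
#' @slot repeats data.frame of repeat annotations (internal coordinates).
#' @slot runLibraries list of per-run repeat family libraries.
#' @slot comparators list of comparator-species family libraries.
#' @slot truth list of truth tables (`haplotigs`, `dup_gene_pairs`,
#'   `repeat_truth`, `benchmark_truth`).
#' @slot config the [simConfig()] list that produced the object.
#' @aliases SyntheticGenome
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
         representation(assembly = "DNAStringSet", annotation = "GRanges",
                        busco = "data.frame", outgroup = "DNAStringSet",
                        outgroupAnnotation = "GRanges",
                        repeats = "data.frame", runLibraries = "list",
                        comparators = "list", truth = "list",
                        config = "list"))

setValidity("SyntheticGenome", function(object) {
  msg <- character(0)
  ids <- names(object@assembly)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "assembly scaffold ids must be unique and non-empty")
  hap <- object@truth$haplotigs
  if (!is.null(hap) && !all(hap$seqid %in% ids))
    msg <- c(msg, "every planted haplotig id must exist in the assembly")
  if (length(msg)) msg else TRUE
})

#' End-to-end pipeline report
#'
#' Consolidated result of [runPipeline()]: pre- and post-deduplication
#' assembly metrics, the scaffold screening result, duplicate-gene counts,
#' the repeat summary, and a provenance block (seed, parameters, stage
#' outputs).
#'
#' @slot preMetrics [AssemblyMetrics-class] before deduplication.
#' @slot postMetrics [AssemblyMetrics-class] after deduplication.
#' @slot dedup [DedupResult-class].
#' @slot geneDup list with elements `pairs` (data.frame), `n_genes`,
#'   `n_dup_genes`, `fraction_pct`.
#' @slot repeats [RepeatSummary-class] of the kept assembly.
#' @slot provenance list of seed, thresholds and file manifest.
#' @aliases RunReport
#' @exportClass RunReport
setClass("RunReport",
         representation(preMetrics = "AssemblyMetrics",
                        postMetrics = "AssemblyMetrics",
                        dedup = "DedupResult",
                        geneDup = "list",
                        repeats = "RepeatSummary",
                        provenance = "list"))
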