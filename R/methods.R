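# Accessor and show methods.

#' @rdname AssemblyMetrics-class
#' @export
setMethod("totalLength", "AssemblyMetrics", function(x, ...) x@totalLength)

#' @rdname AssemblyMetrics-class
#' @export
setMethod("nScaffolds", "AssemblyMetrics", function(x, ...) x@nScaffolds)

#' @rdname AssemblyMetrics-class
#' @export
setMethod("nx", "AssemblyMetrics", function(x, ...) x@nx)

#' @rdname AssemblyMetrics-class
#' @export
setMethod("lx", "AssemblyMetrics", function(x, ...) x@lx)

#' @rdname AssemblyMetrics-class
#' @export
setMethod("gcPct", "AssemblyMetrics", function(x, ...) x@gcPct)

setMethod("show", "AssemblyMetrics", function(object) {
  cat("AssemblyMetrics:", object@nScaffolds, "scaffolds,",
      format(object@totalLength, big.mark = ","), "bp, GC",
      sprintf("%.2f%%\n", object@gcPct))
  for (x in names(object@nx))
    cat(sprintf("  N%s = %s bp  L%s = %d\n", x,
                format(object@nx[[x]], big.mark = ","), x, object@lx[[x]]))
})

setMethod("show", "AnnotationMetrics", function(object) {
  cat("AnnotationMetrics:", object@nGenes, "genes (",
      object@nProteinCoding, "protein-coding ),", object@nExons, "exons\n")
  cat(sprintf("  transcript length: median %.0f bp, longest %.0f bp\n",
              object@medianTranscriptLen, object@longestTranscriptLen))
})

#' @rdname DedupResult-class
#' @export
setMethod("decisions", "DedupResult", function(x, ...) x@decisions)

#' @rdname DedupResult-class
#' @export
setMethod("dupProfiles", "DedupResult", function(x, ...) x@profiles)

#' @rdname DedupResult-class
#' @export
setMethod("removedScaffolds", "DedupResult", function(x, ...)
  x@decisions$seqid[x@decisions$status == "remove"])

#' @rdname DedupResult-class
#' @export
setMethod("keptScaffolds", "DedupResult", function(x, ...)
  x@decisions$seqid[x@decisions$status != "remove"])

#' @rdname DedupResult-class
#' @export
setMethod("coverageThreshold", "DedupResult", function(x, ...) x@threshold)

setMethod("show", "DedupResult", function(object) {
  d <- object@decisions
  cat("DedupResult:", nrow(d), "scaffolds screened at coverage threshold",
      object@threshold, "\n")
  cat("  candidates:", sum(d$n_dup >= 1),
      " removed:", sum(d$status == "remove"),
      " unresolved:", sum(d$status == "candidate_unresolved"), "\n")
  rm <- d$seqid[d$status == "remove"]
  if (length(rm))
    cat("  removed:", paste(rm, collapse = ", "), "\n")
})

#' @rdname RepeatSummary-class
#' @export
setMethod("repeatTable", "RepeatSummary", function(x, ...) x@table)

#' @rdname RepeatSummary-class
#' @export
setMethod("genomeSize", "RepeatSummary", function(x, ...) x@genomeBp)

setMethod("show", "RepeatSummary", function(object) {
  tot <- object@table[object@table$rclass == "Total", ]
  cat("RepeatSummary over", format(object@genomeBp, big.mark = ","),
      "bp genome:", sprintf("%.3f%% repetitive\n", tot$pct))
  shown <- object@table[object@table$masked_bp > 0 &
                          object@table$rclass != "Total", ]
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  %-10s %10d bp  %7.3f%%\n", shown$rclass[i],
                shown$masked_bp[i], shown$pct[i]))
})

#' @rdname SyntheticGenome-class
#' @export
setMethod("assemblySeqs", "SyntheticGenome", function(x, ...) x@assembly)

#' @rdname SyntheticGenome-class
#' @export
setMethod("annotationFeatures", "SyntheticGenome", function(x, ...)
  x@annotation)

#' @rdname SyntheticGenome-class
#' @export
setMethod("buscoTable", "SyntheticGenome", function(x, ...) x@busco)

#' @rdname SyntheticGenome-class
#' @export
setMethod("outgroupSeqs", "SyntheticGenome", function(x, ...) x@outgroup)

#' @rdname SyntheticGenome-class
#' @export
setMethod("outgroupFeatures", "SyntheticGenome", function(x, ...)
  x@outgroupAnnotation)

#' @rdname SyntheticGenome-class
#' @export
setMethod("repeatAnnotations", "SyntheticGenome", function(x, ...) x@repeats)

#' @rdname SyntheticGenome-class
#' @export
setMethod("truthSet", "SyntheticGenome", function(x, ...) x@truth)

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:", length(object@assembly), "scaffolds,",
      format(sum(Biostrings::width(object@assembly)), big.mark = ","),
      "bp (seed", object@config$seed, ")\n")
  cat("  planted haplotigs:",
      paste(object@truth$haplotigs$seqid, collapse = ", "), "\n")
  cat("  planted duplicate gene pairs:",
      nrow(object@truth$dup_gene_pairs), "\n")
  cat("  planted repeat intervals:", nrow(object@truth$repeat_truth), "\n")
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport (seed", object@provenance$seed, ")\n")
  cat("-- pre-dedup --\n"); show(object@preMetrics)
  cat("-- post-dedup --\n"); show(object@postMetrics)
  show(object@dedup)
  gd <- object@geneDup
  cat(sprintf("Duplicate genes: %d of %d (%.2f%%), %d pairs\n",
              gd$n_dup_genes, gd$n_genes, gd$fraction_pct, nrow(gd$pairs)))
  show(object@repeats)
})
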