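# Accessor generics. Slot access from user code goes through these.

#' @rdname AssemblyMetrics-class
#' @param x An object.
#' @param ... Unused.
#' @export
setGeneric("totalLength", function(x, ...) standardGeneric("totalLength"))

#' @rdname AssemblyMetrics-class
#' @export
setGeneric("nScaffolds", function(x, ...) standardGeneric("nScaffolds"))

#' @rdname AssemblyMetrics-class
#' @export
setGeneric("nx", function(x, ...) standardGeneric("nx"))

#' @rdname AssemblyMetrics-class
#' @export
setGeneric("lx", function(x, ...) standardGeneric("lx"))

#' @rdname AssemblyMetrics-class
#' @export
setGeneric("gcPct", function(x, ...) standardGeneric("gcPct"))

#' @rdname DedupResult-class
#' @param x An object.
#' @param ... Unused.
#' @export
setGeneric("decisions", function(x, ...) standardGeneric("decisions"))

#' @rdname DedupResult-class
#' @export
setGeneric("dupProfiles", function(x, ...) standardGeneric("dupProfiles"))

#' @rdname DedupResult-class
#' @export
setGeneric("removedScaffolds", function(x, ...)
  standardGeneric("removedScaffolds"))

#' @rdname DedupResult-class
#' @export
setGeneric("keptScaffolds", function(x, ...) standardGeneric("keptScaffolds"))

#' @rdname DedupResult-class
#' @export
setGeneric("coverageThreshold", function(x, ...)
  standardGeneric("coverageThreshold"))

#' @rdname RepeatSummary-class
#' @param x An object.
#' @param ... Unused.
#' @export
setGeneric("repeatTable", function(x, ...) standardGeneric("repeatTable"))

#' @rdname RepeatSummary-class
#' @export
setGeneric("genomeSize", function(x, ...) standardGeneric("genomeSize"))

#' @rdname SyntheticGenome-class
#' @param x An object.
#' @param ... Unused.
#' @export
setGeneric("assemblySeqs", function(x, ...) standardGeneric("assemblySeqs"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("annotationFeatures", function(x, ...)
  standardGeneric("annotationFeatures"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("buscoTable", function(x, ...) standardGeneric("buscoTable"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("outgroupSeqs", function(x, ...) standardGeneric("outgroupSeqs"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("outgroupFeatures", function(x, ...)
  standardGeneric("outgroupFeatures"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("repeatAnnotations", function(x, ...)
  standardGeneric("repeatAnnotations"))

#' @rdname SyntheticGenome-class
#' @export
setGeneric("truthSet", function(x, ...) standardGeneric("truthSet"))
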