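# Contiguity, composition and annotation statistics.

#' Nx / Lx contiguity statistics
#'
#' Nx is the length of the scaffold at which the descending cumulative
#' length first reaches x% of the assembly total; Lx is the number of
#' scaffolds up to and including that one. Ties at the boundary length are
#' resolved by a stable descending sort, so Lx counts through the first
#' scaffold reaching the threshold.
#'
#' @param lengths Scaffold lengths in bp (all >= 1).
#' @param x Percentage in (0, 100].
#' @return list with elements `nx` (bp) and `lx` (count).
#' @examples
#' computeNxLx(c(100, 50, 30, 20), 50) # N50 = 100, L50 = 1
#' @export
computeNxLx <- function(lengths, x) {
  if (!length(lengths) || any(lengths < 1))
    stop("lengths must be non-empty and all >= 1")
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x > 100)
    stop("x must lie in (0, 100]")
  sl <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(as.numeric(sl))
  i <- which(cs >= x / 100 * cs[length(cs)])[1]
  list(nx = sl[i], lx = i)
}

#' GC percentage of an assembly
#'
#' 100 * (G + C) / (A + C + G + T) over all records; ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param records A `DNAStringSet` (or character vector of sequences).
#' @return GC percentage.
#' @export
gcPercent <- function(records) {
  if (!length(records)) stop("no sequences supplied")
  if (!is(records, "DNAStringSet"))
    records <- Biostrings::DNAStringSet(records)
  freq <- colSums(Biostrings::alphabetFrequency(records,
                                                baseOnly = TRUE))
  denom <- sum(freq[c("A", "C", "G", "T")])
  if (denom == 0) stop("assembly contains no unambiguous bases")
  100 * sum(freq[c("G", "C")]) / denom
}

#' Cumulative scaffold-length curve
#'
#' Descending-length cumulative fractions used for contiguity plots.
#' Scaffolds shorter than `minLen` are excluded and fractions are taken
#' over the filtered total, so the curve ends at 1.
#'
#' @param lengths Scaffold lengths in bp.
#' @param minLen Minimum scaffold length retained (default 1000).
#' @return data.frame with columns `scaffold_rank` and
#'   `cumulative_fraction`; zero rows when everything is filtered.
#' @export
lengthCdf <- function(lengths, minLen = 1000) {
  keep <- sort(lengths[lengths >= minLen], decreasing = TRUE)
  if (!length(keep))
    return(data.frame(scaffold_rank = integer(),
                      cumulative_fraction = numeric()))
  data.frame(scaffold_rank = seq_along(keep),
             cumulative_fraction = cumsum(as.numeric(keep)) / sum(keep))
}

#' Assembly metrics
#'
#' Computes total length, scaffold count, Nx/Lx at the requested
#' percentages and GC content in one pass.
#'
#' @param assembly A named `DNAStringSet`.
#' @param x Percentages for Nx/Lx (default 50 and 90).
#' @return An [AssemblyMetrics-class] object.
#' @export
assemblyMetrics <- function(assembly, x = c(50, 90)) {
  lens <- Biostrings::width(assembly)
  nxlx <- lapply(x, function(p) computeNxLx(lens, p))
  new("AssemblyMetrics",
      totalLength = sum(as.numeric(lens)),
      nScaffolds = length(assembly),
      nx = setNames(vapply(nxlx, `[[`, numeric(1), "nx"), as.character(x)),
      lx = setNames(vapply(nxlx, function(v) as.integer(v$lx), integer(1)),
                    as.character(x)),
      gcPct = gcPercent(assembly))
}

#' Annotation statistics
#'
#' Gene/exon counts and transcript length summaries from a
#' gene/mRNA/exon/CDS hierarchy. A gene counts as protein-coding when at
#' least one of its mRNA children has a CDS child. Transcript length is the
#' genomic span of the mRNA feature (end - start + 1), not summed exon
#' length; the median of an even transcript count is the mean of the two
#' central values. mRNAs whose Parent is not a gene feature trigger a
#' warning and count toward transcripts only.
#'
#' @param features A `GRanges` annotation as returned by
#'   [readAnnotation()].
#' @return An [AnnotationMetrics-class] object.
#' @export
annotationStats <- function(features) {
  mc <- S4Vectors::mcols(features)
  type <- mc$type
  geneIds <- mc$ID[type == "gene"]
  isMrna <- type == "mRNA"
  mrnaParents <- mc$Parent[isMrna]
  orphan <- !is.na(mrnaParents) & !(mrnaParents %in% geneIds) |
    is.na(mrnaParents)
  if (any(orphan))
    warning(sum(orphan), " mRNA feature(s) without a gene parent; ",
            "counted toward transcripts only")
  cdsParents <- unique(mc$Parent[type == "CDS"])
  codingMrna <- mc$ID[isMrna][mc$ID[isMrna] %in% cdsParents]
  codingGenes <- unique(mc$Parent[isMrna][mc$ID[isMrna] %in% codingMrna])
  codingGenes <- codingGenes[codingGenes %in% geneIds]
  spans <- BiocGenerics::width(features[isMrna])
  new("AnnotationMetrics",
      nGenes = sum(type == "gene"),
      nProteinCoding = length(codingGenes),
      nExons = sum(type == "exon"),
      medianTranscriptLen = if (length(spans)) stats::median(spans)
                            else NA_real_,
      longestTranscriptLen = if (length(spans)) max(spans) else NA_real_)
}
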