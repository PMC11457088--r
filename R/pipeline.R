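# Orchestrated end-to-end run: simulate/load -> stats -> profile -> align
# -> decide -> split -> re-stats -> gene duplicates -> repeats, with a
# consolidated report and a manifest of stage outputs.

#' Pipeline configuration
#'
#' Inputs are either a [simConfig()] (the pipeline then generates its own
#' inputs and reads them back through the format readers) or paths to an
#' assembly FASTA, annotation GFF3, benchmark full table, outgroup FASTA +
#' GFF3 and optional precomputed alignments (PAF/coords) and similarity
#' hits. Validation reports every problem, not just the first.
#'
#' @param outDir Run directory (created).
#' @param sim Optional [simConfig()].
#' @param fasta,gff,busco,outgroupFasta,outgroupGff Input paths (ignored
#'   when `sim` is given).
#' @param alignments Optional alignment file; bypasses the internal
#'   aligner.
#' @param alignmentDialect `"paf"` or `"coords"`.
#' @param hits Optional similarity-hit file; bypasses the surrogate
#'   scorer.
#' @param coverageThreshold Coverage fraction for scaffold removal.
#' @param dedupAnchor [anchorParams()] for candidate-partner alignment.
#'   The default match floor (30 bp) suits haplotype pairs at about 1\%
#'   divergence, where maximal exact stretches average some 100 bp (see
#'   the methods vignette).
#' @param geneDupMode `"reciprocal"` or `"mutual"`.
#' @param geneAnchor [anchorParams()] for the surrogate gene scorer.
#' @param familyIdentityMin,familyCoverageMin Repeat family match rule.
#' @param seed Seed recorded in the provenance block for externally
#'   supplied inputs; when `sim` is given the simulation seed is recorded
#'   instead.
#' @return Validated configuration list of class `run_config`.
#' @export
pipelineConfig <- function(outDir,
                           sim = NULL,
                           fasta = NULL, gff = NULL, busco = NULL,
                           outgroupFasta = NULL, outgroupGff = NULL,
                           alignments = NULL,
                           alignmentDialect = c("paf", "coords"),
                           hits = NULL,
                           coverageThreshold = 0.95,
                           dedupAnchor = anchorParams(minMatch = 30,
                                                      maxGap = 2000),
                           geneDupMode = c("reciprocal", "mutual"),
                           geneAnchor = anchorParams(minMatch = 50,
                                                     maxGap = 1000),
                           familyIdentityMin = 0.8,
                           familyCoverageMin = 0.8,
                           seed = NULL) {
  problems <- character(0)
  if (is.null(sim)) {
    need <- list(fasta = fasta, gff = gff, busco = busco,
                 outgroupFasta = outgroupFasta, outgroupGff = outgroupGff)
    for (f in names(need)) {
      if (is.null(need[[f]]))
        problems <- c(problems, paste0("missing input field: ", f))
      else if (!file.exists(need[[f]]))
        problems <- c(problems, paste0(f, " file not found: ", need[[f]]))
    }
    for (f in c("alignments", "hits")) {
      v <- get(f)
      if (!is.null(v) && !file.exists(v))
        problems <- c(problems, paste0(f, " file not found: ", v))
    }
  } else if (!inherits(sim, "sim_config")) {
    problems <- c(problems, "sim must be a simConfig() object")
  }
  if (coverageThreshold <= 0 || coverageThreshold > 1)
    problems <- c(problems, "coverageThreshold must lie in (0, 1]")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(list(outDir = outDir, sim = sim, fasta = fasta, gff = gff,
                 busco = busco, outgroupFasta = outgroupFasta,
                 outgroupGff = outgroupGff, alignments = alignments,
                 alignmentDialect = match.arg(alignmentDialect),
                 hits = hits, coverageThreshold = coverageThreshold,
                 dedupAnchor = dedupAnchor,
                 geneDupMode = match.arg(geneDupMode),
                 geneAnchor = geneAnchor,
                 familyIdentityMin = familyIdentityMin,
                 familyCoverageMin = familyCoverageMin,
                 seed = if (!is.null(sim)) sim$seed else seed),
            class = "run_config")
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log(sprintf("stage %-10s done in %.1fs", name,
              proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full curation pipeline
#'
#' Executes simulate/load, pre-deduplication statistics, duplicate-scaffold
#' screening, assembly/annotation splitting, post-deduplication statistics,
#' duplicate-gene classification and repeat accounting, writing every stage
#' output as a headered TSV (plus FASTA/GFF3) under the run directory with
#' a manifest. A failed stage aborts with the stage name; outputs of
#' earlier stages are preserved. Identical configuration and inputs give an
#' identical report.
#'
#' @param config A [pipelineConfig()] (or a [simConfig()], shorthand for a
#'   simulated run into `outDir`).
#' @param outDir Run directory when `config` is a [simConfig()].
#' @param quiet Suppress stage logging.
#' @return A [RunReport-class].
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
  if (inherits(config, "sim_config")) {
    if (is.null(outDir)) stop("outDir is required")
    config <- pipelineConfig(outDir = outDir, sim = config)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outDir, "run.log")
  log <- function(msg) {
    if (!quiet) message(msg)
    cat(msg, "\n", file = logFile, append = TRUE)
  }
  manifest <- list()
  emit <- function(name, path) manifest[[name]] <<- path

  # ---- inputs --------------------------------------------------------
  inputs <- .stage("inputs", log, {
    if (!is.null(config$sim)) {
      simDir <- file.path(config$outDir, "sim")
      sim <- simulateGenome(config$sim)
      paths <- writeSyntheticGenome(sim, simDir)
      list(assembly = readAssembly(paths[["assembly"]]),
           features = readAnnotation(paths[["annotation"]]),
           busco = readBuscoTable(paths[["busco"]]),
           outgroup = readAssembly(paths[["outgroup"]]),
           outgroupFeatures = readAnnotation(paths[["outgroup_annotation"]]),
           repeats = rbind(readRepeatTable(paths[["rmout"]], "rmout",
                                           runId = "masking"),
                           readRepeatTable(paths[["trf"]], "trf",
                                           runId = "trf")),
           runLibraries = sim@runLibraries,
           comparators = sim@comparators,
           truth = truthSet(sim), sim = sim)
    } else {
      list(assembly = readAssembly(config$fasta),
           features = readAnnotation(config$gff),
           busco = readBuscoTable(config$busco),
           outgroup = readAssembly(config$outgroupFasta),
           outgroupFeatures = readAnnotation(config$outgroupGff),
           repeats = NULL, runLibraries = NULL, comparators = NULL,
           truth = NULL, sim = NULL)
    }
  })

  preMetrics <- .stage("stats", log, {
    m <- assemblyMetrics(inputs$assembly)
    writeTsv(data.frame(
      metric = c("total_length_bp", "n_scaffolds", "n50_bp", "l50",
                 "n90_bp", "l90", "gc_pct"),
      value = c(totalLength(m), nScaffolds(m), nx(m)[["50"]],
                lx(m)[["50"]], nx(m)[["90"]], lx(m)[["90"]],
                round(gcPct(m), 4))),
      file.path(config$outDir, "stats_pre.tsv"))
    emit("stats_pre", "stats_pre.tsv")
    m
  })

  blocks <- NULL
  if (!is.null(config$alignments))
    blocks <- .stage("align", log,
                     readAlignments(config$alignments,
                                    config$alignmentDialect))

  dedup <- .stage("dedup", log, {
    d <- screenDuplicates(inputs$assembly, inputs$busco, blocks = blocks,
                          params = config$dedupAnchor,
                          threshold = config$coverageThreshold)
    writeTsv(decisions(d), file.path(config$outDir, "dedup_decisions.tsv"))
    emit("dedup_decisions", "dedup_decisions.tsv")
    d
  })

  parts <- .stage("split", log, {
    p <- splitAssembly(inputs$assembly, inputs$features, dedup)
    writeAssembly(p$kept, file.path(config$outDir, "kept.fa"))
    writeAnnotation(p$keptFeatures, file.path(config$outDir, "kept.gff3"))
    if (length(p$removed)) {
      writeAssembly(p$removed, file.path(config$outDir, "removed.fa"))
      writeAnnotation(p$removedFeatures,
                      file.path(config$outDir, "removed.gff3"))
    }
    emit("kept_fasta", "kept.fa"); emit("kept_gff", "kept.gff3")
    log(sprintf("  kept %d scaffolds (%d features); removed %d (%d)",
                length(p$kept), length(p$keptFeatures),
                length(p$removed), length(p$removedFeatures)))
    p
  })

  postMetrics <- .stage("restats", log, {
    m <- assemblyMetrics(parts$kept)
    keptBusco <- updateBuscoStatus(inputs$busco, names(parts$kept))
    writeBuscoTable(keptBusco,
                    file.path(config$outDir, "busco_post_dedup.tsv"))
    emit("busco_post", "busco_post_dedup.tsv")
    attr(m, "busco") <- keptBusco
    m
  })

  geneDup <- .stage("genedup", log, {
    focal <- extractGeneRegions(parts$kept, parts$keptFeatures)
    og <- extractGeneRegions(inputs$outgroup, inputs$outgroupFeatures)
    hits <- if (!is.null(config$hits)) readHits(config$hits)
            else emitHits(focal, og, config$geneAnchor)
    tab <- bestScores(hits, names(focal), names(og))
    pairs <- classifyDuplicates(tab, mode = config$geneDupMode)
    rep <- dupGeneReport(pairs, names(focal))
    writeTsv(data.frame(gene_id = rep$genes),
             file.path(config$outDir, "dup_genes.tsv"))
    writeTsv(pairs, file.path(config$outDir, "dup_gene_pairs.tsv"))
    emit("dup_genes", "dup_genes.tsv")
    emit("dup_gene_pairs", "dup_gene_pairs.tsv")
    rep
  })

  repeats <- .stage("repeats", log, {
    ann <- inputs$repeats
    if (is.null(ann)) {
      summ <- classifyBases(
        data.frame(seqid = character(), start = integer(),
                   end = integer(), rclass = character(),
                   family = character(), run_id = character()),
        setNames(Biostrings::width(parts$kept), names(parts$kept)))
    } else {
      keptAnn <- ann[ann$seqid %in% names(parts$kept), , drop = FALSE]
      summ <- classifyBases(keptAnn, setNames(
        Biostrings::width(parts$kept), names(parts$kept)))
      writeTsv(perScaffoldProfiles(keptAnn, parts$kept),
               file.path(config$outDir, "repeats_per_scaffold.tsv"))
      emit("repeats_per_scaffold", "repeats_per_scaffold.tsv")
    }
    writeTsv(repeatTable(summ),
             file.path(config$outDir, "repeats_summary.tsv"))
    emit("repeats_summary", "repeats_summary.tsv")
    if (!is.null(inputs$runLibraries)) {
      fams <- consensusFamilies(inputs$runLibraries,
                                config$familyIdentityMin,
                                config$familyCoverageMin)
      cons <- do.call(rbind, lapply(names(inputs$runLibraries),
                                    function(r) inputs$runLibraries[[r]]))
      fams$consensus <- cons$consensus[match(fams$family, cons$family)]
      fams <- lineageSpecific(fams, inputs$comparators,
                              config$familyIdentityMin,
                              config$familyCoverageMin)
      writeTsv(fams[, setdiff(names(fams), "consensus")],
               file.path(config$outDir, "repeat_families.tsv"))
      emit("repeat_families", "repeat_families.tsv")
      attr(summ, "families") <- fams
    }
    summ
  })

  writeTsv(data.frame(output = names(manifest),
                      path = unlist(manifest)),
           file.path(config$outDir, "manifest.tsv"))

  report <- new("RunReport", preMetrics = preMetrics,
                postMetrics = postMetrics, dedup = dedup,
                geneDup = geneDup, repeats = repeats,
                provenance = list(
                  seed = config$seed,
                  coverage_threshold = config$coverageThreshold,
                  dedup_anchor = unclass(config$dedupAnchor),
                  gene_dup_mode = config$geneDupMode,
                  manifest = unlist(manifest),
                  truth = inputs$truth))
  .writeReportMd(report, file.path(config$outDir, "report.md"))
  report
}

.writeReportMd <- function(report, path) {
  d <- decisions(report@dedup)
  gd <- report@geneDup
  lines <- c(
    "# Curation run report", "",
    "## Assembly metrics",
    sprintf("| metric | pre-dedup | post-dedup |"),
    "|---|---|---|",
    sprintf("| total length (bp) | %.0f | %.0f |",
            totalLength(report@preMetrics), totalLength(report@postMetrics)),
    sprintf("| scaffolds | %d | %d |",
            nScaffolds(report@preMetrics), nScaffolds(report@postMetrics)),
    sprintf("| N50 (bp) | %.0f | %.0f |",
            nx(report@preMetrics)[["50"]], nx(report@postMetrics)[["50"]]),
    sprintf("| L50 | %d | %d |",
            lx(report@preMetrics)[["50"]], lx(report@postMetrics)[["50"]]),
    sprintf("| GC%% | %.2f | %.2f |",
            gcPct(report@preMetrics), gcPct(report@postMetrics)),
    "",
    "## Duplicate scaffolds",
    sprintf("- candidates: %d", sum(d$n_dup >= 1)),
    sprintf("- removed: %d (%s)", sum(d$status == "remove"),
            paste(d$seqid[d$status == "remove"], collapse = ", ")),
    "",
    "## Duplicate genes",
    sprintf("- %d of %d genes (%.2f%%) in %d pairs", gd$n_dup_genes,
            gd$n_genes, gd$fraction_pct, nrow(gd$pairs)),
    "",
    "## Repeat content",
    sprintf("- total repetitive: %.3f%% of %.0f bp",
            repeatTable(report@repeats)$pct[
              repeatTable(report@repeats)$rclass == "Total"],
            genomeSize(report@repeats)))
  writeLines(lines, path)
  invisible(path)
}

#' Compare assemblies side by side
#'
#' Builds the wide one-column-per-assembly layout used for multi-species
#' contiguity/repeat tables.
#'
#' @param entries Named list; each element is a list with an element
#'   `metrics` ([AssemblyMetrics-class]) and optionally `repeats`
#'   ([RepeatSummary-class]).
#' @return data.frame with one row per statistic and one column per
#'   assembly.
#' @export
compareAssemblies <- function(entries) {
  if (!length(entries)) stop("at least one assembly is required")
  if (is.null(names(entries))) names(entries) <- paste0("asm", seq_along(entries))
  cols <- lapply(entries, function(e) {
    m <- e$metrics
    v <- c("Total length (bp)" = totalLength(m),
           "Scaffolds" = nScaffolds(m),
           "N50 (bp)" = unname(nx(m)[["50"]]),
           "L50" = unname(lx(m)[["50"]]),
           "GC%" = round(gcPct(m), 2))
    if (!is.null(e$repeats)) {
      rt <- repeatTable(e$repeats)
      rv <- setNames(round(rt$pct, 3), paste0("Repeat ", rt$rclass, " (%)"))
      v <- c(v, rv)
    }
    v
  })
  rows <- unique(unlist(lapply(cols, names)))
  out <- data.frame(statistic = rows, stringsAsFactors = FALSE)
  for (nm in names(cols))
    out[[nm]] <- unname(cols[[nm]][rows])
  out
}
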