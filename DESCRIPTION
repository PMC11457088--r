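Package: hapcull
Title: Benchmark-Gene-Guided Duplicate Scaffold Removal and Post-Assembly Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly curation toolkit for draft genome assemblies that
    retain both haplotypes of heterozygous regions as separate scaffolds.
    Profiles per-scaffold duplication of single-copy benchmark genes
    (BUSCO-style full tables), verifies candidate haplotypic scaffolds by
    maximal-exact-match anchor alignment and merged coverage, and splits the
    assembly and annotation into kept and removed sets. Also classifies
    residual duplicate gene pairs by reciprocal best similarity against an
    outgroup, builds multi-run repeat-library consensus with per-base
    multiclass repeat-content accounting, computes assembly and annotation
    statistics (N50/L50/L90, GC content, transcript metrics), and ships a
    deterministic synthetic-genome generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
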