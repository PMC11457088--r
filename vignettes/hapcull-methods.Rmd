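---
title: "Curating haplotype-duplicated assemblies with hapcull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating haplotype-duplicated assemblies with hapcull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapcull)
```

## The problem

Long-read assemblies of inbred but not fully homozygous lines often
represent some genomic regions twice: once inside a chromosome-scale
scaffold and once as a separate, slightly diverged scaffold carrying the
alternate haplotype (a *haplotig*). Segregating inversions aggravate this,
because they suppress recombination, preserve heterozygosity and encourage
the assembler to split the two haplotypes. The symptoms are characteristic:
benchmark single-copy orthologs (BUSCO-style) reported as Duplicated, an
inflated total assembly length, and whole-genome self-alignments in which a
small scaffold aligns end-to-end into a larger one.

hapcull implements the curation steps around this artifact as a reusable,
tested pipeline:

1. **Duplicate-scaffold removal** — profile benchmark-gene duplication per
   scaffold, select candidate scaffolds carrying at least one Duplicated
   benchmark gene, verify full duplication by anchor-alignment coverage
   against the scaffolds holding the alternate copies, and split the
   assembly and annotation into kept and removed sets.
2. **Duplicate-gene labeling** — extract strand-oriented gene regions,
   score them against each other and against an outgroup genome, and pair
   genes that are reciprocal best matches scoring strictly above anything
   in the outgroup.
3. **Repeat accounting** — cluster repeat families found by several
   independent discovery runs, flag lineage-specific families, and account
   repeat content per class with per-base multiclass resolution.
4. **Evaluation statistics** — N50/L50/L90, GC content, cumulative length
   curves and annotation summaries.

All stages are exercised end to end on synthetic genomes with planted
ground truth.

## The duplicate-scaffold decision

For every scaffold the package tallies `n_busco` benchmark placements and
`n_dup` placements with status Duplicated, sorts scaffolds by
`pct_dup = 100 * n_dup / n_busco`, and treats every scaffold with
`n_dup >= 1` as a candidate. Fragmented placements count toward the
denominator by default (benchmark *content* is read broadly); a switch
restricts the denominator to Complete + Duplicated.

A candidate is *fully duplicated* when the union of its alignments to its
partner scaffolds (the scaffolds holding alternate copies of its
Duplicated benchmark genes) covers at least a fraction `threshold` of its
length. The threshold defaults to **0.95**: "complete alignment" is a
judgment call in manual curation, and 0.95 leaves room for diverged
scaffold ends while still requiring essentially end-to-end coverage. It is
configurable.

Two safeguards shape the decision:

* **Keeper designation.** Within a mutually covered pair, the longer
  scaffold is kept (ties: more Complete benchmark placements, then the
  lexicographically smaller id). Candidates are processed in keeper order
  and partner alignments are pooled over partners that are still kept, so
  both members of a pair can never be removed — also along chains of
  partners.
* **All-or-nothing removal.** Scaffolds are removed whole; there is no
  trimming. Zero-benchmark scaffolds are never candidates and are always
  kept.

## The anchor aligner and its match floor

When no external alignment table (PAF or `show-coords -T`) is supplied,
coverage comes from the package's own nucmer-style aligner: maximal exact
matches are seeded on shared 21-mers, extended in both directions,
de-duplicated per diagonal, and found on both strands (`N` matches
nothing, including another `N`). Same-strand collinear matches whose ref-
and qry-side gaps are both at most `maxGap` are chained into blocks, and
coverage is the union of block spans. The compiled core is validated
against a quadratic-time brute-force enumeration in the test suite.

The exact-match floor must match the divergence of the sequences being
compared. Under a uniform substitution model at divergence $d$, maximal
exact tracts have mean length $1/d$ and a tract of length $\ge m$ occurs at
density $d\,e^{-md}$ per bp. At the $d = 0.01$ typical of residual
heterozygosity, tracts $\ge 500$ bp arise only about once per 15 kb —
a 500 bp floor *cannot* recover near-complete coverage of a haplotig, no
matter the chaining gap. With a 30 bp floor, tracts are dense
(one per ~270 bp), about three quarters of all bases lie inside kept
tracts, and chaining with `maxGap = 2000` bridges the remainder; the
expected uncovered sequence is ~130 bp per haplotig end or inversion
boundary, far inside the 5% slack of the 0.95 threshold. The pipeline
therefore defaults to `anchorParams(minMatch = 30, maxGap = 2000)` for
candidate-partner alignment, while `anchorParams()` itself keeps the 500 bp
default conventional for cross-assembly comparisons of real genomes (with
1000 bp the usual choice at greater evolutionary distance).

## Duplicate-gene labeling

Gene regions (the genomic span of each `gene` feature, reverse-complemented
on the minus strand) are scored all-against-all and against the outgroup's
gene regions. A pair (A, B) is labeled duplicate when A's best-scoring
focal match is B, B's is A, and both scores are **strictly** greater than
the respective best outgroup score; score ties with the outgroup never
qualify, and bit-score ties for the best focal subject break by longer
alignment, then subject id. This reciprocal-best reading is the default; a
`mutual` mode relaxes reciprocity to "both directions beat the outgroup",
in which case one gene may join several pairs. Duplicate *genes* (pair
members) are counted separately from pairs, and the reported fraction is
`100 * n_dup_genes / n_genes`.

Scores may come from an external 12-column tabular hit file. Without one,
the package scores regions with its internal anchor-match surrogate
(2 × matched bp, reported in the same 12-column layout). The surrogate is
deliberately simple and is intended for synthetic data and testing: its
scores are comparable within one run but are not BLAST bit scores. No
e-value or coverage floor is applied before scoring.

## Repeat accounting

Repeat annotations (RepeatMasker-style `.out`, TRF-style `.dat`) are
normalized to half-open 0-based intervals and an eleven-class vocabulary
(Tandem, Simple, Satellite, DNA, RC, LINE, LTR, rRNA, snRNA, tRNA,
Unknown); unmappable class strings become Unknown with a warning, never
dropped. Accounting is per-base and disjoint: overlapping annotations of
one class are merged first, a base annotated with two or more distinct
classes counts only toward **Multiclass**, and **Total** is the size of the
union — so the class rows plus Multiclass always sum to Total. Tandem-
repeat intervals take part in the same accounting, so a TRF interval
overlapping a transposon contributes to Multiclass. Genome-wide tables
equal the length-weighted aggregation of per-scaffold profiles, which is
asserted in the tests against an independent per-base bitmap.

Because de novo repeat discovery is stochastic, family libraries from
several independent runs are clustered into consensus families by
reciprocal sequence match — by default ≥ 80% identity over ≥ 80% of the
shorter consensus (a declared convention, both thresholds configurable;
local alignment via `Biostrings::pairwiseAlignment`). The cluster class is
the majority class (ties → Unknown) and `run_support` counts distinct
runs. Families with zero matches in every comparator library are flagged
lineage-specific; when such a family has single-run support the flag
carries an explicit caveat, since its evidence is one observation. Final
masking uses the union of runs with consensus family labels.

## The synthetic study system

`simulateGenome()` emits the full input bundle — assembly, GFF3 annotation,
benchmark full table, outgroup FASTA + GFF3, repeat tables, per-run family
libraries, comparator libraries — plus truth tables, deterministically from
one integer seed (identical seed, byte-identical files).

Default conditions (chosen once, a priori, as a desk-scale portrait of the
artifact model):

* 10 scaffolds of which 3 are haplotigs: each haplotig copies a 40–50 kb
  region of a 70–100 kb primary scaffold, mutated at **1%** substitutions/bp
  (residual-heterozygosity scale), and spans an internal inversion covering
  30% of its length with probability 1. Region sizes follow from the
  coverage model above: expected end/boundary losses (~6 × 130 bp) must sit
  well below 5% of the haplotig length.
* 60 benchmark genes as 1 kb unique tags; benchmark semantics are emulated
  at the table level (statuses follow the planted geometry), not by
  sequence search. At least three tags per duplicated region guarantee the
  haplotig is discoverable; a configurable few are Fragmented or Missing.
* 30 gene loci (gene/mRNA/exon/CDS hierarchies) with 8 tandem duplicate
  pairs at 1% mutual divergence; every locus has a single ortholog in the
  outgroup at **8%** divergence, safely above the within-pair divergence so
  planted pairs out-score their outgroup matches by construction.
* 9 planted repeat families across LTR/LINE/DNA/RC/Unknown/Tandem
  (~60 kb total) with fly-like 40% GC background; two families are planted
  lineage-specific with single-run support, mirroring how low-confidence
  species-specific families present in practice. The smallest primary
  scaffold is repeat-enriched. Two designed overlaps between a Tandem
  annotation and an LTR tail exercise the Multiclass row.
* Substitution-only mutation by default, which keeps exact-match coverage
  analyzable; an indel-rate option exists for stress tests.

What the generator does *not* emulate — and hence what green tests do not
show about real data: read-level errors and coverage biases, gaps and
scaffolding breaks, gene structure with real codon content, repeat
landscapes with nested and decayed copies, segmental duplications that are
real rather than artifactual, and BUSCO's actual HMM-based search. The
pipeline's behavior on those phenomena must be judged on real assemblies.

## Numerical choices and degenerate inputs

* Coordinates are half-open 0-based internally; 1-based inclusive only at
  the GFF3/BUSCO/coords boundaries, converted exactly once in `formats_io`
  and covered by round-trip tests.
* Nx/Lx: the scaffold at which the descending cumulative sum first reaches
  x% of the total; ties resolved by a stable descending sort. Transcript
  length is the mRNA genomic span (not summed exons); the median of an even
  count is the mean of the two central values. GC excludes ambiguity codes
  from numerator and denominator.
* Chained-block identity is matched bp over the larger of the two spans;
  merged coverage is invariant to block order and duplication.
* Empty inputs: an empty candidate list, a scaffold without benchmarks, an
  annotation-free scaffold and an empty removal set are all legal and
  covered by tests; a candidate without partner alignments is reported
  `candidate_unresolved`, never silently kept or removed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
the default ~0.7 Mb synthetic genome for the end-to-end stages, 1,000
random length vectors for the contiguity oracle, 200 sequence pairs up to
2 kb for the aligner oracle, 1,000 random score tables (up to 50 genes) for
the classifier oracle, and 100 random annotation sets over ≤ 160 kb
genomes for the repeat-accounting oracle. These sizes were chosen so each
oracle explores its input space densely while a full run stays comfortable
on a laptop.

## Known limitations

* The internal aligner reports all maximal matches (maxmatch-like
  semantics); no uniqueness filtering is attempted, and identity of chained
  blocks is exact-match bookkeeping, not base-level alignment identity.
* The surrogate gene scorer is not a BLAST replacement; with real data,
  supply a tabular hit file.
* Removal is whole-scaffold only; intra-scaffold (regional) duplications
  are detected indirectly at best and never resolved.
* Reciprocal-best pairing cannot represent duplicate families of three or
  more members; the `mutual` mode can, at the cost of overlapping pairs.
* With `mum`-style uniqueness or base-level identity required, or for
  assemblies beyond tens of Mb, a dedicated whole-genome aligner should
  replace the internal one via `--alignments`.
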