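# hapcull

Post-assembly curation for draft genome assemblies that carry both
haplotypes of heterozygous regions as separate scaffolds.

Inbred-line assemblies are rarely fully homozygous. Where heterozygosity
survives — especially under segregating inversions — long-read assemblers
tend to emit the two haplotypes of a region as *separate scaffolds*: a
chromosome-scale scaffold plus a smaller, slightly diverged duplicate
(a haplotig). The result is an inflated assembly with benchmark
single-copy orthologs (BUSCO-style) reported as Duplicated and duplicate
gene models in the annotation. hapcull is for assembly curators who need
to find and remove these artifactual scaffolds, label residual duplicate
genes, and report honest assembly, annotation and repeat statistics.

## What it computes

**Duplicate-scaffold removal.** Scaffolds are profiled by benchmark-gene
content; every scaffold with at least one Duplicated benchmark gene is a
candidate. Each candidate is aligned against its *partners* (the scaffolds
carrying the alternate copies of its duplicated benchmark genes) with a
nucmer-style maximal-exact-match aligner; matches are chained and the
merged coverage of the candidate computed. A candidate whose covered
fraction reaches a threshold (default 0.95) — and which is not the
designated keeper of its pair (keep the longer; ties by Complete
benchmark count, then id) — is removed, and the assembly and annotation
are split into kept and removed sets.

**Duplicate-gene labeling.** Strand-oriented gene regions are scored
all-against-all and against an outgroup genome. Genes A and B form a
duplicate pair when they are reciprocal best matches and both scores are
strictly greater than either gene's best outgroup score:

    pair(A, B)  iff  best(A) = B, best(B) = A,
                     S(A,B) > max_o S(A,o)  and  S(B,A) > max_o S(B,o)

**Repeat accounting.** Repeat annotations are accounted per base and
disjointly: bases under one repeat class count toward that class, bases
under two or more distinct classes count toward *Multiclass* only, and
*Total* is the union — so rows always sum to Total. Families from
independent discovery runs are clustered by reciprocal sequence match
(≥80% identity over ≥80% of the shorter consensus, configurable), with
run support counted and lineage-specific families flagged against
comparator libraries.

**Assembly/annotation statistics.** N50/L50/L90 (descending
cumulative-sum definition), GC content excluding ambiguity codes,
cumulative scaffold-length curves, gene/exon counts and transcript-span
summaries.

**Synthetic study system.** A deterministic generator plants haplotigs
(optionally spanning an inversion), benchmark-gene placements, tandem
duplicate gene pairs, a diverged outgroup and repeat families, and emits
every input format plus truth tables — the test bed for everything above.

## Worked example

```r
library(hapcull)

sim <- simulateGenome(simConfig(seed = 42))
sim
#> SyntheticGenome: 10 scaffolds, 778,514 bp (seed 42 )
#>   planted haplotigs: scaffold_08, scaffold_09, scaffold_10
#>   planted duplicate gene pairs: 8
#>   planted repeat intervals: 186

assemblyMetrics(assemblySeqs(sim))
#> AssemblyMetrics: 10 scaffolds, 778,514 bp, GC 40.09%
#>   N50 = 89,252 bp  L50 = 5
#>   N90 = 47,523 bp  L90 = 9

res <- screenDuplicates(assemblySeqs(sim), buscoTable(sim),
                        params = anchorParams(minMatch = 30, maxGap = 2000))
res
#> DedupResult: 10 scaffolds screened at coverage threshold 0.95
#>   candidates: 6  removed: 3  unresolved: 0
#>   removed: scaffold_09, scaffold_08, scaffold_10
```

Six scaffolds carry duplicated benchmark genes (each planted haplotig
*and* its primary partner), but only the three haplotigs align
end-to-end into their partners (coverage ≥ 0.95), so exactly the planted
`scaffold_08/09/10` are removed — the longer partners are the designated
keepers. `splitAssembly()` then partitions the FASTA/GFF3, and
`updateBuscoStatus()` shows zero Duplicated benchmark genes afterwards.

The whole chain — simulate → stats → screen → split → re-stats →
duplicate genes → repeats — is one call:

```r
report <- runPipeline(simConfig(seed = 42), outDir = "run1")
```

writing per-stage TSVs, kept/removed FASTA+GFF3, a manifest and a
Markdown report under `run1/`. A thin command-line interface wraps the
same functions (`exec/hapcull`), e.g.
`hapcull dedup --fasta asm.fa --gff asm.gff3 --busco full_table.tsv
--out-prefix dedup/`.

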