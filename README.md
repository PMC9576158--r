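# wildcore

SNP-based genetic diversity analysis and core-collection construction for
germplasm panels, built around the kind of survey used for common wild rice
(*Oryza rufipogon*): hundreds of accessions from a handful of regional
populations, genotyped at ~1,600 biallelic SNPs, from which a curator wants
(i) per-region diversity statistics, (ii) distance-based population
structure, and (iii) a core collection — a small subset of accessions that
preserves nearly all of the allelic diversity of the full collection.

## What it computes

**Diversity statistics.** For each biallelic locus with alternate-allele
frequency *p* (*q* = 1 − *p*) on *n* called genotypes:

| statistic | formula |
|---|---|
| expected heterozygosity (He) | 1 − *p*² − *q*² |
| Nei's unbiased diversity | (2*n* / (2*n* − 1)) · He |
| effective allele number (Ne) | 1 / (*p*² + *q*²) |
| polymorphism information content (PIC) | 1 − (*p*² + *q*²) − 2*p*²*q*² |
| Shannon–Wiener index (I) | −*p* ln *p* − *q* ln *q* |
| observed heterozygosity (Ho) | heterozygote fraction among called |

Per-population tables average these over the loci polymorphic within the
population; whole-collection reports average over all loci (both policies
are explicit arguments).

**Distances and trees.** Modified Rogers distance between accessions,
MR<sub>ij</sub> = √( Σ<sub>l</sub> (x<sub>il</sub> − x<sub>jl</sub>)² / 4L<sub>ij</sub> )
on pairwise-complete loci; Nei (1972) distance D = −ln I between
populations; a deterministic neighbour-joining implementation (lexicographic
tie-breaks, non-negative branch lengths) returning `ape` trees; dosage PCA.

**Core selection.** Population-priority seeding (one maximally outlying
accession per region), a greedy allele-coverage ranking curve, and subset
optimization of the weighted objective

  score(S) = 0.7 · meanMR(S) + 0.3 · pooledShannon(S)

by greedy fill plus steepest-ascent swap search (compiled kernel, seeds
protected, deterministic for a given seed). Evaluation reports per-region
origin counts and the retention percentage of every diversity statistic in
the core versus the total collection.

**Synthetic panels.** A Balding–Nichols island-model simulator with known
truth generates survey-shaped data (998 accessions, 14 regions, 1,592 SNPs
on 12 chromosomes, mean MAF ≈ 0.128) so the whole pipeline can be run and
validated without any genotype download.

## Worked example

```r
library(wildcore)

sim  <- wildRicePanel(seed = 1)          # 998 x 1,592 synthetic survey panel
g    <- filterLoci(sim$genotypes)        # MAF >= 1%, call rate >= 50%
#> filterLoci: kept 1536 of 1592 loci (removed 56)
g
#> SnpGenotypes: 1536 loci x 998 accessions
#>   missing calls: 8.0%
#>   populations: 14 labels
#>   chromosomes: 12

print(head(summaryTable(g), 4), digits = 4)   # per-region diversity table
#>       group  n    maf   np na    ne    nei shannon    pic     ho     he
#> 1  Dongguan 19 0.1668 1134  2 1.382 0.2530  0.3933 0.2048 0.2556 0.2457
#> 2    Foshan 48 0.1477 1312  2 1.337 0.2228  0.3575 0.1849 0.2255 0.2203
#> 3 Guangzhou 60 0.1456 1318  2 1.333 0.2201  0.3541 0.1832 0.2210 0.2181
#> 4    Heyuan 38 0.1516 1257  2 1.346 0.2292  0.3660 0.1895 0.2302 0.2259

core <- optimizeCore(g, size = 299, rngSeed = 1)   # 30% core, seeds protected
core
#> CoreSelection of 299 accessions
#>   objective: 0.523917 (weights mr = 0.7, sh = 0.3)
#>   allele coverage: 1.0000
#>   regions represented: 14

rep3 <- compareCore(g, core)             # retention report (Table-3 style)
rep3[rep3$statistic %in% c("np", "nei", "shannon", "he"), ]
#>    statistic     total      core retentionPct
#> 3         np 1536.0000 1536.0000       100.00
#> 6        nei    0.2008    0.2084       103.78
#> 7    shannon    0.3361    0.3461       102.98
#> 10        he    0.2007    0.2080       103.64
```

The 299-accession core (30% of the panel) carries every allele of the full
collection (coverage 1.0000) and *more* average diversity per locus than
the whole panel (retention > 100% for He, Nei and Shannon) — exactly the
behaviour expected of a diversity-maximizing core.

`runPipeline(pipelineConfig(simulate = simulationConfig(rngSeed = 1)), "out/")`
runs every stage (filter → diversity table → distances → NJ trees → PCA →
coverage curve → core → evaluation) and writes the full artifact set plus a
log with per-stage timings.

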