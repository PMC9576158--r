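---
title: "Methods: diversity statistics, distances and core-collection optimization in wildcore"
author: "wildcore authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics, distances and core-collection optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildcore)
```

wildcore implements the analysis chain of a germplasm SNP survey: filter a
diploid biallelic genotype panel, summarize diversity per regional
population, describe structure with distances, trees and PCA, and build a
core collection under a population-priority constraint. This vignette is
the package's own account of the models and the choices behind them.

## Data model

The central object, `SnpGenotypes`, extends `RangedSummarizedExperiment`:
loci are rows (a `GRanges` with `ref`/`alt` alleles), accessions are
columns, and the single assay holds the alternate-allele dosage per call —
0, 1 or 2, with a dedicated `NA` for missing calls. Dosage coding makes
every downstream statistic a small arithmetic expression in the
alternate-allele frequency; the missing sentinel is never conflated with
the reference-homozygote 0. Heterozygotes are ordinary data: wild rice
outcrosses appreciably (observed heterozygosity around 0.2–0.35 per
region), so nothing is collapsed to pseudo-homozygotes.

## Locus filtering

`filterLoci()` keeps loci with minor allele frequency ≥ `mafMin` (default
1%) and call rate ≥ `callRateMin` (default 50%); both thresholds are
inclusive, and MAF is computed on non-missing calls only. "Integrity" in
genotyping-panel parlance is read as the per-locus call rate; filtering is
applied jointly across all accessions (a per-batch reading would need batch
metadata the data model does not carry). The operation is idempotent and
never alters surviving calls.

## Diversity statistics

For a biallelic locus with alternate-allele frequency $p$, $q = 1-p$, and
$n$ called genotypes:

$$He = 1 - p^2 - q^2, \qquad Nei = \frac{2n}{2n-1}\,He, \qquad
Ne = \frac{1}{p^2+q^2},$$
$$PIC = 1 - (p^2+q^2) - 2p^2q^2, \qquad I = -p\ln p - q\ln q,$$

and $Ho$ is the heterozygote fraction among called genotypes. The `Nei`
column is the *unbiased* gene diversity (finite-sample correction with the
per-locus called count, so missingness is handled locus by locus), while
`He` is the plain $1-\sum p^2$; on large samples the two coincide to three
decimals. The Shannon index uses the natural logarithm (its biallelic
maximum is $\ln 2 \approx 0.693$); PIC is bounded by $He$ with equality
only at fixed loci, and peaks at 0.375 when $p = 0.5$.

**Locus-inclusion policy.** Per-population summaries average the per-locus
statistics over the loci *polymorphic within that population*, and `np`
counts those loci; this is the convention of per-region diversity tables,
where a locus fixed in one region is not informative about that region's
diversity. Whole-collection reports (`compareCore()`) instead average over
*all* defined loci, the natural policy when core and total sets must be
compared on a common denominator. Both policies are explicit arguments
(`polymorphicOnly`), and the summary-table mean row is the unweighted
arithmetic mean of the population rows with the polymorphic count rounded
to an integer, matching how such tables are printed. `Ne` is averaged as
the mean of per-locus $1/(p^2+q^2)$ — not derived from the mean He — since
the two differ by Jensen's inequality and published tables follow the
per-locus mean.

Report rounding is half-up (4 decimals for statistics, 2 for percentages),
the convention of the printed tables this layout mirrors; base R's
round-half-even would disagree on boundary digits.

## Distances and trees

**Modified Rogers** between accessions $i,j$:
$MR_{ij} = \sqrt{\sum_l (x_{il}-x_{jl})^2 / (4 L_{ij})}$ over the $L_{ij}$
loci called in both. Pairwise-complete loci (rather than global
complete-case) preserve information at the 50% integrity floor; a pair
sharing no called locus is an error naming the pair. Entries live in
$[0,1]$ and MR is a metric on complete data.

**Nei (1972)** between populations: $D = -\ln I$ with
$I = J_{xy} / \sqrt{J_x J_y}$, the normalized gene identity of the two
allele-frequency profiles, summed over loci with defined frequencies in
both populations. $I = 0$ (no shared allele anywhere) would give an
infinite distance; it is capped at a configurable 10 with a warning so
downstream tree building stays defined.

**Neighbour-joining** is implemented in the package so that its
determinism is part of the contract: Q-criterion ties are broken by the
lexicographically smallest pair of cluster keys (a cluster's key is the
smallest original label it contains), and a negative branch-length
estimate is clamped to zero with the deficit moved to the sister branch so
the joined distance is preserved — the behaviour of mainstream tree
software. On additive matrices the output reproduces every pairwise
distance to $10^{-9}$, which the tests verify against exhaustive topology
search on quartets and against an independent NJ implementation.
`cutTreeHeight()` provides the "tree scale" reading of a dendrogram:
delete edges longer than a threshold and report the leaf partition.

**PCA** centres dosages per locus after mean-imputing missing calls — the
standard dosage-PCA convention, which places a missing call at the locus
centroid where it cannot influence the axes.

## Core-collection construction

The search honours *population priority*: `stratifiedSeed()` fixes one
accession per region — the member with maximal mean modified Rogers
distance to its own region (the most diversity-bearing representative;
ties go to the smallest id) — and the optimizer may never remove it.

The objective is a convex combination
$$score(S) = w_{MR}\,\overline{MR}(S) + w_{SH}\,SH(S), \qquad
w_{MR} = 0.7,\; w_{SH} = 0.3,$$
where $\overline{MR}$ is the mean pairwise modified Rogers distance within
the subset and $SH$ pools every allele of every locus (each locus weighted
equally, so pooled frequencies sum to 1) into one Shannon index, normalized
by the log of the total allele count to $[0,1]$. The 0.7/0.3 weighting is
the usual weighted-index mode of core-selection software, with weights
summing to one. Mean-pairwise is the distance aggregation; an
entry-to-nearest aggregation is a known alternative but the mean-pairwise
default is stated and logged with every run.

The search is greedy fill from the seed set by best objective gain,
followed by steepest-ascent single-swap hill climbing (any non-seed member
against any outside candidate), stopping when no swap improves the
objective or after `maxIter` accepted moves. Additional restarts begin
from random seed-respecting fills drawn from the run's RNG seed, so the
whole procedure is deterministic; the best final objective wins. The
accepted-move trace is monotone and the final objective can never fall
below the greedy start. A stochastic-metaheuristic engine (replica
exchange, as used by some core-selection software) was deliberately not
reproduced: the steepest-ascent design is desk-scale verifiable — the
tests enumerate all seed-respecting subsets at $N=10$, $k=4$ and confirm
the optimizer attains the exhaustive optimum. The inner delta evaluation
is compiled (Rcpp) because a survey-scale sweep examines ~2×10⁵ candidate
swaps, each requiring an $O(L)$ pooled-Shannon update.

The default core size is the smallest $k$ whose greedy allele-coverage
ranking reaches 99.9% — the "knee" criterion used when a target size is
not imposed; `size` overrides it. The greedy ranking itself
(`coverageRanking()`) carries the usual $(1-1/e)$ approximation guarantee
for coverage at every prefix, which the tests check against exhaustive
optima on small panels.

## Evaluation

`compareCore()` recomputes every statistic within the core (so core MAF
can legitimately exceed total MAF — rare alleles are enriched), rounds the
reported values first and derives retention percentages from the rounded
columns, so a reader can recompute every percentage exactly from the
printed numerators and denominators. `countsByRegion()` plus
`withTotalsRow()` reproduce the origin-table layout; `pcaOverlay()` labels
the full-collection PCA scores by core membership.

## The synthetic panel

`simulateGenotypes()` is a Balding–Nichols island model: per locus an
ancestral alternate-allele frequency whose MAF follows a Beta(1, 7.5) law
truncated to [0.01, 0.5]; per deme a frequency drawn from
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ so that
$E[\tilde p] = p$ and $\mathrm{Var}[\tilde p] = F p(1-p)$; genotypes
$\mathrm{Binomial}(2, \tilde p)$; calls masked missing uniformly at 8%.
The defaults emulate the survey shape the package is modelled on: 998
accessions in 14 regional populations with the survey's exact sizes, 1,592
SNPs spread unevenly over 12 chromosomes (one heavily loaded chromosome of
623 loci, one light one of 80). The Beta shapes and $F = 0.08$ were chosen
once so that the realized panel-wide mean MAF after the standard filter is
about 0.128 and ≥ 95% of loci survive the filter — the regime of the
emulated panel; $F$ of this size also yields the small between-region Nei
distances (tree scales of order 0.005–0.01) characteristic of weakly
differentiated regional collections. All randomness flows through R's
Mersenne-Twister from a single integer seed, making panels bit-reproducible
across platforms.

What the simulator does *not* emulate: linkage disequilibrium (no analysis
here uses it), mutation or selection, batch-structured missingness, and
model-based admixture groups (group labels for plots come from k-means on
PCA scores, declared plumbing — re-implementing an admixture likelihood is
out of scope). Passing tests on synthetic panels therefore validate the
*computations*, not claims about any particular real collection.

**Validation scales.** The test suite runs the full pipeline once at
survey scale (998 × 1,592, 30% core) and checks island-model He recovery
($E[He_{deme}] = (1-F)\,He_{anc}$, within 3 Monte-Carlo standard errors)
and Fst recovery by regressing among-deme frequency variance on
$p(1-p)$ (within 15% relative error at 1,592 loci). The 20-replicate
retention property keeps the full accession dimension (998 accessions, 14
demes — the sampling fraction and the post-filter allele-copy regime live
there) and down-scales the locus panel to 200 SNPs; replicates at reduced
accession counts would admit 2-copy alleles that a 1%-MAF filter on 998
accessions structurally excludes, which distorts coverage for reasons of
scale, not of method.

## Numerical and degenerate-input choices

* Loci with no called genotype in a subset have undefined frequency; they
  are flagged and excluded from summaries and from the pooled Shannon.
* An all-removed filter result is a warning plus an empty-locus object,
  not an error — pipelines report it rather than crash.
* Objective comparisons in the optimizer use a $10^{-12}$ improvement
  margin; equal-objective swaps are not accepted, so local search
  terminates.
* VCF input accepts phased separators and treats any genotype containing a
  missing allele as missing; multi-allelic and non-SNP records are skipped
  with a count. Coordinates are 1-based.

## Known limitations

* Biallelic diploid data only; multi-allelic or polyploid panels are out
  of scope by design.
* The NJ implementation is quadratic per iteration and intended for up to
  a few hundred taxa (regions, or core-sized accession sets), not for
  thousands.
* Nei's distance between very small populations is noisy; the package
  reports it as computed and leaves interpretation to the analyst.
* The optimizer guarantees a local optimum of the swap neighbourhood (and
  the exhaustive optimum on enumerable sizes); global optimality at survey
  scale is not certified, which is inherent to the problem class.
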