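#' SnpGenotypes: diploid biallelic SNP genotypes for a germplasm panel
#'
#' An S4 container extending [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are SNP loci (a `GRanges` with `ref`/`alt` metadata columns), columns
#' are accessions. The single assay `"dosage"` holds the count of the
#' alternate allele per call: 0, 1, 2 or `NA` for a missing call. An optional
#' `population` column in `colData` assigns every accession to exactly one
#' (regional) population.
#'
#' @slot .. see `RangedSummarizedExperiment`; no additional slots.
#' @seealso [snpGenotypes()], [dosages()], [populations()], [filterLoci()]
#' @export
setClass("SnpGenotypes", contains = "RangedSummarizedExperiment")

setValidity("SnpGenotypes", function(object) {
  msgs <- character()
  if (!"dosage" %in% assayNames(object))
    msgs <- c(msgs, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msgs <- c(msgs, "non-missing dosages must be 0, 1 or 2 (biallelic diploid)")
  }
  ids <- colnames(object)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msgs <- c(msgs, "accession ids (colnames) must be present and non-empty")
  else if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicate accession ids")
  rr <- rowRanges(object)
  mc <- mcols(rr)
  if (!all(c("ref", "alt") %in% names(mc)))
    msgs <- c(msgs, "rowRanges must carry 'ref' and 'alt' metadata columns")
  else if (length(rr) && any(as.character(mc$ref) == as.character(mc$alt)))
    msgs <- c(msgs, "ref and alt alleles must differ at every locus")
  if (length(rr) && any(start(rr) < 1L))
    msgs <- c(msgs, "locus positions must be >= 1")
  if ("population" %in% names(colData(object))) {
    p <- colData(object)$population
    if (anyNA(p) || any(p == ""))
      msgs <- c(msgs, "every accession needs exactly one population label when a map is attached")
  }
  if (length(msgs)) msgs else TRUE
})

#' CoreSelection: a chosen core subset of accessions
#'
#' Result of [optimizeCore()]. Holds the selected accession ids, the weighted
#' objective value achieved, the fraction of the full collection's alleles
#' present in the subset, and per-region counts.
#'
#' @slot selected character vector of accession ids in the core.
#' @slot objective numeric weighted objective (modified Rogers + Shannon).
#' @slot weights numeric length-2 named vector `c(mr =, sh =)`.
#' @slot coverage numeric in `[0, 1]`, allele coverage of the full collection.
#' @slot perRegionCounts named integer vector, accessions per population.
#' @slot trace numeric vector of accepted objective values (monotone).
#' @export
setClass("CoreSelection", representation(
  selected = "character",
  objective = "numeric",
  weights = "numeric",
  coverage = "numeric",
  perRegionCounts = "integer",
  trace = "numeric"
))

setValidity("CoreSelection", function(object) {
  msgs <- character()
  if (anyDuplicated(object@selected))
    msgs <- c(msgs, "duplicated accession ids in selection")
  if (length(object@coverage) != 1L || object@coverage < 0 || object@coverage > 1)
    msgs <- c(msgs, "coverage must be a single value in [0, 1]")
  if (length(object@perRegionCounts) &&
      sum(object@perRegionCounts) != length(object@selected))
    msgs <- c(msgs, "per-region counts must sum to the core size")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the island-model genotype simulator
#'
#' Balding-Nichols style simulation: each locus has an ancestral alternate
#' frequency drawn from a Beta law truncated to keep the minor allele
#' frequency in a realistic band; each deme (regional population) draws its
#' own frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)`; genotypes are
#' `Binomial(2, deme frequency)`; calls are set missing uniformly at
#' `missingRate`.
#'
#' @slot demeLabels character, one label per deme.
#' @slot demeSizes integer, accessions per deme (same length).
#' @slot nLoci integer number of SNP loci.
#' @slot chromProps numeric length-12, proportion of loci per chromosome.
#' @slot fst numeric in (0, 1), differentiation among demes.
#' @slot betaShape numeric length-2, Beta(a, b) shapes of the ancestral law.
#' @slot mafRange numeric length-2, truncation band of the ancestral MAF.
#' @slot missingRate numeric in [0, 0.5].
#' @slot rngSeed integer seed (Mersenne-Twister via `set.seed`).
#' @export
setClass("SimulationConfig", representation(
  demeLabels = "character",
  demeSizes = "integer",
  nLoci = "integer",
  chromProps = "numeric",
  fst = "numeric",
  betaShape = "numeric",
  mafRange = "numeric",
  missingRate = "numeric",
  rngSeed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (length(object@demeLabels) != length(object@demeSizes))
    msgs <- c(msgs, "demeLabels and demeSizes must have equal length")
  if (anyDuplicated(object@demeLabels))
    msgs <- c(msgs, "deme labels must be unique")
  if (any(object@demeSizes < 1L))
    msgs <- c(msgs, "all deme sizes must be >= 1")
  if (object@nLoci < 1L)
    msgs <- c(msgs, "nLoci must be >= 1")
  if (length(object@chromProps) != 12L || any(object@chromProps <= 0))
    msgs <- c(msgs, "chromProps must be 12 positive proportions")
  if (object@fst <= 0 || object@fst >= 1)
    msgs <- c(msgs, "fst must lie in (0, 1)")
  if (any(object@betaShape <= 0))
    msgs <- c(msgs, "Beta shapes must be positive")
  if (object@mafRange[1] < 0 || object@mafRange[2] > 0.5 ||
      object@mafRange[1] >= object@mafRange[2])
    msgs <- c(msgs, "mafRange must be an increasing interval within [0, 0.5]")
  if (object@missingRate < 0 || object@missingRate > 0.5)
    msgs <- c(msgs, "missingRate must lie in [0, 0.5]")
  if (length(msgs)) msgs else TRUE
})
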