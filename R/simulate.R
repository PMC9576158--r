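## Island-model genotype simulator (Balding-Nichols).
##
## Each locus has an ancestral alternate-allele frequency whose minor-allele
## frequency follows a truncated Beta law; each deme draws its own frequency
## from Beta(p(1-F)/F, (1-p)(1-F)/F), so E[deme freq] = p and
## Var[deme freq] = F p (1-p); genotypes are Binomial(2, deme frequency) and
## calls are masked missing uniformly. All randomness flows through R's
## Mersenne-Twister via set.seed(rngSeed), which makes every run
## bit-reproducible for a given seed.

.DEME_LABELS <- c("Dongguan", "Foshan", "Guangzhou", "Heyuan", "Huizhou",
                  "Jiangmen", "Jieyang", "Maoming", "Qingyuan", "Shanwei",
                  "Shenzhen", "Yangjiang", "Zhanjiang", "Hainan")
.DEME_SIZES <- c(19L, 48L, 60L, 38L, 232L, 128L, 74L, 90L, 53L, 120L,
                 15L, 22L, 52L, 47L)
## uneven chromosome loading of the emulated panel (chr7 heavy, chr10 light)
.CHROM_COUNTS <- c(85, 88, 90, 92, 95, 86, 623, 99, 84, 80, 89, 81)

#' Configure the island-model genotype simulator
#'
#' Defaults emulate the shape of the wild-rice survey panel this package is
#' modelled on: 998 accessions in 14 regional populations (sizes 19, 48, 60,
#' 38, 232, 128, 74, 90, 53, 120, 15, 22, 52, 47), 1,592 biallelic SNPs
#' spread unevenly over 12 chromosomes, an ancestral minor-allele-frequency
#' law tuned so the realized panel-wide mean MAF is about 0.128, moderate
#' differentiation among demes, and missing calls well inside the 50%
#' integrity filter.
#'
#' @param demeLabels,demeSizes population labels and accession counts.
#' @param nLoci number of SNP loci.
#' @param chromProps proportions of loci per chromosome (length 12).
#' @param fst differentiation among demes, in (0, 1).
#' @param betaShape Beta(a, b) shapes of the ancestral MAF law.
#' @param mafRange truncation band of the ancestral MAF.
#' @param missingRate probability a call is missing.
#' @param rngSeed integer seed.
#' @return a validated [SimulationConfig-class] object.
#' @export
simulationConfig <- function(demeLabels = .DEME_LABELS,
                             demeSizes = .DEME_SIZES,
                             nLoci = 1592L,
                             chromProps = .CHROM_COUNTS / sum(.CHROM_COUNTS),
                             fst = 0.08,
                             betaShape = c(1, 7.5),
                             mafRange = c(0.01, 0.5),
                             missingRate = 0.08,
                             rngSeed = 1L) {
  new("SimulationConfig", demeLabels = as.character(demeLabels),
      demeSizes = as.integer(demeSizes), nLoci = as.integer(nLoci),
      chromProps = as.numeric(chromProps), fst = as.numeric(fst),
      betaShape = as.numeric(betaShape), mafRange = as.numeric(mafRange),
      missingRate = as.numeric(missingRate), rngSeed = as.integer(rngSeed))
}

## deterministic locus counts per chromosome by largest remainder
.chromCounts <- function(nLoci, props) {
  raw <- props / sum(props) * nLoci
  cnt <- floor(raw)
  short <- nLoci - sum(cnt)
  if (short > 0) {
    up <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[up] <- cnt[up] + 1
  }
  as.integer(cnt)
}

#' Simulate a structured genotype panel with known truth
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return a list with `genotypes` (a [SnpGenotypes-class], populations
#'   attached) and `truth` (list with `ancestral` frequency per locus,
#'   `demeFreq` loci-by-demes matrix, and the `config` echo).
#' @export
simulateGenotypes <- function(config) {
  validObject(config)
  set.seed(config@rngSeed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  L <- config@nLoci
  K <- length(config@demeLabels)
  N <- sum(config@demeSizes)
  a <- config@betaShape[1]; b <- config@betaShape[2]
  lo <- stats::pbeta(config@mafRange[1], a, b)
  hi <- stats::pbeta(config@mafRange[2], a, b)
  maf <- stats::qbeta(runif(L, lo, hi), a, b)
  flip <- runif(L) < 0.5                  # unpolarized ref/alt
  p <- ifelse(flip, 1 - maf, maf)
  FF <- config@fst
  demeFreq <- sapply(seq_len(K), function(k)
    rbeta(L, p * (1 - FF) / FF, (1 - p) * (1 - FF) / FF))
  dimnames(demeFreq) <- NULL
  d <- matrix(NA_integer_, nrow = L, ncol = N)
  col <- 0L
  for (k in seq_len(K)) {
    nk <- config@demeSizes[k]
    d[, col + seq_len(nk)] <- matrix(rbinom(L * nk, 2L, demeFreq[, k]), nrow = L)
    col <- col + nk
  }
  if (config@missingRate > 0)
    d[runif(length(d)) < config@missingRate] <- NA_integer_
  ids <- unlist(lapply(seq_len(K), function(k)
    sprintf("%s_%03d", config@demeLabels[k], seq_len(config@demeSizes[k]))))
  pops <- rep(config@demeLabels, config@demeSizes)
  cnt <- .chromCounts(L, config@chromProps)
  chrom <- rep(sprintf("chr%02d", seq_len(12L)), cnt)
  pos <- unlist(lapply(cnt, function(m) sort(sample.int(3e7L, m))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  dimnames(d) <- list(paste0(chrom, "_", pos), ids)
  loci <- data.frame(locus = rownames(d), chrom = chrom, pos = pos,
                     ref = unname(ref), alt = unname(alt))
  g <- snpGenotypes(d, loci = loci, populations = setNames(pops, ids))
  truth <- list(ancestral = p, demeFreq = demeFreq, config = config)
  list(genotypes = g, truth = truth)
}

#' Simulate the survey-shaped panel
#'
#' Convenience wrapper: [simulateGenotypes()] with all defaults (998
#' accessions, 14 regions, 1,592 loci) and the given seed.
#'
#' @param seed integer seed.
#' @return as [simulateGenotypes()].
#' @export
wildRicePanel <- function(seed = 1L) {
  simulateGenotypes(simulationConfig(rngSeed = as.integer(seed)))
}

#' Write the simulation truth record as JSON
#'
#' @param truth the `truth` element of [simulateGenotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimulationTruth <- function(truth, path) {
  cfg <- truth$config
  jsonlite::write_json(list(
    ancestral = truth$ancestral,
    deme_freq = as.data.frame(setNames(as.data.frame(truth$demeFreq),
                                       cfg@demeLabels)),
    config = list(demeLabels = cfg@demeLabels, demeSizes = cfg@demeSizes,
                  nLoci = cfg@nLoci, fst = cfg@fst,
                  betaShape = cfg@betaShape, mafRange = cfg@mafRange,
                  missingRate = cfg@missingRate, rngSeed = cfg@rngSeed)),
    path, digits = NA)
  invisible(path)
}
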