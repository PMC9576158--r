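## Per-locus and per-population diversity statistics of a biallelic SNP panel.
##
## For a locus with alternate-allele frequency p (q = 1 - p) on n called
## genotypes:
##   he   = 1 - p^2 - q^2                 (Nei gene diversity, biased)
##   nei  = 2n/(2n - 1) * he              (unbiased gene diversity, Nei 1978)
##   ne   = 1 / (p^2 + q^2)               (effective allele number)
##   pic  = 1 - (p^2 + q^2) - 2 p^2 q^2   (polymorphism information content)
##   i    = -p ln p - q ln q              (Shannon-Wiener index, 0 when fixed)
##   ho   = heterozygote fraction among called genotypes

#' Per-locus alternate-allele frequencies
#'
#' @param x a [SnpGenotypes-class] object.
#' @param subset accessions to use: `"all"` (default), a character vector of
#'   ids, or an index. Must be non-empty.
#' @return a `DataFrame` (one row per locus) with columns `p` (alternate
#'   allele frequency, `NA` where no genotype is called), `maf` and
#'   `nCalled`.
#' @export
alleleFrequencies <- function(x, subset = "all") {
  idx <- .resolveSubset(x, subset)
  d <- dosages(x)[, idx, drop = FALSE]
  nCalled <- unname(rowSums(!is.na(d)))
  p <- ifelse(nCalled > 0L, unname(rowSums(d, na.rm = TRUE)) / (2 * nCalled),
              NA_real_)
  DataFrame(p = p, maf = pmin(p, 1 - p), nCalled = nCalled,
            row.names = rownames(d))
}

#' Per-locus diversity statistics
#'
#' Computes, per locus over the chosen accessions, the allele frequency and
#' the panel statistics: observed (`ho`) and expected (`he`) heterozygosity,
#' Nei's unbiased gene diversity (`nei`, sample-size corrected with the
#' per-locus called count), effective allele number (`ne`), polymorphism
#' information content (`pic`), Shannon-Wiener index (`shannon`), observed
#' allele count (`na`) and a polymorphism flag. Loci with no called genotype
#' have all statistics `NA` and are excluded from summaries.
#'
#' @inheritParams alleleFrequencies
#' @return a `DataFrame` with one row per locus.
#' @export
locusStats <- function(x, subset = "all") {
  idx <- .resolveSubset(x, subset)
  d <- dosages(x)[, idx, drop = FALSE]
  af <- alleleFrequencies(x, idx)
  p <- af$p
  q <- 1 - p
  he <- 1 - p^2 - q^2
  n <- af$nCalled
  nei <- ifelse(n > 0L, 2 * n / (2 * n - 1) * he, NA_real_)
  ne <- 1 / (p^2 + q^2)
  pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  shannon <- ifelse(is.na(p), NA_real_,
                    -ifelse(p > 0, p * log(p), 0) - ifelse(q > 0, q * log(q), 0))
  ho <- ifelse(n > 0L, unname(rowSums(d == 1L, na.rm = TRUE)) / n, NA_real_)
  na <- ifelse(is.na(p), NA_integer_, 1L + (p > 0 & p < 1))
  DataFrame(p = p, maf = af$maf, nCalled = n, ho = ho, he = he, nei = nei,
            ne = ne, pic = pic, shannon = shannon, na = na,
            isPolymorphic = !is.na(p) & p > 0 & p < 1,
            row.names = rownames(d))
}

## means of per-locus statistics for one accession subset.
## polymorphicOnly = TRUE restricts to loci segregating within the subset
## (the per-region reporting policy); FALSE averages over every defined locus
## (the whole-collection policy).
.subsetSummary <- function(x, idx, label, polymorphicOnly = TRUE) {
  ls <- locusStats(x, idx)
  defined <- !is.na(ls$p)
  np <- sum(ls$isPolymorphic)
  use <- if (polymorphicOnly) ls$isPolymorphic else defined
  mean0 <- function(v) if (any(use)) mean(v[use]) else 0
  data.frame(
    group = label, n = length(idx), maf = mean0(ls$maf), np = np,
    na = mean0(as.numeric(ls$na)), ne = mean0(ls$ne), nei = mean0(ls$nei),
    shannon = mean0(ls$shannon), pic = mean0(ls$pic), ho = mean0(ls$ho),
    he = mean0(ls$he), stringsAsFactors = FALSE)
}

#' Diversity summary of one population
#'
#' Means of the per-locus statistics over the loci polymorphic within the
#' population (default policy for per-region tables) or over all defined
#' loci (`polymorphicOnly = FALSE`, the whole-collection policy).
#'
#' @param x a [SnpGenotypes-class] with populations attached.
#' @param population a population label present in `x`.
#' @param polymorphicOnly locus-inclusion policy (see Details).
#' @return a one-row data.frame with columns `group`, `n`, `maf`, `np`,
#'   `na`, `ne`, `nei`, `shannon`, `pic`, `ho`, `he`.
#' @export
populationSummary <- function(x, population, polymorphicOnly = TRUE) {
  pops <- populations(x)
  if (is.null(pops)) stop("no populations attached")
  if (!population %in% pops) stop("unknown population: ", population)
  idx <- which(pops == population)
  .subsetSummary(x, idx, population, polymorphicOnly)
}

#' Per-population diversity table with mean row
#'
#' One summary row per population (columns ordered MAF, Np, Na, Ne, Nei, I,
#' PIC, Ho, He after the grouping columns) plus a final `Mean` row holding
#' the unweighted arithmetic mean of the population rows; the mean of the
#' polymorphic-marker counts is rounded to the nearest integer, as count
#' columns are printed.
#'
#' @inheritParams populationSummary
#' @return a data.frame, one row per population plus the mean row.
#' @export
summaryTable <- function(x, polymorphicOnly = TRUE) {
  pops <- populations(x)
  if (is.null(pops)) stop("no populations attached")
  labs <- unique(pops)
  rows <- do.call(rbind, lapply(labs, function(l)
    populationSummary(x, l, polymorphicOnly)))
  num <- c("maf", "np", "na", "ne", "nei", "shannon", "pic", "ho", "he")
  meanRow <- rows[1L, , drop = FALSE]
  meanRow$group <- "Mean"
  meanRow$n <- sum(rows$n)
  for (cn in num) meanRow[[cn]] <- mean(rows[[cn]])
  meanRow$np <- roundHalfUp(meanRow$np)
  out <- rbind(rows, meanRow)
  rownames(out) <- NULL
  out
}

#' Write a diversity summary table
#'
#' Serializes a [summaryTable()] (or [compareCore()] numerator rows) in the
#' conventional column order MAF, Np, Na, Ne, Nei, I, PIC, Ho, He, values
#' rounded half-up to 4 decimals.
#'
#' @param tab data.frame from [summaryTable()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
writeDiversityTable <- function(tab, path, sep = "\t") {
  out <- data.frame(
    Group = tab$group,
    MAF = roundHalfUp(tab$maf, 4), Np = tab$np,
    Na = roundHalfUp(tab$na, 4), Ne = roundHalfUp(tab$ne, 4),
    Nei = roundHalfUp(tab$nei, 4), I = roundHalfUp(tab$shannon, 4),
    PIC = roundHalfUp(tab$pic, 4), Ho = roundHalfUp(tab$ho, 4),
    He = roundHalfUp(tab$he, 4), check.names = FALSE)
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
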