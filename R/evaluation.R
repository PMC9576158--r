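## Core-versus-total evaluation: diversity retention report, per-region
## origin counts, and PCA overlay data.

#' Diversity retention of a core versus the whole collection
#'
#' Computes the panel statistics (MAF, Np, Na, Ne, Nei, I, PIC, Ho, He) over
#' all loci (whole-collection policy, allele frequencies recomputed within
#' each set) for the total collection and the core subset, and the retention
#' percentage `100 * core / total` per statistic, plus the core size
#' percentage. Values are rounded half-up to `digits` decimals first, so the
#' printed percentages recompute exactly from the printed numerator and
#' denominator columns; percentages are rounded to 2 decimals.
#'
#' @param x a [SnpGenotypes-class] object.
#' @param core a [CoreSelection-class] or character vector of accession ids
#'   (must be a non-empty subset of the accessions).
#' @param digits decimals kept on the reported statistic values (default 4).
#' @return a data.frame with one row per statistic (`n`, `maf`, `np`, `na`,
#'   `ne`, `nei`, `shannon`, `pic`, `ho`, `he`) and columns `total`, `core`,
#'   `retentionPct`.
#' @export
compareCore <- function(x, core, digits = 4) {
  ids <- if (is(core, "CoreSelection")) core@selected else as.character(core)
  if (length(ids) == 0L) stop("empty core")
  idx <- .resolveSubset(x, ids)
  tot <- .subsetSummary(x, seq_len(ncol(x)), "total", polymorphicOnly = FALSE)
  cor <- .subsetSummary(x, idx, "core", polymorphicOnly = FALSE)
  stat <- c("n", "maf", "np", "na", "ne", "nei", "shannon", "pic", "ho", "he")
  tv <- roundHalfUp(unlist(tot[stat]), digits)
  cv <- roundHalfUp(unlist(cor[stat]), digits)
  data.frame(statistic = stat, total = unname(tv), core = unname(cv),
             retentionPct = unname(roundHalfUp(100 * cv / tv, 2)))
}

#' Per-region composition of a core collection
#'
#' One row per region with the accession count of the full collection, the
#' core count, and the core share in percent; use [withTotalsRow()] to
#' append the totals row.
#'
#' @param core a [CoreSelection-class] or character vector of core ids.
#' @param populations named character vector accession id -> region, or a
#'   [SnpGenotypes-class] with populations attached.
#' @return a data.frame with columns `region`, `nTotal`, `nCore`,
#'   `corePct` (share of the core, 2 decimals half-up).
#' @export
countsByRegion <- function(core, populations) {
  if (is(populations, "SnpGenotypes")) populations <- populations(populations)
  if (is.null(populations)) stop("no populations attached")
  ids <- if (is(core, "CoreSelection")) core@selected else as.character(core)
  regions <- unique(populations)
  nTotal <- as.integer(table(factor(populations, levels = regions)))
  nCore <- as.integer(table(factor(populations[ids], levels = regions)))
  data.frame(region = regions, nTotal = nTotal, nCore = nCore,
             corePct = roundHalfUp(100 * nCore / length(ids), 2))
}

#' Append a totals row to a count table
#'
#' Sums every numeric count column (integer-valued columns) of a per-region
#' table and appends the result as a final `Total` row; non-count numeric
#' columns (percentages) are left `NA` in the totals row.
#'
#' @param tab a data.frame whose first column is the region label.
#' @return `tab` with one extra row.
#' @export
withTotalsRow <- function(tab) {
  tot <- tab[1L, , drop = FALSE]
  tot[[1L]] <- "Total"
  for (cn in names(tab)[-1L]) {
    v <- tab[[cn]]
    tot[[cn]] <- if (is.numeric(v) && all(v == round(v))) sum(v) else NA
  }
  out <- rbind(tab, tot)
  rownames(out) <- NULL
  out
}

#' PCA scores labelled by core membership
#'
#' Same scores as [genoPCA()] on the full collection, with every accession
#' labelled in-core or out-of-core (the labels partition the accessions).
#'
#' @param x a [SnpGenotypes-class] object.
#' @param core a [CoreSelection-class] or character vector of core ids.
#' @param k number of components (default 2).
#' @return a data.frame with `accession`, score columns `PC1..PCk`, and a
#'   logical `inCore` column.
#' @export
pcaOverlay <- function(x, core, k = 2) {
  ids <- if (is(core, "CoreSelection")) core@selected else as.character(core)
  .resolveSubset(x, ids)   # validates membership
  pc <- genoPCA(x, k)
  data.frame(accession = rownames(pc$scores), pc$scores,
             inCore = rownames(pc$scores) %in% ids, check.names = FALSE)
}
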