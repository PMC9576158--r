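## Core-collection construction: population-priority seeding, greedy
## allele-coverage ranking, the weighted modified-Rogers + Shannon objective,
## and subset optimization by greedy fill plus steepest-ascent swap hill
## climbing with restarts (compiled kernel in src/core_search.cpp).

#' Population-priority seed set
#'
#' Selects exactly one accession per population: the one with maximal mean
#' modified Rogers distance to the other members of its own population (the
#' most "outlying", diversity-carrying representative); a single-accession
#' population contributes that accession. Ties resolve to the
#' lexicographically smallest accession id.
#'
#' @param x a [SnpGenotypes-class] with populations attached.
#' @param D optional precomputed [modifiedRogers()] matrix over all
#'   accessions (computed when `NULL`).
#' @return character vector of accession ids, one per population.
#' @export
stratifiedSeed <- function(x, D = NULL) {
  pops <- populations(x)
  if (is.null(pops)) stop("no populations attached")
  if (is.null(D)) D <- modifiedRogers(x)
  ids <- colnames(x)
  vapply(unique(pops), function(l) {
    member <- ids[pops == l]
    if (length(member) == 1L) return(member)
    sub <- D[member, member, drop = FALSE]
    score <- rowSums(sub) / (length(member) - 1L)
    best <- member[score >= max(score) - 1e-12]
    sort(best, method = "radix")[1L]
  }, character(1), USE.NAMES = TRUE)
}

.allelePresence <- function(x) {
  d <- dosages(x)                       # L x N
  refP <- !is.na(d) & d <= 1L           # carries reference allele
  altP <- !is.na(d) & d >= 1L           # carries alternate allele
  rbind(refP, altP)                     # 2L x N presence matrix
}

#' Allele coverage of an accession subset
#'
#' Fraction of the alleles observed anywhere in the full collection that are
#' also present in the subset.
#'
#' @param x a [SnpGenotypes-class] object.
#' @param subset accession ids or index.
#' @export
setMethod("alleleCoverage", "SnpGenotypes", function(x, subset) {
  idx <- .resolveSubset(x, subset)
  P <- .allelePresence(x)
  inAll <- rowSums(P) > 0L
  if (!any(inAll)) return(1)
  sum(rowSums(P[inAll, idx, drop = FALSE]) > 0L) / sum(inAll)
})

#' Greedy allele-coverage ranking
#'
#' Ranks accessions by greedy marginal gain in distinct-allele count: rank 1
#' carries the most distinct alleles, each later rank adds the most alleles
#' not yet covered. Ties resolve to the lexicographically smallest id. The
#' resulting coverage curve is non-decreasing and reaches 1 at `k = N`.
#'
#' @param x a [SnpGenotypes-class] object.
#' @return a data.frame with columns `rank`, `accession`, `coverage`
#'   (coverage after including the first `rank` accessions).
#' @export
coverageRanking <- function(x) {
  P <- .allelePresence(x)
  P <- P[rowSums(P) > 0L, , drop = FALSE]
  nAllele <- nrow(P)
  ids <- colnames(x)
  ord <- order(ids, method = "radix")
  remaining <- ord                       # candidate indices, id-sorted
  uncovered <- rep(TRUE, nAllele)
  ranking <- integer(0)
  coverage <- numeric(0)
  while (length(remaining)) {
    gain <- colSums(P[uncovered, remaining, drop = FALSE])
    pick <- remaining[which.max(gain)]   # first max = smallest id (id-sorted)
    uncovered[P[, pick]] <- FALSE
    ranking <- c(ranking, pick)
    coverage <- c(coverage, 1 - sum(uncovered) / nAllele)
    remaining <- remaining[remaining != pick]
  }
  data.frame(rank = seq_along(ranking), accession = ids[ranking],
             coverage = coverage)
}

#' Weighted core objective of an accession subset
#'
#' `score = wMr * MR(S) + wSh * SH(S)` where `MR(S)` is the mean pairwise
#' modified Rogers distance within the subset and `SH(S)` is the
#' Shannon-Wiener index of the pooled allele frequencies (every allele of
#' every locus, each locus weighted equally so frequencies sum to 1),
#' normalized by the log of the total allele count to `[0, 1]`. The default
#' weights 0.7 / 0.3 follow the convex multi-objective convention of core
#' selection software.
#'
#' @param x a [SnpGenotypes-class] object.
#' @param subset accession ids or index, at least 2.
#' @param wMr,wSh convex weights, must sum to 1.
#' @param D optional precomputed [modifiedRogers()] matrix over all
#'   accessions.
#' @param mrAggregate how the within-subset distances are aggregated:
#'   `"mean"` (mean pairwise, the default used by the optimizer) or
#'   `"nearest"` (mean distance of each entry to its nearest other entry).
#' @return the numeric score.
#' @export
subsetObjective <- function(x, subset, wMr = 0.7, wSh = 0.3, D = NULL,
                            mrAggregate = c("mean", "nearest")) {
  idx <- .resolveSubset(x, subset)
  mrAggregate <- match.arg(mrAggregate)
  if (length(idx) < 2L) stop("subset must contain at least 2 accessions")
  if (abs(wMr + wSh - 1) > 1e-9) stop("weights must sum to 1")
  if (is.null(D)) D <- modifiedRogers(x)
  ids <- colnames(x)[idx]
  sub <- D[ids, ids, drop = FALSE]
  mr <- if (mrAggregate == "mean") mean(sub[upper.tri(sub)]) else {
    diag(sub) <- Inf
    mean(apply(sub, 1L, min))
  }
  wMr * mr + wSh * .pooledShannon(x, idx)
}

## normalized pooled Shannon index over loci with >= 1 call in the subset
.pooledShannon <- function(x, idx) {
  af <- alleleFrequencies(x, idx)
  p <- af$p[!is.na(af$p)]
  lEff <- length(p)
  if (lEff == 0L) return(0)
  q <- 1 - p
  iL <- -ifelse(p > 0, p * log(p), 0) - ifelse(q > 0, q * log(q), 0)
  (mean(iL) + log(lEff)) / log(2 * lEff)
}

#' Optimize a core collection
#'
#' Builds a core of `size` accessions that always contains the
#' population-priority seed set (one accession per population,
#' [stratifiedSeed()]), maximizing the weighted objective of
#' [subsetObjective()]. Search: greedy fill by objective gain from the seed
#' set, then steepest-ascent single-swap hill climbing in which seeds never
#' leave; additional `restarts` start from random fills (driven by
#' `rngSeed`, so the whole run is deterministic) and the best final
#' objective wins. The accepted-move objective trace is monotone
#' non-decreasing and the final objective is never below the greedy start.
#'
#' @param x a [SnpGenotypes-class] with populations attached.
#' @param size target core size; at least the number of populations. The
#'   default is the smallest k whose greedy allele coverage reaches 0.999.
#' @param wMr,wSh convex objective weights (default 0.7 / 0.3).
#' @param restarts number of starts (1 = greedy only).
#' @param maxIter cap on accepted hill-climb moves per start.
#' @param rngSeed integer seed for the restart draws.
#' @param D optional precomputed [modifiedRogers()] matrix.
#' @param allocation `"global"` (default) optimizes one constrained search
#'   over the whole collection; `"proportional"` first allots the core
#'   slots to the populations proportionally to their sizes (largest
#'   remainder, at least one each) and screens each population separately —
#'   the per-group reading of population-priority construction.
#' @return a [CoreSelection-class] object.
#' @export
optimizeCore <- function(x, size = NULL, wMr = 0.7, wSh = 0.3, restarts = 1,
                         maxIter = 500, rngSeed = 1, D = NULL,
                         allocation = c("global", "proportional")) {
  allocation <- match.arg(allocation)
  pops <- populations(x)
  if (is.null(pops)) stop("no populations attached")
  if (abs(wMr + wSh - 1) > 1e-9) stop("weights must sum to 1")
  ids <- colnames(x)
  N <- length(ids)
  if (is.null(size)) {
    cr <- coverageRanking(x)
    size <- which(cr$coverage >= 0.999)[1L]
    message("optimizeCore: default size ", size,
            " (smallest k with greedy coverage >= 0.999)")
  }
  nPop <- length(unique(pops))
  if (size < nPop)
    stop("size (", size, ") is below the number of populations (", nPop,
         "); cannot honour population priority")
  if (size > N) stop("size exceeds the number of accessions")
  if (is.null(D)) D <- modifiedRogers(x)
  D <- D[ids, ids]
  if (size == N) {
    sel <- ids
    obj <- subsetObjective(x, sel, wMr, wSh, D = D)
    return(.coreSelection(x, sel, obj, c(mr = wMr, sh = wSh), obj))
  }
  if (allocation == "proportional")
    return(.optimizeProportional(x, size, wMr, wSh, restarts, maxIter,
                                 rngSeed, D))
  seedIds <- stratifiedSeed(x, D = D)
  seed0 <- match(seedIds, ids) - 1L
  geno <- dosages(x)
  storage.mode(geno) <- "integer"
  set.seed(rngSeed)
  best <- NULL
  for (r in seq_len(restarts)) {
    init0 <- if (r == 1L) seed0 else
      c(seed0, sample(setdiff(seq_len(N) - 1L, seed0), size - length(seed0)))
    res <- .cpp_core_search(geno, D, seed0, init0, size, wMr, wSh, maxIter)
    if (is.null(best) || res$objective > best$objective + 1e-12) best <- res
  }
  sel <- sort(ids[best$selected + 1L], method = "radix")
  .coreSelection(x, sel, best$objective, c(mr = wMr, sh = wSh), best$trace)
}

## per-group screening: proportional slot allotment (largest remainder,
## minimum one per population), then an independent search inside each
## population; the reported objective is the global score of the union
.optimizeProportional <- function(x, size, wMr, wSh, restarts, maxIter,
                                  rngSeed, D) {
  pops <- populations(x)
  labs <- unique(pops)
  sizes <- as.integer(table(factor(pops, levels = labs)))
  raw <- sizes / sum(sizes) * size
  quota <- pmax(floor(raw), 1L)
  while (sum(quota) < size) {
    frac <- raw - quota
    frac[quota >= sizes] <- -Inf
    quota[which.max(frac)] <- quota[which.max(frac)] + 1L
    raw[which.max(frac)] <- quota[which.max(frac)]   # stop re-picking
  }
  while (sum(quota) > size) {
    over <- which(quota > 1L)
    k <- over[which.min((raw - quota)[over])]
    quota[k] <- quota[k] - 1L
  }
  quota <- pmin(quota, sizes)
  sel <- character(0)
  for (k in seq_along(labs)) {
    member <- names(pops)[pops == labs[k]]
    if (quota[k] >= length(member)) { sel <- c(sel, member); next }
    sub <- x[, member]
    if (quota[k] == 1L) {
      sel <- c(sel, stratifiedSeed(sub, D = D[member, member]))
      next
    }
    coK <- optimizeCore(sub, size = quota[k], wMr = wMr, wSh = wSh,
                        restarts = restarts, maxIter = maxIter,
                        rngSeed = rngSeed, D = D[member, member])
    sel <- c(sel, selectedIds(coK))
  }
  sel <- sort(sel, method = "radix")
  obj <- subsetObjective(x, sel, wMr, wSh, D = D)
  .coreSelection(x, sel, obj, c(mr = wMr, sh = wSh), obj)
}

.coreSelection <- function(x, sel, objective, weights, trace) {
  pops <- populations(x)
  counts <- integer(0)
  if (!is.null(pops)) {
    tab <- table(factor(pops[sel], levels = unique(pops)))
    counts <- setNames(as.integer(tab), names(tab))
  }
  new("CoreSelection", selected = sel, objective = objective,
      weights = weights, coverage = alleleCoverage(x, sel),
      perRegionCounts = counts, trace = as.numeric(trace))
}

#' Write a core selection as JSON
#'
#' @param core a [CoreSelection-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoreSelection <- function(core, path) {
  jsonlite::write_json(list(
    size = length(core@selected),
    objective = core@objective,
    weights = as.list(core@weights),
    coverage = core@coverage,
    per_region_counts = as.list(core@perRegionCounts),
    selected = core@selected), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
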