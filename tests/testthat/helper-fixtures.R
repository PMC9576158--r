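# Fixture builders and naive-loop oracles. Oracles are written as direct
# transcriptions of the definitions (explicit loops over genotypes) and stay
# independent of the package's vectorized / compiled implementations.

# small genotype object from an accessions-by-loci matrix (spec orientation)
toyGenotypes <- function(callsAccByLocus, populations = NULL,
                         ids = NULL, lociIds = NULL) {
  m <- as.matrix(callsAccByLocus)
  if (is.null(ids)) ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("acc%02d", seq_len(nrow(m)))
  if (is.null(lociIds)) lociIds <- colnames(m)
  if (is.null(lociIds)) lociIds <- sprintf("s%02d", seq_len(ncol(m)))
  d <- t(m)
  dimnames(d) <- list(lociIds, ids)
  if (!is.null(populations) && is.null(names(populations)))
    populations <- setNames(populations, ids)
  snpGenotypes(d, populations = populations)
}

# random matrix with missingness, accessions x loci
randomCalls <- function(n, l, missing = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(0:2, n * l, replace = TRUE), nrow = n)
  m[matrix(runif(n * l) < missing, nrow = n)] <- NA
  m
}

# ---- naive diversity oracle: explicit loops, one locus at a time ----------
oracleLocusStats <- function(callsAccByLocus) {
  m <- as.matrix(callsAccByLocus)
  out <- NULL
  for (j in seq_len(ncol(m))) {
    g <- m[, j]
    g <- g[!is.na(g)]
    n <- length(g)
    if (n == 0) {
      out <- rbind(out, data.frame(p = NA, maf = NA, nCalled = 0, ho = NA,
                                   he = NA, nei = NA, ne = NA, pic = NA,
                                   shannon = NA, na = NA))
      next
    }
    nAlt <- 0; nHet <- 0
    for (gg in g) { nAlt <- nAlt + gg; if (gg == 1) nHet <- nHet + 1 }
    p <- nAlt / (2 * n); q <- 1 - p
    he <- 1 - p^2 - q^2
    sh <- 0
    if (p > 0) sh <- sh - p * log(p)
    if (q > 0) sh <- sh - q * log(q)
    out <- rbind(out, data.frame(
      p = p, maf = min(p, q), nCalled = n, ho = nHet / n, he = he,
      nei = 2 * n / (2 * n - 1) * he, ne = 1 / (p^2 + q^2),
      pic = 1 - (p^2 + q^2) - 2 * p^2 * q^2, shannon = sh,
      na = if (p > 0 && p < 1) 2 else 1))
  }
  out
}

# ---- naive modified Rogers: loop over pairs and loci ----------------------
oracleModifiedRogers <- function(callsAccByLocus) {
  m <- as.matrix(callsAccByLocus)
  n <- nrow(m)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ss <- 0; cnt <- 0
    for (l in seq_len(ncol(m))) {
      if (!is.na(m[i, l]) && !is.na(m[j, l])) {
        ss <- ss + (m[i, l] - m[j, l])^2
        cnt <- cnt + 1
      }
    }
    D[i, j] <- sqrt(ss / (4 * cnt))
  }
  dimnames(D) <- list(rownames(m), rownames(m))
  D
}

# ---- naive Nei 1972 distance from two frequency vectors -------------------
oracleNeiD <- function(p1, p2) {
  jxy <- sum(p1 * p2 + (1 - p1) * (1 - p2))
  jx <- sum(p1^2 + (1 - p1)^2)
  jy <- sum(p2^2 + (1 - p2)^2)
  -log(jxy / sqrt(jx * jy))
}

# ---- exhaustive 4-taxon NJ check: best additive fit over the 3 topologies -
# for a 4-taxon tree ab|cd with branches (ea, eb, ec, ed, em) solve least
# squares against D and return the best topology and its branch lengths
oracleBestQuartet <- function(D) {
  labs <- rownames(D)
  tops <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (t in tops) {
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    # path-length design for pairs ab, ac, ad, bc, bd, cd
    X <- rbind(c(1, 1, 0, 0, 0), c(1, 0, 1, 0, 1), c(1, 0, 0, 1, 1),
               c(0, 1, 1, 0, 1), c(0, 1, 0, 1, 1), c(0, 0, 1, 1, 0))
    y <- c(D[a, b], D[a, c], D[a, d], D[b, c], D[b, d], D[c, d])
    beta <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% beta)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, split = sort(labs[c(a, b)]), branches = drop(beta))
  }
  best
}

# pairwise path lengths between leaves of a phylo tree
treeDistances <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

# ---- exhaustive core optimum: enumerate all subsets honouring the seeds ---
oracleBestCore <- function(g, size, seedIds, wMr = 0.7, wSh = 0.3) {
  ids <- accessionIds(g)
  D <- modifiedRogers(g)
  free <- setdiff(ids, seedIds)
  pick <- utils::combn(free, size - length(seedIds))
  bestObj <- -Inf; bestSet <- NULL
  for (k in seq_len(ncol(pick))) {
    s <- c(seedIds, pick[, k])
    o <- subsetObjective(g, s, wMr, wSh, D = D)
    if (o > bestObj) { bestObj <- o; bestSet <- sort(unname(s)) }
  }
  list(objective = bestObj, selected = bestSet)
}

# shoelace area of the convex hull of 2-column points
hullArea <- function(xy) {
  h <- grDevices::chull(xy)
  xy <- xy[h, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# mean silhouette width for a 2-group labelling on a distance matrix
meanSilhouette <- function(D, grp) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    a <- mean(D[i, grp == grp[i] & seq_len(n) != i])
    b <- mean(D[i, grp != grp[i]])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
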