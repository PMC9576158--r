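test_that("modified Rogers matches hand evaluation and analytic extremes", {
  # identical accessions -> 0; all-loci opposite homozygotes -> 1
  g <- toyGenotypes(rbind(c(0, 0), c(0, 0), c(2, 2), c(1, 2)),
                    ids = c("a", "b", "c", "d"))
  D <- modifiedRogers(g)
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], 1)
  # dosages (0,0) vs (1,2): sqrt((1 + 4) / 8)
  expect_equal(D["a", "d"], sqrt(5 / 8))
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("modified Rogers agrees with the naive pair loop and stays in [0,1]", {
  for (seed in 1:4) {
    m <- randomCalls(6, 12, missing = 0.2, seed = seed)
    D <- modifiedRogers(toyGenotypes(m))
    expect_equal(unname(D), unname(oracleModifiedRogers(m)), tolerance = 1e-12)
    expect_true(all(D >= 0 & D <= 1))
  }
})

test_that("modified Rogers is a metric on complete-data panels", {
  for (seed in 5:7) {
    m <- randomCalls(6, 10, missing = 0, seed = seed)
    D <- modifiedRogers(toyGenotypes(m))
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("accession pairs sharing no called locus are an error", {
  m <- rbind(c(1, NA), c(NA, 1), c(0, 0))
  expect_error(modifiedRogers(toyGenotypes(m)), "share no called locus")
})

test_that("Nei distance matches hand evaluation of the gene identity", {
  # single locus, p1 = 0.8, p2 = 0.3
  # I = 0.38 / sqrt(0.68 * 0.58), D = -ln I = 0.5024
  m <- rbind(c(2), c(2), c(1), c(2), c(1),     # 5 accessions, p = 0.8
             c(1), c(1), c(1), c(0), c(0))     # 5 accessions, p = 0.3
  g <- toyGenotypes(m, populations = rep(c("P1", "P2"), each = 5))
  D <- neiDistance(g)
  expect_equal(D["P1", "P2"], oracleNeiD(0.8, 0.3), tolerance = 1e-12)
  expect_equal(D["P1", "P2"], 0.5024, tolerance = 1e-4)
})

test_that("Nei distance is zero for identical profiles and capped at I = 0", {
  m <- rbind(c(0, 1), c(2, 1), c(0, 1), c(2, 1))
  g <- toyGenotypes(m, populations = c("A", "A", "B", "B"))
  expect_equal(neiDistance(g)["A", "B"], 0)
  m2 <- rbind(0, 0, 2, 2)
  g2 <- toyGenotypes(m2, populations = c("A", "A", "B", "B"))
  expect_warning(D2 <- neiDistance(g2, cap = 10), "capped")
  expect_equal(D2["A", "B"], 10)
})

test_that("Nei distance is invariant to swapping ref/alt at any locus", {
  m <- randomCalls(10, 8, missing = 0.1, seed = 21)
  pops <- rep(c("A", "B"), each = 5)
  D1 <- neiDistance(toyGenotypes(m, populations = pops))
  m2 <- m
  m2[, 3] <- 2 - m2[, 3]     # relabel alleles at locus 3
  m2[, 7] <- 2 - m2[, 7]
  D2 <- neiDistance(toyGenotypes(m2, populations = pops))
  expect_equal(D1, D2, tolerance = 1e-12)
})

test_that("three-taxon NJ solves the two-point equations", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighborJoining(D)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  pd <- treeDistances(tr)
  expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-9)
})

test_that("NJ recovers the additive quartet with exact branch lengths", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, dimnames = list(labs, labs))
  tr <- neighborJoining(D)
  # brute-force: best least-squares fit over all 3 quartet topologies
  best <- oracleBestQuartet(D)
  expect_equal(best$rss, 0, tolerance = 1e-18)
  expect_equal(best$split, c("A", "B"))
  split <- ape::prop.part(tr)
  pd <- treeDistances(tr)
  expect_equal(pd[labs, labs], D, tolerance = 1e-9)     # additive exactness
  # branch lengths (A:2, B:3, internal:1, C:4, D:5)
  expect_setequal(round(tr$edge.length, 9), c(2, 3, 1, 4, 5))
})

test_that("NJ is exact on random additive matrices from random trees", {
  for (seed in 1:4) {
    set.seed(seed)
    nt <- sample(5:8, 1)
    tr0 <- ape::rtree(nt, rooted = FALSE)
    tr0$edge.length <- runif(length(tr0$edge.length), 0.1, 2)
    D <- ape::cophenetic.phylo(tr0)
    tr <- neighborJoining(D)
    pd <- treeDistances(tr)
    expect_equal(pd[rownames(D), colnames(D)], D, tolerance = 1e-9)
    # topology identical to ape's NJ (independent implementation)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ape::nj(D))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("label permutation permutes the NJ tree without changing it", {
  m <- randomCalls(6, 20, missing = 0, seed = 31)
  D <- modifiedRogers(toyGenotypes(m))
  perm <- c(4, 1, 6, 2, 5, 3)
  t1 <- neighborJoining(D)
  t2 <- neighborJoining(D[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  d1 <- treeDistances(t1); d2 <- treeDistances(t2)
  expect_equal(d1[rownames(D), rownames(D)], d2[rownames(D), rownames(D)],
               tolerance = 1e-9)
})

test_that("equidistant matrices give a deterministic tie-broken tree", {
  labs <- c("a", "b", "c", "d")
  D <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(D) <- 0
  t1 <- neighborJoining(D)
  t2 <- neighborJoining(D)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  # the Q-tie resolves to the lexicographically smallest pair (a, b)
  expect_true(grepl("\\(a:[0-9.]+,b:", ape::write.tree(t1)) ||
              grepl("\\(b:[0-9.]+,a:", ape::write.tree(t1)))
  expect_error(neighborJoining(D[1:2, 1:2]), "at least 3")
})

test_that("negative NJ branch estimates are clamped with deficit moved", {
  # a near-degenerate matrix known to produce a negative branch estimate
  labs <- c("w", "x", "y", "z")
  D <- matrix(c(0, 0.1, 0.6, 0.6,
                0.1, 0, 0.7, 0.5,
                0.6, 0.7, 0, 0.1,
                0.6, 0.5, 0.1, 0), 4, dimnames = list(labs, labs))
  tr <- neighborJoining(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("tree cutting at a height threshold partitions the leaves", {
  txt <- "((a:0.01,b:0.01):0.5,(c:0.02,d:0.01):0.4,e:0.9);"
  tr <- ape::read.tree(text = txt)
  cl <- cutTreeHeight(tr, 0.05)
  expect_equal(length(cl), 5L)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_equal(cl[["c"]], cl[["d"]])
  expect_false(cl[["a"]] == cl[["c"]])
  expect_false(cl[["e"]] %in% c(cl[["a"]], cl[["c"]]))
  # cutting at a huge height keeps everything together
  expect_equal(length(unique(cutTreeHeight(tr, 10))), 1L)
})

test_that("PCA matches a brute-force eigendecomposition on a small panel", {
  m <- randomCalls(6, 8, missing = 0, seed = 13)
  g <- toyGenotypes(m)
  pc <- genoPCA(g, 3)
  A <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(A) / 1)      # oracle: eigen of the Gram matrix
  lam <- eigen(tcrossprod(A))$values
  vf <- lam[1:3] / sum(lam[lam > 1e-12])
  expect_equal(pc$varianceFraction, vf, tolerance = 1e-8)
  # scores equal projections up to sign
  pr <- A %*% eigen(crossprod(A))$vectors[, 1:3]
  for (k in 1:3)
    expect_equal(abs(unname(pc$scores[, k])), abs(unname(pr[, k])),
                 tolerance = 1e-8)
})

test_that("PCA of identical rows has zero variance fractions", {
  g <- toyGenotypes(matrix(1, nrow = 5, ncol = 6))
  pc <- genoPCA(g, 2)
  expect_equal(pc$varianceFraction, c(0, 0))
  expect_error(genoPCA(g, 0), "positive")
  expect_error(genoPCA(g, 99), "exceeds")
})

test_that("PC1 separates two strongly diverged simulated demes", {
  cfg <- simulationConfig(demeLabels = c("D1", "D2"), demeSizes = c(30L, 30L),
                          nLoci = 300L, fst = 0.3, rngSeed = 77)
  sim <- simulateGenotypes(cfg)
  pc <- genoPCA(sim$genotypes, 2)
  grp <- rep(c(1, 2), each = 30)
  d1 <- as.matrix(dist(pc$scores[, 1]))
  expect_gt(meanSilhouette(d1, grp), 0.5)
})
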