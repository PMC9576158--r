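test_that("stratified seeding picks one outlying accession per population", {
  cfg <- simulationConfig(demeLabels = c("A", "B", "C"),
                          demeSizes = c(6L, 5L, 1L), nLoci = 40L, rngSeed = 2)
  g <- simulateGenotypes(cfg)$genotypes
  s <- stratifiedSeed(g)
  expect_equal(length(s), 3L)
  expect_identical(unname(populations(g)[s]), c("A", "B", "C"))
  expect_identical(unname(s["C"]), "C_001")   # singleton population
  # the seed maximizes mean distance to its own deme
  D <- modifiedRogers(g)
  pops <- populations(g)
  for (lab in c("A", "B")) {
    member <- names(pops)[pops == lab]
    sc <- rowSums(D[member, member]) / (length(member) - 1)
    expect_equal(sc[[s[[lab]]]], max(sc))
  }
})

test_that("seed ties resolve to the lexicographically smallest id", {
  # two identical accessions in one population
  m <- rbind(c(0, 2), c(0, 2), c(1, 1))
  g <- toyGenotypes(m, populations = c("P", "P", "P"),
                    ids = c("a2", "a1", "a3"))
  s <- stratifiedSeed(g)
  # a1 and a2 are identical; a3 is farthest from both, so a3 wins alone;
  # drop a3 to force the tie
  g2 <- toyGenotypes(m[1:2, ], populations = c("P", "P"), ids = c("a2", "a1"))
  expect_identical(unname(stratifiedSeed(g2)), "a1")
  expect_identical(unname(s), "a3")
})

test_that("coverage ranking reproduces the hand greedy trace", {
  # locus 1 alleles A/a, locus 2 alleles B/b
  # acc1 carries {A, a, B}; acc2 {A, B}; acc3 {A, B, b}
  m <- rbind(acc1 = c(1, 0), acc2 = c(0, 0), acc3 = c(0, 1))
  cr <- coverageRanking(toyGenotypes(m))
  expect_identical(cr$accession, c("acc1", "acc3", "acc2"))
  expect_equal(cr$coverage[2], 1)
  expect_equal(cr$coverage[3], 1)
})

test_that("coverage curve is monotone, ends at 1, and handles degenerate data", {
  g <- toyGenotypes(randomCalls(15, 30, missing = 0.1, seed = 5))
  cr <- coverageRanking(g)
  expect_true(all(diff(cr$coverage) >= -1e-12))
  expect_equal(cr$coverage[nrow(cr)], 1)
  # identical homozygotes: full coverage at k = 1
  g2 <- toyGenotypes(matrix(2, 4, 6))
  cr2 <- coverageRanking(g2)
  expect_equal(cr2$coverage[1], 1)
})

test_that("greedy coverage achieves the (1 - 1/e) guarantee on small panels", {
  m <- randomCalls(8, 10, missing = 0.2, seed = 17)
  g <- toyGenotypes(m)
  cr <- coverageRanking(g)
  for (k in 1:4) {
    subs <- utils::combn(accessionIds(g), k)
    opt <- max(apply(subs, 2, function(s) alleleCoverage(g, s)))
    expect_gte(cr$coverage[k], (1 - exp(-1)) * opt - 1e-12)
  }
})

test_that("subset objective reduces correctly at its edge cases", {
  m <- rbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(2, 1, 0))
  g <- toyGenotypes(m)
  D <- modifiedRogers(g)
  # identical pair: MR term zero, score = wSh x Shannon term
  o <- subsetObjective(g, c("a", "b"), wMr = 0.7, wSh = 0.3, D = D)
  o10 <- subsetObjective(g, c("a", "b"), wMr = 1, wSh = 0, D = D)
  expect_equal(o10, 0)
  expect_equal(subsetObjective(g, c("a", "c"), wMr = 1, wSh = 0, D = D),
               D["a", "c"])
  expect_error(subsetObjective(g, "a", D = D), "at least 2")
  expect_error(subsetObjective(g, c("a", "b"), wMr = 0.9, wSh = 0.3, D = D),
               "sum to 1")
  expect_gt(o, 0)
})

test_that("subset objective matches a hand-computed weighted sum", {
  m <- rbind(w = c(0, 0, 1), x = c(1, 2, 1), y = c(2, 2, 0), z = c(0, 1, 1))
  g <- toyGenotypes(m)
  S <- c("w", "x", "y")
  Do <- oracleModifiedRogers(m[S, ])
  mr <- mean(Do[upper.tri(Do)])
  # pooled Shannon: per-locus allele frequencies within S
  p <- colSums(m[S, ]) / (2 * 3)
  iL <- vapply(p, function(pp) {
    s <- 0
    if (pp > 0) s <- s - pp * log(pp)
    if (pp < 1) s <- s - (1 - pp) * log(1 - pp)
    s
  }, numeric(1))
  sh <- (mean(iL) + log(3)) / log(6)
  expect_equal(subsetObjective(g, S, 0.7, 0.3),
               0.7 * mr + 0.3 * sh, tolerance = 1e-12)
})

test_that("optimizer attains the exhaustively enumerated optimum (N=10, k=4)", {
  cfg <- simulationConfig(demeLabels = c("A", "B"), demeSizes = c(5L, 5L),
                          nLoci = 25L, missingRate = 0.05, rngSeed = 9)
  g <- simulateGenotypes(cfg)$genotypes
  seedIds <- stratifiedSeed(g)
  best <- oracleBestCore(g, 4, seedIds)
  co <- optimizeCore(g, size = 4, restarts = 3, rngSeed = 1)
  expect_equal(co@objective, best$objective, tolerance = 1e-10)
  expect_identical(selectedIds(co), best$selected)
  expect_true(all(seedIds %in% selectedIds(co)))
})

test_that("optimizer honours trivial sizes and determinism", {
  cfg <- simulationConfig(demeLabels = c("A", "B"), demeSizes = c(4L, 4L),
                          nLoci = 20L, rngSeed = 4)
  g <- simulateGenotypes(cfg)$genotypes
  all8 <- optimizeCore(g, size = 8)
  expect_identical(selectedIds(all8), sort(accessionIds(g), method = "radix"))
  expect_error(optimizeCore(g, size = 1), "population")
  a <- optimizeCore(g, size = 4, restarts = 4, rngSeed = 42)
  b <- optimizeCore(g, size = 4, restarts = 4, rngSeed = 42)
  expect_identical(selectedIds(a), selectedIds(b))
  expect_identical(a@objective, b@objective)
})

test_that("accepted-move trace is monotone and final beats the greedy start", {
  cfg <- simulationConfig(demeLabels = c("A", "B", "C"),
                          demeSizes = c(10L, 10L, 10L), nLoci = 60L,
                          rngSeed = 6)
  g <- simulateGenotypes(cfg)$genotypes
  co <- optimizeCore(g, size = 9, restarts = 1, rngSeed = 1)
  expect_true(all(diff(co@trace) > 0 | length(co@trace) == 1))
  expect_gte(co@objective, co@trace[1])
  expect_equal(sum(co@perRegionCounts), coreSize(co))
})

test_that("optimized cores beat random subsets in allele coverage on average", {
  covOpt <- covRnd <- numeric(10)
  for (r in 1:10) {
    cfg <- simulationConfig(demeLabels = c("A", "B"), demeSizes = c(12L, 12L),
                            nLoci = 80L, rngSeed = 100 + r)
    g <- simulateGenotypes(cfg)$genotypes
    co <- optimizeCore(g, size = 6, rngSeed = r)
    covOpt[r] <- co@coverage
    set.seed(r)
    covRnd[r] <- mean(replicate(5, alleleCoverage(
      g, sample(accessionIds(g), 6))))
  }
  expect_gte(mean(covOpt), mean(covRnd))
})

test_that("nearest-entry aggregation and proportional allocation behave", {
  cfg <- simulationConfig(demeLabels = c("A", "B", "C"),
                          demeSizes = c(12L, 6L, 3L), nLoci = 50L,
                          rngSeed = 14)
  g <- simulateGenotypes(cfg)$genotypes
  D <- modifiedRogers(g)
  S <- accessionIds(g)[c(1, 2, 13, 20)]
  sub <- D[S, S]
  diag(sub) <- Inf
  oNear <- subsetObjective(g, S, wMr = 1, wSh = 0, D = D,
                           mrAggregate = "nearest")
  expect_equal(oNear, mean(apply(sub, 1, min)))
  # nearest-entry never exceeds mean-pairwise
  expect_lte(oNear, subsetObjective(g, S, wMr = 1, wSh = 0, D = D))

  co <- optimizeCore(g, size = 7, rngSeed = 1, allocation = "proportional")
  expect_equal(coreSize(co), 7L)
  # quotas proportional to deme sizes (12:6:3 -> 4:2:1), every region kept
  expect_equal(unname(co@perRegionCounts), c(4L, 2L, 1L))
  co2 <- optimizeCore(g, size = 7, rngSeed = 1, allocation = "proportional")
  expect_identical(selectedIds(co), selectedIds(co2))
})
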