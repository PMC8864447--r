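test_that("edge weights are the unit-max to vertex-rate ratio with an epsilon floor", {
  rates <- rbind(c(10, 50, 0), c(20, 100, 5))
  g <- buildGraph(ratePSTH(rates, binMs = 1), epsilon = 1e-3)
  expect_equal(g$w[2, 2], 1) # the unit-max vertex costs 1 to enter
  expect_equal(g$w[1, 2], 2)
  expect_equal(g$w[1, 3], 100 / 1e-3) # zero-rate vertex: finite floor
  expect_true(all(is.finite(g$w)) && all(g$w > 0))
})

test_that("the primary path follows a bright column and uniform grids cost Z", {
  # middle column dominant: every path vertex sits at t = 2
  rates <- matrix(1, 3, 3)
  rates[, 2] <- 100
  paths <- kDisjointShortestPaths(buildGraph(ratePSTH(rates)), k = 1)
  expect_identical(unique(paths[[1]]@vertices$t), 2L)
  expect_identical(sort(paths[[1]]@vertices$z), 1:3)

  # uniform rates: shortest vertex count wins, one vertex per row at weight 1
  pu <- kDisjointShortestPaths(buildGraph(ratePSTH(matrix(7, 4, 6))), k = 1)
  expect_equal(pu[[1]]@totalWeight, 4)
  expect_identical(nrow(pu[[1]]@vertices), 4L)
})

test_that("successive paths are vertex-disjoint and exhaustion returns fewer", {
  # two bright columns 10 bins apart: ranks 1-2 trace them disjointly
  rates <- matrix(1, 5, 20)
  rates[, 5] <- 100
  rates[, 15] <- 80
  paths <- kDisjointShortestPaths(buildGraph(ratePSTH(rates)), k = 3)
  expect_identical(unique(paths[[1]]@vertices$t), 5L)
  expect_identical(unique(paths[[2]]@vertices$t), 15L)
  keys <- lapply(paths, function(p) paste(p@vertices$z, p@vertices$t))
  expect_identical(length(unique(unlist(keys))), length(unlist(keys)))

  # a 2x2 grid cannot host 3 disjoint paths
  p22 <- kDisjointShortestPaths(buildGraph(ratePSTH(matrix(5, 2, 2))), k = 3)
  expect_lt(length(p22), 3L)
  expect_gte(length(p22), 1L)

  # an all-zero unit yields no paths at all
  expect_identical(kDisjointShortestPaths(buildGraph(ratePSTH(matrix(0, 3, 4)))),
                   list())
})

test_that("primary path weight matches brute-force enumeration on random grids", {
  set.seed(2024)
  for (i in 1:20) {
    Z <- sample(2:4, 1)
    B <- sample(3:8, 1)
    rates <- matrix(rexp(Z * B, 0.02), Z, B)
    g <- buildGraph(ratePSTH(rates))
    p1 <- kDisjointShortestPaths(g, k = 1)[[1]]
    expect_equal(p1@totalWeight, shortestPathOracle(g$w), tolerance = 1e-9)
  }
})

test_that("path weight is anti-monotone in vertex rates", {
  set.seed(31)
  rates <- matrix(rexp(4 * 8, 0.02), 4, 8)
  base <- kDisjointShortestPaths(buildGraph(ratePSTH(rates)), k = 1)[[1]]
  # raising a non-path vertex's rate never worsens the optimum
  off <- which(!(paste(rep(1:4, 8), rep(1:8, each = 4)) %in%
                 paste(base@vertices$z, base@vertices$t)))[1]
  up <- rates
  up[off] <- up[off] + 50
  pUp <- kDisjointShortestPaths(buildGraph(ratePSTH(up)), k = 1)[[1]]
  expect_lte(pUp@totalWeight, base@totalWeight + 1e-9)
  # cutting a path vertex's rate never improves it
  v <- base@vertices[2, ]
  down <- rates
  down[v$z, v$t] <- down[v$z, v$t] / 10
  pDown <- kDisjointShortestPaths(buildGraph(ratePSTH(down)), k = 1)[[1]]
  expect_gte(pDown@totalWeight, base@totalWeight - 1e-9)
})

test_that("path features report lattice medians and non-stationarity", {
  vertical <- data.frame(z = 1:10, t = 14L, rate = 50)
  f <- pathFeatures(vertical)
  expect_equal(f$medianTime, 14)
  expect_equal(f$nonstationarityMs, 0)

  diagonal <- data.frame(z = 1:10, t = (1:10) + 9L, rate = 50)
  expect_equal(pathFeatures(diagonal)$nonstationarityMs, 9)

  # 0.25 bins/row realized on the lattice: quantized shifts give 2 ms span
  lattice <- data.frame(z = 1:10, t = 10L + round(0.25 * (0:9)), rate = 50)
  expect_equal(pathFeatures(lattice)$nonstationarityMs, 2)

  # per-row rates on a programmed slope recover the slope sign
  sloped <- data.frame(z = 1:10, t = 12L, rate = 100 + 5 * (0:9))
  fr <- pathFeatures(sloped)$perRow
  expect_gt(coef(lm(fr$rate ~ fr$z))[2], 0)
})

test_that("path rate correlations detect aligned and opposing intensity profiles", {
  mk <- function(rates) new("ComponentPath", rank = 1L,
    vertices = data.frame(z = seq_along(rates), t = 10L, rate = rates),
    totalWeight = 1, medianTime = 10,
    perRow = data.frame(z = seq_along(rates), time = 10L, rate = rates),
    nonstationarityMs = 0)
  a <- mk(seq(10, 100, by = 10))
  expect_equal(pathRateCorrelation(a, a)$r, 1)
  b <- mk(seq(100, 10, by = -10))
  expect_equal(pathRateCorrelation(a, b)$r, -1)
  short <- mk(c(5, 6))
  expect_false(pathRateCorrelation(a, short)$computable)
})

test_that("opposing programmed slopes give a negative path correlation", {
  # Two components whose amplitudes change in opposite directions with
  # intensity. Per-row path rates come from single 1-ms bins, so their
  # Poisson noise (sd ~ sqrt(lambda / (n_trials * 1 ms))) swamps weak slopes
  # at low trial counts; the opposing-profile signature is tested where the
  # correlation has power: +/-20 Hz/step over 10 intensities at 200 trials.
  hits <- 0
  for (i in 1:20) {
    spec <- syntheticUnitSpec(sprintf("op%d", i),
      componentTimes = c(12.3, 26.6), peakRates = c(120, 300),
      rateSlopes = c(20, -20), latencyShifts = c(0, 0), baselineRate = 2,
      nIntensities = 10, nTrials = 200, seed = 5000 + i)
    res <- graphComponents(buildPSTH(generateUnit(spec)$raster), k = 2)
    cr <- res$correlations
    if (nrow(cr) == 1L && isTRUE(cr$computable) && cr$r < 0 && cr$p < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 16)
})
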