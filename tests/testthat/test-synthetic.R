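test_that("the trapezoid waveform has the programmed ramp, hold and release", {
  w <- basicWaveform(400)
  s <- w@samples
  expect_equal(s$amplitude_mm[s$time_ms == 0], 0)
  expect_equal(max(s$amplitude_mm), 3.6)
  # 3.6 mm / 400 mm/s = 9 ms on-ramp
  expect_equal(s$amplitude_mm[s$time_ms == 9], 3.6)
  expect_lt(s$amplitude_mm[s$time_ms == 8.5], 3.6)
  # hold for 20 ms then a 40-ms off-ramp
  expect_equal(s$amplitude_mm[s$time_ms == 29], 3.6)
  expect_equal(max(s$time_ms), 9 + 20 + 40)
  expect_equal(s$amplitude_mm[s$time_ms == max(s$time_ms)], 0)

  # 30 mm/s: 120-ms ramp, far beyond the 50-ms analysis window, still emitted
  w30 <- basicWaveform(30)
  expect_equal(max(w30@samples$time_ms), 120 + 60)
  expect_error(basicWaveform(0), "positive")
})

test_that("the contact proxy lasts 100 ms, starts at rest and scales linearly", {
  w1 <- contactWaveform(1)
  expect_equal(range(w1@samples$time_ms), c(0, 100))
  expect_equal(w1@samples$amplitude_mm[1], 0)
  expect_equal(max(w1@samples$amplitude_mm), 1)
  w2 <- contactWaveform(2)
  expect_equal(w2@samples$amplitude_mm, 2 * w1@samples$amplitude_mm)
})

test_that("a baseline-only unit fires at the programmed baseline rate", {
  spec <- syntheticUnitSpec("base", baselineRate = 20, nIntensities = 5,
                            nTrials = 20, seed = 9)
  p <- buildPSTH(generateUnit(spec)$raster)
  # grand mean rate within 3 SE of baseline (Poisson counts over all cells)
  nCells <- 5 * 50 * 20
  grand <- mean(psthRates(p))
  expect_lt(abs(grand - 20), 3 * sqrt(20 / 0.001 / nCells))
})

test_that("component spike counts follow the Poisson mean", {
  spec <- syntheticUnitSpec("pois", componentTimes = 25.3, peakRates = 100,
    rateSlopes = 0, latencyShifts = 0, componentWidth = 1, baselineRate = 0,
    nIntensities = 1, nTrials = 20, seed = 33)
  gen <- generateUnit(spec)
  lam <- unitLambda(spec)
  expectedCount <- sum(lam) * 0.001 * 20
  observed <- nrow(gen$raster@events)
  expect_lt(abs(observed - expectedCount), 3 * sqrt(expectedCount))
})

test_that("latency shifts move true component times by the closed form", {
  spec <- syntheticUnitSpec("shift", componentTimes = 20, peakRates = 100,
    rateSlopes = 0, latencyShifts = 0.5, baselineRate = 0, nIntensities = 10,
    nTrials = 5, seed = 2)
  gt <- generateUnit(spec)$groundTruth
  expect_equal(gt$true_time_ms[gt$intensity == 10], 20 - 0.5 * 9)
  expect_equal(unique(gt$true_nonstationarity_ms), 4.5)
  # the rate surface peaks at the shifted bin in the last row
  lam <- unitLambda(spec)
  expect_equal(which.max(lam[10, ]), 16) # mu = 15.5 lies in bin 16
  expect_error(
    syntheticUnitSpec("bad", componentTimes = 3, peakRates = 10,
                      rateSlopes = 0, latencyShifts = 0.5, nIntensities = 10),
    "before stimulus onset"
  )
})

test_that("generation is deterministic and leaves the caller's RNG alone", {
  spec <- syntheticUnitSpec("det", componentTimes = 15, peakRates = 150,
    rateSlopes = 2, latencyShifts = 0.2, baselineRate = 5, nIntensities = 5,
    nTrials = 10, seed = 123)
  g1 <- generateUnit(spec)
  set.seed(555)
  before <- runif(3)
  set.seed(555)
  g2 <- generateUnit(spec)
  after <- runif(3)
  expect_identical(g1$raster@events, g2$raster@events)
  expect_identical(before, after)

  f1 <- tempfile()
  f2 <- tempfile()
  writeRaster(g1$raster, f1)
  writeRaster(g2$raster, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the empirical PSTH converges to the programmed rate surface", {
  spec <- syntheticUnitSpec("conv", componentTimes = 20.4, peakRates = 90,
    rateSlopes = 0, latencyShifts = 0.3, componentWidth = 1, baselineRate = 10,
    nIntensities = 3, nTrials = 500, seed = 8)
  p <- buildPSTH(generateUnit(spec)$raster)
  lam <- unitLambda(spec)
  # every bin within 5 standard errors of its Poisson mean, grand mean within 3
  se <- sqrt(pmax(lam, 1e-6) / (500 * 0.001))
  z <- (psthRates(p) - lam) / se
  expect_lt(max(abs(z)), 5)
  seMean <- sqrt(sum(lam / (500 * 0.001))) / length(lam)
  expect_lt(abs(mean(psthRates(p)) - mean(lam)) / seMean, 3)
})

test_that("largest-remainder allocation is exact and deterministic", {
  expect_identical(largestRemainder(c(0.5, 0.5, 0, 0), 10), c(5L, 5L, 0L, 0L))
  expect_identical(largestRemainder(c(0.4, 0.3, 0.2, 0.1), 10), c(4L, 3L, 2L, 1L))
  expect_identical(sum(largestRemainder(c(1, 2, 4) / 7, 23)), 23L)
  set.seed(6)
  for (i in 1:25) {
    p <- runif(4)
    p <- p / sum(p)
    n <- sample(1:200, 1)
    alloc <- largestRemainder(p, n)
    expect_identical(sum(alloc), n)
    expect_true(all(abs(alloc - p * n) < 1))
  }
})

test_that("population generation honours proportions, timing model and coverage", {
  pop <- populationSpec(
    cells = data.frame(layer = "IV", condition = "sham", stimulus = "contact",
                       nUnits = 20L, p0 = 0.5, p1 = 0.5, p2 = 0, p3 = 0),
    masterSeed = 77L
  )
  gen <- generatePopulation(pop)
  cats <- vapply(gen$specs, function(s) s$nComponents, integer(1))
  expect_identical(sum(cats == 0L), 10L) # exactly half non-responders
  expect_identical(length(gen$rasters), 20L)
  # ground truth covers every emitted raster, no orphans
  expect_setequal(unique(gen$groundTruth$unit_id), names(gen$rasters))

  # noiseless timing model: second = first + 10 exactly in the ground truth
  popT <- populationSpec(
    cells = data.frame(layer = "II", condition = "sham", stimulus = "basic",
                       nUnits = 8L, p0 = 0, p1 = 0, p2 = 1, p3 = 0),
    timing = list(a = 10, b = 1, sigma = 0), minSeparation = 8,
    masterSeed = 3L
  )
  genT <- generatePopulation(popT)
  for (s in genT$specs)
    expect_equal(s$componentTimes[2], s$componentTimes[1] + 10)

  # determinism: identical reruns byte for byte
  gen2 <- generatePopulation(populationSpec(
    cells = data.frame(layer = "IV", condition = "sham", stimulus = "contact",
                       nUnits = 20L, p0 = 0.5, p1 = 0.5, p2 = 0, p3 = 0),
    masterSeed = 77L
  ))
  expect_identical(gen$groundTruth, gen2$groundTruth)
  expect_identical(gen$rasters[[3]]@events, gen2$rasters[[3]]@events)
})

test_that("independent per-component shifts are available behind sharedShift", {
  pop <- populationSpec(
    cells = data.frame(layer = "IV", condition = "sham", stimulus = "contact",
                       nUnits = 12L, p0 = 0, p1 = 0, p2 = 1, p3 = 0),
    sharedShift = FALSE, masterSeed = 5L
  )
  gen <- generatePopulation(pop)
  shiftPairs <- t(vapply(gen$specs, function(s) s$latencyShifts, numeric(2)))
  expect_gt(nrow(unique(shiftPairs)), 1)
  expect_true(any(shiftPairs[, 1] != shiftPairs[, 2]))
})
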