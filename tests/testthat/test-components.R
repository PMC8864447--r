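test_that("local maxima are strict interior peaks with the plateau-median rule", {
  expect_identical(localMaxima(numeric(50)), integer(0))
  expect_identical(localMaxima(rowWithPeaks(3, 5, B = 10)), 3L)
  expect_identical(localMaxima(c(0, 4, 4, 4, 0, 0)), 3L) # plateau median
  expect_identical(localMaxima(c(0, 4, 4, 0)), 2L) # even plateau: lower median
  # endpoints are never maxima, even when they dominate
  expect_identical(localMaxima(c(9, 1, 0, 1, 9)), integer(0))
  # plateau touching an edge has no flank and yields nothing
  expect_identical(localMaxima(c(4, 4, 1, 0)), integer(0))
  expect_identical(localMaxima(c(1, 2, 5, 2, 7, 1)), c(3L, 5L))
})

test_that("the 25%-of-max filter removes only weak maxima with silent neighbours", {
  row <- rowWithPeaks(c(10, 20, 30), c(100, 20, 20))
  row[29] <- 5 # bin 30's left neighbour is active
  lm <- localMaxima(row)
  expect_setequal(lm, c(10L, 20L, 30L))
  kept <- filterMaxima(lm, row)
  expect_true(10L %in% kept) # the row max is always kept
  expect_false(20L %in% kept) # 20 < 25 and neighbours silent
  expect_true(30L %in% kept) # weak but neighbour is non-zero
  # at exactly the threshold the maximum is kept (< is strict)
  row2 <- rowWithPeaks(c(10, 20), c(100, 25))
  expect_setequal(filterMaxima(localMaxima(row2), row2), c(10L, 20L))
})

test_that("iterative nearest-pair merging reproduces hand traces", {
  expect_equal(mergeMaxima(c(10, 30)), c(10, 30))
  expect_equal(mergeMaxima(c(10, 12, 30)), c(11, 30))
  # nearest pair first: (13,15) -> 14, then (10,14) -> 12
  expect_equal(mergeMaxima(c(10, 13, 15)), 12)
  expect_equal(mergeMaxima(numeric(0)), numeric(0))
  expect_equal(mergeMaxima(17), 17)
})

test_that("merging is permutation-invariant, idempotent and range-bounded", {
  set.seed(404)
  for (i in 1:50) {
    bins <- sample.int(50, sample(1:12, 1))
    merged <- mergeMaxima(bins)
    expect_equal(mergeMaxima(bins[sample.int(length(bins))]), merged)
    expect_equal(mergeMaxima(merged), merged) # separations now all > 5
    if (length(merged) > 1L) expect_true(all(diff(merged) > 5))
    expect_true(all(merged >= min(bins) & merged <= max(bins)))
  }
})

test_that("merging agrees with the exhaustive nearest-pair oracle", {
  set.seed(99)
  for (i in 1:100) {
    bins <- sample.int(50, sample(1:12, 1), replace = TRUE)
    expect_identical(mergeMaxima(bins), mergeOracle(bins))
  }
})

test_that("unit components pool per-intensity maxima into categories", {
  # all-zero PSTH: non-responder
  cs0 <- unitComponents(ratePSTH(matrix(0, 5, 50)))
  expect_identical(componentCategory(cs0), "0")
  expect_identical(nComponents(cs0), 0L)

  # per-intensity maxima {10},{11},{12},{11},{10} pool to a single component at 11
  cs1 <- unitComponents(noiselessPSTH(list(10, 11, 12, 11, 10)))
  expect_equal(componentTimes(cs1), 11)
  expect_identical(componentSupport(cs1), 5L)
  expect_identical(componentCategory(cs1), "1")

  # two programmed bumps 9 ms apart, noiseless: category 2, both exact
  cs2 <- unitComponents(noiselessPSTH(lapply(1:5, function(z) c(15, 24))))
  expect_equal(componentTimes(cs2), c(15, 24))
  expect_identical(componentCategory(cs2), "2")

  # minSupport drops clusters backed by a single intensity
  psth3 <- noiselessPSTH(list(c(10), c(10), c(10), c(10), c(40)))
  expect_equal(componentTimes(unitComponents(psth3)), c(10, 40))
  expect_equal(componentTimes(unitComponents(psth3, minSupport = 2)), 10)
})

test_that("unit-level component times stay within the contributing maxima range", {
  set.seed(15)
  for (i in 1:20) {
    Z <- sample(3:10, 1)
    bins <- lapply(seq_len(Z), function(z) sort(sample.int(50, sample(0:3, 1))))
    if (sum(lengths(bins)) == 0L) next
    cs <- unitComponents(noiselessPSTH(bins, amp = 100))
    contributed <- unlist(cs@perIntensityMaxima)
    if (length(componentTimes(cs)) > 0L) {
      expect_true(all(componentTimes(cs) >= min(contributed)))
      expect_true(all(componentTimes(cs) <= max(contributed)))
    }
  }
})

test_that("category labels partition units by component count", {
  expect_identical(classifyComponents(0L), "0")
  expect_identical(classifyComponents(2L), "2")
  expect_identical(classifyComponents(4L), "3plus")
  cs <- unitComponents(noiselessPSTH(lapply(1:5, function(z) c(8, 18, 28, 40))))
  expect_identical(componentCategory(cs), "3plus")
  expect_identical(nComponents(cs), 4L)
})

test_that("noiseless programmed units are recovered exactly through the raster path", {
  # two components >= 8 ms apart, no baseline, no trial noise beyond Poisson at
  # high rate: category and times recovered through generateUnit -> buildPSTH
  spec <- syntheticUnitSpec("clean", componentTimes = c(12.4, 23.4),
    peakRates = c(400, 400), rateSlopes = c(0, 0), latencyShifts = c(0.5, 0.5),
    componentWidth = 0.6, baselineRate = 0, nIntensities = 10, nTrials = 50,
    seed = 77)
  cs <- unitComponents(buildPSTH(generateUnit(spec)$raster), minSupport = 5)
  expect_identical(componentCategory(cs), "2")
  # lattice time of the pooled component: median row time within 1 ms of
  # tau - s * (Z-1)/2
  expect_lt(abs(componentTimes(cs)[1] - (12.4 - 0.5 * 4.5)), 1.5)
  expect_lt(abs(componentTimes(cs)[2] - (23.4 - 0.5 * 4.5)), 1.5)
})
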