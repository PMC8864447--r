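test_that("two-sample KS behaves at the identities and detects shifts", {
  x <- c(1, 2, 3, 4, 5)
  same <- ksTwoSample(x, x)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  disjoint <- ksTwoSample(rep(0, 10), rep(1, 10))
  expect_equal(disjoint$D, 1)

  set.seed(88)
  a <- rnorm(100)
  b <- rnorm(100, mean = 2)
  shifted <- ksTwoSample(a, b)
  # cross-check against a direct ks.test call on the same data
  ref <- stats::ks.test(a, b)
  expect_equal(shifted$D, unname(ref$statistic))
  expect_lt(shifted$p, 0.001)
  expect_error(ksTwoSample(numeric(), 1), "non-empty")
})

test_that("timing regression recovers exact and noisy linear relations", {
  first <- c(8, 12, 16, 20)
  exact <- timingRegression(first, 10 + first)
  expect_equal(exact$intercept, 10)
  expect_equal(exact$slope, 1)
  expect_equal(exact$interceptSE, 0)
  expect_equal(exact$slopeSE, 0)
  expect_true(exact$significant)

  set.seed(19)
  f <- runif(40, 8, 20)
  s <- 10 + f + rnorm(40, 0, 2)
  fit <- timingRegression(f, s)
  expect_lt(abs(fit$intercept - 10), 2 * fit$interceptSE)
  expect_lt(fit$p, 0.001)

  expect_false(timingRegression(c(1, 2), c(3, 4))$computable)
})

test_that("shuffling the pairing destroys the timing relation", {
  set.seed(23)
  f <- runif(30, 8, 20)
  s <- 10 + f + rnorm(30, 0, 1)
  insignificant <- 0
  for (i in 1:20) {
    fit <- timingRegression(f, s[sample.int(30)])
    if (fit$p >= 0.05) insignificant <- insignificant + 1
  }
  expect_gte(insignificant, 18)
})

test_that("category proportions normalize per cell and recover programmed mixes", {
  one <- data.frame(layer = "II", condition = "sham", stimulus = "basic",
                    category = rep("2", 7))
  tab1 <- categoryProportions(one)
  expect_equal(tab1$prop_2, 1)
  expect_equal(tab1$prop_0 + tab1$prop_1 + tab1$prop_2 + tab1$prop_3plus, 1)

  # deterministic allocation makes recovery exact at the generator level
  pop <- populationSpec(
    cells = data.frame(layer = "IV", condition = "sham", stimulus = "contact",
                       nUnits = 10L, p0 = 0.4, p1 = 0.3, p2 = 0.2, p3 = 0.1),
    masterSeed = 31L
  )
  gen <- generatePopulation(pop)
  units <- data.frame(
    layer = "IV", condition = "sham", stimulus = "contact",
    category = vapply(gen$specs, function(s) classifyComponents(s$nComponents),
                      character(1))
  )
  tab <- categoryProportions(units)
  expect_equal(unlist(tab[, c("prop_0", "prop_1", "prop_2", "prop_3plus")],
                      use.names = FALSE),
               c(0.4, 0.3, 0.2, 0.1))

  set.seed(10)
  many <- data.frame(
    layer = sample(c("II", "IV"), 120, TRUE),
    condition = sample(c("sham", "tbi_4d"), 120, TRUE),
    stimulus = "basic",
    category = sample(c("0", "1", "2", "3plus"), 120, TRUE)
  )
  tabM <- categoryProportions(many)
  expect_true(all(abs(rowSums(tabM[, c("prop_0", "prop_1", "prop_2",
                                       "prop_3plus")]) - 1) < 1e-12))
})

test_that("pairwise category comparisons report KS and chi-square p-values", {
  set.seed(12)
  units <- rbind(
    data.frame(layer = "II", condition = "sham", stimulus = "basic",
               category = sample(c("0", "1"), 60, TRUE, prob = c(0.8, 0.2))),
    data.frame(layer = "IV", condition = "sham", stimulus = "basic",
               category = sample(c("2", "3plus"), 60, TRUE))
  )
  cmp <- categoryComparisons(units)
  expect_identical(nrow(cmp), 1L)
  expect_equal(cmp$D, 1) # supports are disjoint
  expect_lt(cmp$p_ks, 0.001)
  expect_lt(cmp$p_chisq, 0.001)
  # cells differing in both layer and condition are not compared
  units2 <- rbind(
    data.frame(layer = "II", condition = "sham", stimulus = "basic", category = "1"),
    data.frame(layer = "IV", condition = "tbi_4d", stimulus = "basic", category = "1")
  )
  expect_identical(nrow(categoryComparisons(units2)), 0L)
})

test_that("non-stationarity distributions bin to 0-5+ ms with pairwise KS", {
  stationary <- data.frame(layer = "II", condition = "sham",
                           nonstationarity_ms = rep(0, 12))
  nsd <- nonstationarityDistribution(stationary)
  expect_equal(nsd$histogram$prop_0, 1)

  mixed <- rbind(
    data.frame(layer = "II", condition = "sham",
               nonstationarity_ms = c(0, 1, 2, 2, 3, 7, 9)),
    data.frame(layer = "IV", condition = "sham",
               nonstationarity_ms = c(0, 1, 2, 2, 3, 7, 9))
  )
  nsd2 <- nonstationarityDistribution(mixed)
  hist2 <- nsd2$histogram
  expect_equal(hist2$prop_2[1], 2 / 7)
  expect_equal(hist2$prop_5plus[1], 2 / 7)
  # identical groups: D = 0, p = 1
  expect_equal(nsd2$comparisons$D, 0)
  expect_equal(nsd2$comparisons$p, 1)
})

test_that("first/second extraction feeds grouped regressions like the tables", {
  comp <- rbind(
    data.frame(unit_id = sprintf("a%d", 1:5), layer = "II", condition = "sham",
               stimulus = "basic", category = "2", component_index = 1L,
               component_time_ms = c(10, 12, 14, 16, 18),
               supporting_intensities = 5L),
    data.frame(unit_id = sprintf("a%d", 1:5), layer = "II", condition = "sham",
               stimulus = "basic", category = "2", component_index = 2L,
               component_time_ms = c(20, 22, 24, 26, 28),
               supporting_intensities = 5L),
    data.frame(unit_id = "solo", layer = "II", condition = "sham",
               stimulus = "basic", category = "1", component_index = 1L,
               component_time_ms = 9, supporting_intensities = 5L)
  )
  fs <- firstSecondTimes(comp)
  expect_identical(nrow(fs), 5L) # the single-component unit is excluded
  tab <- timingRegressionTable(comp)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$intercept, 10)
  expect_equal(tab$slope, 1)
})
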