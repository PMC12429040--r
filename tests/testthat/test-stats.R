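test_that("moving average emits full-window means only", {
  expect_equal(movingAverage(rep(3, 20), 15), rep(3, 6))
  expect_equal(movingAverage(1:20, 15)[1], 8)      # mean(1:15)
  expect_equal(movingAverage(1:20, 15), 8:13)
  expect_equal(movingAverage(1:10, 10), 5.5)       # w = length: global mean
  expect_error(movingAverage(1:5, 6), "exceeds")
  expect_error(movingAverage(1:5, 0), ">= 1")
})

test_that("lag-1 autocorrelation matches direct evaluation and AR(1) truth", {
  expect_equal(lag1Autocorrelation(c(1, -1, 1, -1)), -0.75)
  expect_error(lag1Autocorrelation(rep(2, 10)), "zero variance")
  expect_error(lag1Autocorrelation(c(1, 2)), "at least 3")
  # long AR(1): Q estimates phi (oracle: stats::arima.sim)
  x <- withr::with_seed(8, as.numeric(arima.sim(list(ar = 0.6), 5000)))
  expect_lt(abs(lag1Autocorrelation(x) - 0.6), 0.05)
})

test_that("Bartlett effective sample size follows N(1-Q)/(1+Q)", {
  expect_equal(effectiveSampleSize(15, 0), 15)
  expect_equal(effectiveSampleSize(15, 0.5), 5)
  # negative Q is clamped (anti-conservative otherwise)
  expect_equal(effectiveSampleSize(15, -0.4), 15)
  # Q -> 0.99 stays positive, near N/199
  expect_equal(effectiveSampleSize(15, 0.999), 15 * 0.01 / 1.99)
  expect_gt(effectiveSampleSize(15, 0.999), 0)
  qs <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(vapply(qs, effectiveSampleSize, numeric(1), N = 15)) < 0))
  expect_error(effectiveSampleSize(1, 0.2), ">= 2")
})

test_that("corrected Friedman reduces to the classical test at Q = 0", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(rnorm(15 * 4), 15, 4)
    ours <- friedmanNeff(m, Q = 0)
    oracle <- friedman.test(m)
    expect_equal(ours$stat, unname(oracle$statistic), tolerance = 1e-9)
    expect_equal(ours$p_asymptotic, oracle$p.value, tolerance = 1e-9)
  }
  # with ties (mid-ranks)
  m <- matrix(sample(1:3, 60, replace = TRUE), 15, 4)
  expect_equal(friedmanNeff(m, Q = 0)$stat,
               unname(friedman.test(m)$statistic), tolerance = 1e-9)
})

test_that("Friedman engine flags obvious effects and flat panels", {
  flat <- matrix(rep(1:15, 4), 15, 4)     # identical treatments
  ft <- friedmanNeff(flat, Q = 0)
  expect_equal(ft$stat, 0)
  expect_equal(ft$p_asymptotic, 1)
  shifted <- withr::with_seed(5, {
    m <- matrix(rnorm(60), 15, 4); m[, 3] <- m[, 3] + 10; m
  })
  expect_lt(friedmanNeff(shifted, Q = 0)$p_asymptotic, 0.001)
  # strong autocorrelation makes a window untestable rather than forced
  expect_true(is.na(friedmanNeff(shifted, Q = 0.9)$p_asymptotic))
  expect_error(friedmanNeff(matrix(1:15, 15, 1)), "k >= 2")
})

test_that("permutation p-values: bounds, reproducibility, asymptotic agreement", {
  flat <- matrix(rep(1:15, 4), 15, 4)
  expect_equal(friedmanPermutation(flat, B = 200, seed = 1), 1)
  shifted <- withr::with_seed(5, {
    m <- matrix(rnorm(60), 15, 4); m[, 3] <- m[, 3] + 10; m
  })
  expect_equal(friedmanPermutation(shifted, B = 1000, seed = 2), 1 / 1001)
  p1 <- friedmanPermutation(shifted, B = 500, seed = 9)
  expect_identical(p1, friedmanPermutation(shifted, B = 500, seed = 9))
  expect_error(friedmanPermutation(shifted, B = 0), "B must be")
  # permutation and asymptotic p agree for white-noise panels (median gap)
  gaps <- withr::with_seed(17, vapply(1:60, function(i) {
    m <- matrix(rnorm(60), 15, 4)
    abs(friedmanPermutation(m, B = 400, seed = i) -
          friedmanNeff(m, Q = 0)$p_asymptotic)
  }, numeric(1)))
  expect_lt(median(gaps), 0.05)
})

test_that("Conover-Holm post hoc isolates the deviant treatment", {
  flat <- matrix(rep(1:12, 4), 12, 4)
  chFlat <- conoverHolm(flat)
  expect_true(all(chFlat[upper.tri(chFlat)] >= 0.999))
  dev <- withr::with_seed(6, {
    m <- matrix(rnorm(15 * 4), 15, 4); m[, 2] <- m[, 2] + 8; m
  })
  ch <- conoverHolm(dev)
  raw <- attr(ch, "raw")
  # Holm: adjusted >= raw for every pair
  pairs <- which(upper.tri(ch), arr.ind = TRUE)
  expect_true(all(ch[pairs] >= raw - 1e-15))
  # the deviant treatment's pairs carry the smallest adjusted p
  inv <- pairs[, 1] == 2 | pairs[, 2] == 2
  expect_lt(max(ch[pairs][inv]), min(ch[pairs][!inv]))
  expect_true(all(ch[pairs][inv] < 0.05))
})

test_that("sliding scan localizes a divergence and stays quiet under the null", {
  # k identical series: zero significant windows
  base <- withr::with_seed(3, rnorm(60))
  same <- seriesPanel(cbind(base, base, base))
  scanSame <- slidingScan(same, maW = 15, windowW = 15, B = 200, seed = 4)
  expect_equal(sum(scanWindows(scanSame)$n_significant_pairs), 0)
  expect_equal(nrow(pairSignificance(scanSame)), 0)
  # two series diverging after the changepoint: the first sustained run of
  # significant windows begins within a window-plus-smoothing span of it
  tstar <- 60
  panel <- genGroupedSeries(3, 120, ar1Phi = 0.2, noiseSd = 1,
                            changepoint = tstar, changeOffsets = c(0, 0, 8),
                            seed = 12)
  scan <- slidingScan(panel, maW = 15, windowW = 15, B = 300, seed = 5)
  w <- scanWindows(scan)
  sig <- w$p_permutation < 0.05
  runs <- rle(sig)
  expect_true(any(runs$values))
  # the longest sustained run of significant windows begins near the
  # changepoint (isolated false positives form only short runs)
  best <- which(runs$values & runs$lengths == max(runs$lengths[runs$values]))[1]
  firstIdx <- sum(runs$lengths[seq_len(best - 1)]) + 1
  first <- w$frame_start[firstIdx]
  expect_gte(first, tstar - 15 - 14)   # window may straddle the smoothing span
  expect_lte(first, tstar + 15)
  # step = window width gives non-overlapping windows with the exact count
  scanStep <- slidingScan(panel, maW = 15, windowW = 15, step = 15, B = 50,
                          seed = 6)
  Tprime <- 120 - 15 + 1
  expect_equal(nrow(scanWindows(scanStep)), floor((Tprime - 15) / 15) + 1)
  expect_error(slidingScan(seriesPanel(matrix(rnorm(20), 10, 2))), "required")
})

test_that("distribution distances: KS and Wasserstein", {
  x <- withr::with_seed(2, rnorm(80))
  expect_equal(distributionDistance(x, x, "ks"), 0)
  expect_equal(distributionDistance(x, x, "wasserstein"), 0)
  # constant shift: Wasserstein equals the shift
  expect_equal(distributionDistance(x, x + 1.7, "wasserstein"), 1.7,
               tolerance = 1e-9)
  # fully separated supports: KS = 1
  expect_equal(distributionDistance(x, x + 100, "ks"), 1)
  # oracle: stats::ks.test statistic
  y <- withr::with_seed(3, rnorm(50, 0.5))
  expect_equal(distributionDistance(x, y, "ks"),
               unname(suppressWarnings(ks.test(x, y)$statistic)),
               tolerance = 1e-12)
  expect_error(distributionDistance(numeric(0), x), "nonempty")
})

test_that("bootstrap CI: degeneracy, bounds ordering, reproducibility", {
  b <- bootstrapCI(rep(4.2, 10), B = 100, seed = 1)
  expect_equal(b$lower, 4.2)
  expect_equal(b$upper, 4.2)
  x <- withr::with_seed(10, rnorm(50))
  b1 <- bootstrapCI(x, B = 2000, seed = 7)
  expect_lte(b1$lower, b1$estimate)
  expect_gte(b1$upper, b1$estimate)
  expect_identical(b1, bootstrapCI(x, B = 2000, seed = 7))
  b0 <- bootstrapCI(x, B = 10, level = 0, seed = 1)
  expect_equal(b0$lower, b0$estimate)
  expect_equal(b0$upper, b0$estimate)
  expect_error(bootstrapCI(x, B = 0), "B must be")
  expect_error(bootstrapCI(1), "at least 2")
})
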