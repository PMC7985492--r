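test_that("global score is the mean of the 52 tests", {
  m <- matrix(0.5, 4, 52)
  expect_equal(globalScore(m), rep(0.5, 4))
  m2 <- cbind(matrix(0, 3, 26), matrix(1, 3, 26))
  expect_equal(globalScore(m2), rep(0.5, 3))
  m2[2, 1] <- NA
  expect_error(globalScore(m2), "filterComplete")
})

test_that("a noiseless line is fitted exactly with zero SEs", {
  a <- seq(30, 71, length.out = 20)
  res <- fitTrajectory(0.01 * a, a, nBoot = 0)
  expect_equal(res$fits$m, 0.01, tolerance = 1e-12)
  expect_equal(res$fits$b, 0, tolerance = 1e-12)
  expect_equal(res$fits$mSe, 0, tolerance = 1e-10)
  expect_equal(res$fits$bSe, 0, tolerance = 1e-10)
})

test_that("OLS equals the closed-form normal-equations solution", {
  set.seed(15)
  a <- sample(30:71, 60, replace = TRUE)
  y <- 0.3 + 0.005 * a + rnorm(60, 0, 0.05)
  res <- fitTrajectory(y, a, nBoot = 0)
  ref <- summary(lm(y ~ a))$coefficients
  expect_equal(res$fits$m, ref["a", "Estimate"])
  expect_equal(res$fits$b, ref["(Intercept)", "Estimate"])
  expect_equal(res$fits$mSe, ref["a", "Std. Error"])
  expect_equal(res$fits$bSe, ref["(Intercept)", "Std. Error"])
  expect_error(fitTrajectory(y, rep(40, 60)), "zero age variance")
})

test_that("equal-slope different-intercept groups are separated correctly", {
  set.seed(16)
  n <- 250
  a <- sample(30:71, 2 * n, replace = TRUE)
  g <- rep(c("lo", "hi"), each = n)
  y <- ifelse(g == "lo", 0.0, 0.25) + 0.008 * a + rnorm(2 * n, 0, 0.08)
  res <- fitTrajectory(y, a, g, nBoot = 400, seed = 2)
  expect_gt(res$slopeContrast$p, 0.05)
  expect_lt(res$interceptContrast$p, 0.05)
})

test_that("identical groups give overlapping coefficient distributions", {
  set.seed(17)
  n <- 150
  a <- sample(30:71, 2 * n, replace = TRUE)
  y <- 0.1 + 0.006 * a + rnorm(2 * n, 0, 0.08)
  g <- rep(c("A", "B"), each = n)
  res <- fitTrajectory(y, a, g, nBoot = 400, seed = 3)
  expect_gt(res$slopeContrast$p, 0.01)
  expect_gt(res$interceptContrast$p, 0.01)
})

test_that("full-fraction subsampling reproduces the full-sample fit", {
  set.seed(18)
  n <- 40
  a <- sample(30:71, n, replace = TRUE)
  y <- 0.2 + 0.004 * a + rnorm(n, 0, 0.03)
  g <- rep("all", n)
  res <- subsampleRegressions(y, a, g, fractions = 1.0, nIter = 1, seed = 4)
  full <- fitTrajectory(y, a, nBoot = 0)$fits
  expect_equal(res$draws$m, full$m)
  expect_equal(res$draws$b, full$b)
})

test_that("subsample spread shrinks with the fraction and tiny ones are skipped", {
  set.seed(19)
  n <- 200
  a <- sample(30:71, n, replace = TRUE)
  y <- 0.1 + 0.006 * a + rnorm(n, 0, 0.08)
  g <- rep("all", n)
  res <- subsampleRegressions(y, a, g, fractions = c(0.2, 0.8),
                              nIter = 300, seed = 5)
  sds <- res$summary$mSd
  expect_gt(sds[1], sds[2])
  # without-replacement subsampling: sd scales like sqrt(1/k - 1/n)
  # (finite-population correction), here sqrt(0.02 / 0.00125) = 4
  k1 <- 0.2 * n; k2 <- 0.8 * n
  expected <- sqrt((1 / k1 - 1 / n) / (1 / k2 - 1 / n))
  expect_equal(sds[1] / sds[2], expected, tolerance = 0.25)
  expect_message(
    subsampleRegressions(y[1:10], a[1:10], g[1:10],
                         fractions = c(0.2, 0.9), nIter = 5, seed = 6),
    "skipped")
})

test_that("planted nationality-style slope ordering is recovered", {
  set.seed(20)
  sizes <- c(MX = 300, CO = 80, GT = 50)
  slopes <- c(MX = 0.0162, CO = 0.0143, GT = 0.0138)
  a <- unlist(lapply(sizes, function(n) sample(30:71, n, replace = TRUE)))
  g <- rep(names(sizes), sizes)
  y <- slopes[g] * a - 0.2 + rnorm(sum(sizes), 0, 0.07)
  res <- subsampleRegressions(pmin(pmax(y, 0), 1.5), a, g,
                              fractions = 0.8, nIter = 300, seed = 7)
  mm <- setNames(res$summary$mMean, res$summary$group)
  expect_gt(mm["MX"], mm["CO"])
  expect_gt(mm["MX"], mm["GT"])
  expect_lt(res$contrasts$pSlope[1], 0.05)
})
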