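test_that("correlation matrix reproduces exact toy cases", {
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(6, 4, 2),
             d = c(0, 1, 0))
  r <- correlationMatrix(m)@r
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(r["d", "a"], 0)
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r, t(r))
})

test_that("degenerate inputs are handled explicitly", {
  m <- cbind(x = c(1, 2, 3, 4), y = rep(2, 4), z = c(4, 3, 1, 0))
  expect_warning(cm <- correlationMatrix(m), "zero variance")
  expect_true(is.na(cm@r["y", "x"]))
  expect_equal(cm@r["x", "z"], cor(m[, "x"], m[, "z"]))
  expect_error(correlationMatrix(m[1:2, ]), "at least 3")
})

test_that("surrogate significance attains the minimal p and flags duplicates", {
  set.seed(2)
  n <- 40
  base <- runif(n)
  m <- cbind(base, base, matrix(runif(n * 6), n, 6))
  cm <- surrogateSignificance(m, nSurrogates = 1000, seed = 3)
  # identical columns: r = 1 cannot be reached by shuffling distinct values
  expect_equal(cm@pValues[1, 2], 1 / 1001)
  expect_true(cm@sigMask[1, 2])
  expect_true(all(cm@pValues >= 1 / 1001, na.rm = TRUE))
  expect_true(all(cm@pValues <= 1, na.rm = TRUE))
  expect_error(surrogateSignificance(m, nSurrogates = 0), ">= 1")
})

test_that("surrogate null keeps approximately nominal type-I error", {
  set.seed(4)
  fracs <- vapply(seq_len(60), function(i) {
    m <- matrix(runif(150 * 10), 150, 10)
    cm <- surrogateSignificance(m, nSurrogates = 99, seed = i)
    mean(cm@sigMask[upper.tri(cm@sigMask)])
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)
})

test_that("summed-correlation ordering is descending with id tie-break", {
  r <- diag(3)
  r[1, 2] <- r[2, 1] <- 0.9
  r[1, 3] <- r[3, 1] <- 0.1
  r[2, 3] <- r[3, 2] <- 0.5
  # row sums off-diagonal: 1.0, 1.4, 0.6 -> order 2, 1, 3
  expect_equal(sortBySummedCorrelation(r), c(2L, 1L, 3L))
  expect_equal(sortBySummedCorrelation(matrix(0.5, 4, 4)), 1:4)
  # an uncorrelated test ranks last
  r2 <- matrix(0.6, 5, 5); diag(r2) <- 1
  r2[4, ] <- r2[, 4] <- 0; r2[4, 4] <- 1
  expect_equal(sortBySummedCorrelation(r2)[5], 4L)
})

test_that("function contrast flags a planted low-correlation block", {
  set.seed(5)
  bat <- defaultBattery()
  n <- 300
  shared <- rnorm(n, 0, 0.3)
  m <- matrix(rnorm(n * 52, 0, 0.3), n, 52) + shared
  att <- which(bat$fn == "attention_memory")
  m[, att] <- matrix(rnorm(n * length(att), 0, 0.45), n) + 0.25 * shared
  cm <- correlationMatrix(pmin(pmax(m + 0.5, 0), 1))
  res <- functionCorrelationContrast(cm, bat)
  expect_lt(res$attention_memory@pValue, 0.05)
  expect_equal(res$attention_memory@tails, "one")
  expect_length(res, 5L)
})

test_that("correlation derivative is the difference of contiguous groups", {
  expect_equal(correlationDerivative(c(0.1, 0.2, 0.3)), c(0.1, 0.1))
  expect_equal(correlationDerivative(rep(0.4, 5)), rep(0, 4))
  expect_error(correlationDerivative(0.3), "two age groups")
})

test_that("identical age groups give equal means and zero slope", {
  set.seed(6)
  block <- matrix(runif(30 * 8), 30, 8)
  m <- rbind(block, block, block)
  grp <- rep(1:3, each = 30)
  # lm warns about the perfect fit of three identical means; expected here
  tr <- suppressWarnings(ageGroupCorrelationTrend(m, grp))
  expect_equal(unname(tr$means[1]), unname(tr$means[2]))
  expect_equal(tr$slope, 0, tolerance = 1e-12)
})
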