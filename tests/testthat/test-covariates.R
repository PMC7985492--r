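test_that("conditional probabilities normalize and recover the planted odds", {
  se <- defaultCohortFixture(1L)
  lab <- plantedTruth(se)$labels$true_cluster
  res <- conditionalProbabilities(se, lab, "school")
  expect_equal(rowSums(res$probs), c(1, 1), ignore_attr = TRUE)
  # cluster 2 planted 2.2x as prevalent in private school
  expect_equal(unname(res$ratio["private"]), 2.2, tolerance = 0.3 / 2.2 * 2)
  hh <- conditionalProbabilities(se, lab, "household")
  expect_equal(unname(hh$ratio["both_parents"]), 1.43, tolerance = 0.15)
})

test_that("degenerate cells give flagged infinite ratios", {
  demo <- data.frame(
    school = rep(c("public", "public", "private"), c(10, 5, 5)),
    household = "both_parents",
    father_age = 30, mother_age = 28, father_edu = 12, mother_edu = 12)
  lab <- rep(c(1, 2), c(10, 10))
  res <- conditionalProbabilities(demo, lab, "school")
  expect_equal(unname(res$probs[2, "private"]), 0.5)
  expect_true(is.infinite(res$ratio["private"]))
  expect_true(res$degenerate["private"])
  expect_error(
    conditionalProbabilities(demo[1:10, ],
                             factor(rep(1, 10), levels = 1:2), "school"),
    "empty cluster")
})

test_that("parent comparisons detect a planted school-linked shift", {
  set.seed(40)
  n <- 600
  school <- sample(c("none", "public", "private"), n, replace = TRUE,
                   prob = c(0.1, 0.65, 0.25))
  shift <- ifelse(school == "private", 4, 0)
  demo <- data.frame(
    school = school, household = "both_parents",
    father_age = rnorm(n, 31 + shift, 5),
    mother_age = rnorm(n, 28 + shift, 5),
    father_edu = rnorm(n, 11, 3), mother_edu = rnorm(n, 11, 3))
  res <- parentGroupComparisons(demo, "school")
  expect_lt(res$father_age$omnibus@pValue, 0.001)
  expect_lt(res$mother_age$omnibus@pValue, 0.001)
  expect_gt(res$father_edu$omnibus@pValue, 0.001)
  expect_s4_class(res$father_age$omnibus, "StatTestResult")
  # ANOVA variant reports an F statistic
  resA <- parentGroupComparisons(demo, "school", method = "anova")
  expect_equal(resA$father_age$omnibus@testName, "anova_oneway")
  expect_error(parentGroupComparisons(demo, rep("one", n)), "2 groups")
})

test_that("MLRM recovers an exact linear signal", {
  set.seed(41)
  n <- 120
  X <- data.frame(Pr1 = sample(0:2, n, TRUE), Pr2 = sample(0:2, n, TRUE),
                  Pr3 = rnorm(n, 31, 5), Pr4 = rnorm(n, 28, 5),
                  Pr5 = rnorm(n, 11, 3), Pr6 = rnorm(n, 11, 3))
  y <- 2 * X$Pr3
  co <- mlrmFit(X, y)
  # Pr3 was z-scored, so its coefficient is 2 * sd(Pr3); everything else 0
  expect_equal(unname(co["Pr3"]), 2 * sd(X$Pr3))
  expect_equal(unname(co[c("Pr1", "Pr2", "Pr4", "Pr5", "Pr6")]),
               rep(0, 5), tolerance = 1e-10)
  # collinear design is refused with names
  Xbad <- X; Xbad$Pr4 <- Xbad$Pr3
  expect_error(mlrmFit(Xbad, y), "collinear")
})

test_that("orthogonal predictors give univariate slopes", {
  set.seed(42)
  n <- 64
  X <- data.frame(Pr1 = rep(c(0, 1), each = n / 2),
                  Pr2 = rep(c(0, 1), times = n / 2))
  X$Pr3 <- rnorm(n); X$Pr3 <- X$Pr3 - mean(X$Pr3)
  # force exact orthogonality of Pr3 to Pr1/Pr2
  X$Pr3 <- residuals(lm(Pr3 ~ Pr1 + Pr2, X))
  X$Pr4 <- 0; X$Pr5 <- 0; X$Pr6 <- 0
  X <- X[, c("Pr1", "Pr2", "Pr3")]
  y <- rnorm(n)
  co <- mlrmFit(X, y)
  uni <- coef(lm(y ~ standardized, data.frame(
    standardized = (X$Pr3 - mean(X$Pr3)) / sd(X$Pr3))))[2]
  expect_equal(unname(co["Pr3"]), unname(uni), tolerance = 1e-8)
})

test_that("joint row permutation preserves predictor correlations exactly", {
  set.seed(43)
  n <- 80
  X <- data.frame(Pr1 = sample(0:2, n, TRUE), Pr2 = sample(0:2, n, TRUE),
                  Pr3 = rnorm(n), Pr4 = rnorm(n),
                  Pr5 = rnorm(n), Pr6 = rnorm(n))
  perm <- sample.int(n)
  expect_equal(cor(X[perm, ]), cor(X))
})

test_that("permutation significance attains minimal p for a strong effect", {
  set.seed(44)
  n <- 150
  X <- data.frame(Pr1 = sample(0:2, n, TRUE), Pr2 = sample(0:2, n, TRUE),
                  Pr3 = rnorm(n, 31, 5), Pr4 = rnorm(n, 28, 5),
                  Pr5 = rnorm(n, 11, 3), Pr6 = rnorm(n, 11, 3))
  y <- 0.1 * X$Pr5 + rnorm(n, 0, 0.05)
  res <- mlrmPermutationSignificance(X, y, nSurrogates = 1000, seed = 1)
  expect_equal(unname(res@empiricalP["Pr5"]), 1 / 1001)
  expect_true(all(res@empiricalP >= 1 / 1001 & res@empiricalP <= 1))
  expect_error(mlrmPermutationSignificance(X, y, nSurrogates = 0), ">= 1")
})

test_that("permutation p-values are invariant to predictor rescaling", {
  set.seed(45)
  n <- 100
  X <- data.frame(Pr1 = sample(0:2, n, TRUE), Pr2 = sample(0:2, n, TRUE),
                  Pr3 = rnorm(n), Pr4 = rnorm(n),
                  Pr5 = rnorm(n), Pr6 = rnorm(n))
  y <- 0.4 * X$Pr3 - 0.2 * X$Pr1 + rnorm(n, 0, 0.5)
  p1 <- mlrmPermutationSignificance(X, y, nSurrogates = 300, seed = 9)
  X2 <- X; X2$Pr3 <- X2$Pr3 * 100 + 7; X2$Pr6 <- X2$Pr6 / 3 - 1
  p2 <- mlrmPermutationSignificance(X2, y, nSurrogates = 300, seed = 9)
  expect_equal(p1@empiricalP, p2@empiricalP)
})

test_that("selective planted effects are the ones flagged", {
  set.seed(46)
  n <- 611
  X <- data.frame(Pr1 = sample(0:2, n, TRUE), Pr2 = sample(0:2, n, TRUE),
                  Pr3 = rnorm(n, 31, 5), Pr4 = rnorm(n, 28, 5),
                  Pr5 = rnorm(n, 11, 3), Pr6 = rnorm(n, 11, 3))
  y <- 0.06 * X$Pr1 + 0.015 * scale(X$Pr5)[, 1] +
    0.015 * scale(X$Pr6)[, 1] + rnorm(n, 0, 0.08)
  plantedFound <- logical(0); falsePos <- integer(0)
  for (s in 1:5) {
    res <- mlrmPermutationSignificance(X, y, nSurrogates = 199, seed = s)
    sig <- names(which(res@empiricalP < 0.05))
    plantedFound <- c(plantedFound,
                      all(c("Pr1", "Pr5", "Pr6") %in% sig))
    falsePos <- c(falsePos, length(setdiff(sig, c("Pr1", "Pr5", "Pr6"))))
  }
  expect_true(all(plantedFound))
  # null predictors flagged only at the nominal false-positive rate
  expect_lte(sum(falsePos), 2L)
})
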