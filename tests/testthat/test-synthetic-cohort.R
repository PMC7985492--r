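# The cohort generator: determinism, planted structure, invariants.

test_that("study-replica cohort matches the configured design", {
  se <- generateCohort(defaultCohortConfig(seed = 4))
  expect_equal(ncol(se), 643L)
  expect_equal(as.vector(table(ageGroups(se))),
               c(98L, 97L, 102L, 101L, 87L, 83L, 75L))
  m <- scoreMatrix(se)
  expect_true(all(is.na(m) | (m >= 0 & m <= 1)))
  # exactly nPartial children carry missing scores
  expect_equal(sum(!complete.cases(m)), 32L)
  expect_equal(nDiscarded(filterComplete(se)), 32L)
})

test_that("same seed gives byte-identical cohorts, different seeds differ", {
  a <- generateCohort(defaultCohortConfig(seed = 9))
  b <- generateCohort(defaultCohortConfig(seed = 9))
  expect_identical(scoreMatrix(a), scoreMatrix(b))
  expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
  c <- generateCohort(defaultCohortConfig(seed = 10))
  expect_false(identical(scoreMatrix(a), scoreMatrix(c)))
})

test_that("noise-free single-cluster limit is exactly linear in age", {
  cfg <- cohortConfig(nChildren = 70L, ageGroupSizes = rep(10L, 7),
                      clusterShares = 1, clusterIntercepts = 0.05,
                      clusterSlopes = 0.01, domainLoading = c(0, 0),
                      noiseSd = 0, latentSd = 0,
                      loadingRange = c(1, 1), seed = 2)
  se <- generateCohort(cfg)
  expect_equal(globalScore(se), 0.05 + 0.01 * ages(se),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nChildren = 10L, ageGroupSizes = rep(1L, 7)),
               "sum to nChildren")
  expect_error(cohortConfig(nChildren = 7L, ageGroupSizes = rep(1L, 7),
                            nationalityProbs = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(cohortConfig(nChildren = 7L, ageGroupSizes = rep(1L, 7),
                            clusterShares = c(0.5, 0.5),
                            clusterIntercepts = 0.1, clusterSlopes = 0.01),
               "per cluster")
  expect_error(cohortConfig(nChildren = 7L, ageGroupSizes = rep(1L, 7),
                            noiseSd = -1), ">= 0")
})

test_that("plantedTruth returns the planted structure and rejects foreign data", {
  se <- defaultCohortFixture(1L)
  tr <- plantedTruth(se)
  expect_equal(tr$slopes, c(8.6e-3, 7.8e-3))
  expect_equal(tr$intercepts, c(1.2e-3, 274.6e-3))
  # planted share ~ 42% of complete cases
  expect_equal(mean(tr$labels$true_cluster == 1), 254 / 611,
               tolerance = 0.15)
  # single-cluster config: all labels 1
  cfg1 <- cohortConfig(nChildren = 35L, ageGroupSizes = rep(5L, 7), seed = 3)
  expect_true(all(plantedTruth(
    generateCohort(cfg1))$labels$true_cluster == 1L))
  # foreign object: no planted labels
  plain <- ScoreExperiment(matrix(0.5, 3, 52),
                           data.frame(age_months = c(31, 40, 50)))
  expect_error(plantedTruth(plain), "planted")
})

test_that("labels joined to scores reproduce the planted mean separation", {
  se <- defaultCohortFixture(1L)
  tr <- plantedTruth(se)
  gs <- globalScore(se)
  planted <- tr$clusterMeans
  observed <- as.vector(tapply(gs, tr$labels$true_cluster, mean))
  # Monte-Carlo error: composition and sampling noise at n ~ 250-360
  expect_true(all(abs(observed - planted) < 0.03))
  subObs <- as.vector(tapply(gs, paste(tr$labels$true_cluster,
                                       tr$labels$true_subcluster), mean))
  expect_true(all(abs(subObs - c(tr$subclusterMeans[[1]],
                                 tr$subclusterMeans[[2]])) < 0.035))
})

test_that("nationality mixture converges to the configured probabilities", {
  cfg <- cohortConfig(nChildren = 10010L,
                      ageGroupSizes = rep(1430L, 7), seed = 5)
  se <- generateCohort(cfg)
  props <- as.vector(prop.table(table(colData(se)$nationality)))
  expect_equal(props, c(470, 87, 54) / 611, tolerance = 0.02)
})

test_that("age-increasing factor loading strengthens correlations with age", {
  # single-cluster cohort isolates the lambda(age) effect from cluster
  # structure; mean off-diagonal correlation must rise over age groups
  cfg <- cohortConfig(nChildren = 4998L, ageGroupSizes = rep(714L, 7),
                      clusterShares = 1, clusterIntercepts = 0.2,
                      clusterSlopes = 0.006,
                      domainLoading = c(0.02, 0.01), seed = 8)
  se <- generateCohort(cfg)
  tr <- ageGroupCorrelationTrend(se)
  expect_length(tr$means, 7L)
  expect_gt(tr$slope, 0)
  expect_gt(tr$slope, 2 * tr$slopeSe)
  # flat lambda: no trend
  cfgFlat <- cfg; cfgFlat@domainLoading <- c(0.05, 0); cfgFlat@seed <- 9L
  trFlat <- ageGroupCorrelationTrend(generateCohort(cfgFlat))
  expect_lt(abs(trFlat$slope), 3 * trFlat$slopeSe)
})

test_that("trajectory regression recovers planted slopes within 2 SE", {
  se <- defaultCohortFixture(1L)
  tr <- plantedTruth(se)
  gs <- globalScore(se)
  a <- ages(se)
  for (c in 1:2) {
    idx <- tr$labels$true_cluster == c
    fit <- summary(lm(gs[idx] ~ a[idx]))$coefficients
    expect_lt(abs(fit[2, 1] - tr$slopes[c]), 2 * fit[2, 2])
  }
})

test_that("seed streams are decoupled and valid", {
  s1 <- deriveSeed(1L, "ages")
  s2 <- deriveSeed(1L, "scores")
  expect_true(s1 != s2)
  expect_identical(s1, deriveSeed(1L, "ages"))
  big <- deriveSeed(2147483000, "x")
  expect_true(big >= 0 && big < 2^31)
})
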