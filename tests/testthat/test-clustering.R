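test_that("k-means recovers point-mass clusters exactly", {
  m <- rbind(matrix(0.2, 10, 52), matrix(0.8, 12, 52))
  fit <- kmeansScores(m, 2, seed = 1)
  expect_equal(unname(fit$centroids[1, ]), rep(0.2, 52))
  expect_equal(unname(fit$centroids[2, ]), rep(0.8, 52))
  expect_equal(unname(fit$labels), rep(c(1L, 2L), c(10, 12)))
  # k = 1: centroid is the column mean
  one <- kmeansScores(m, 1, seed = 1)
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(m)))
  expect_error(kmeansScores(m, 23, seed = 1), "cannot exceed")
})

test_that("planted two-cluster structure is recovered with high agreement", {
  m <- blobMatrix(n1 = 60, n2 = 80, d = 20, sep = 0.3, sd = 0.1, seed = 3)
  truth <- rep(c(1L, 2L), c(60, 80))
  fit <- kmeansScores(m, 2, seed = 5)
  expect_gt(mean(fit$labels == truth), 0.9)
})

test_that("CH and DB match independent brute-force formulas", {
  # naive loop-based oracle, deliberately different from the implementation
  chOracle <- function(m, lab) {
    n <- nrow(m); ks <- unique(lab); mu <- colMeans(m)
    B <- 0; W <- 0
    for (c in ks) {
      pts <- m[lab == c, , drop = FALSE]
      muc <- colMeans(pts)
      B <- B + nrow(pts) * sum((muc - mu)^2)
      for (i in seq_len(nrow(pts))) W <- W + sum((pts[i, ] - muc)^2)
    }
    (B / (length(ks) - 1)) / (W / (n - length(ks)))
  }
  dbOracle <- function(m, lab) {
    ks <- sort(unique(lab)); k <- length(ks)
    cen <- lapply(ks, function(c) colMeans(m[lab == c, , drop = FALSE]))
    S <- numeric(k)
    for (i in seq_len(k)) {
      pts <- m[lab == ks[i], , drop = FALSE]
      S[i] <- mean(apply(pts, 1, function(p) sqrt(sum((p - cen[[i]])^2))))
    }
    vals <- numeric(k)
    for (i in seq_len(k)) {
      best <- -Inf
      for (j in seq_len(k)) {
        if (i == j) next
        best <- max(best, (S[i] + S[j]) /
                      sqrt(sum((cen[[i]] - cen[[j]])^2)))
      }
      vals[i] <- best
    }
    mean(vals)
  }
  set.seed(9)
  for (rep in 1:5) {
    m <- matrix(runif(30 * 4), 30, 4)
    lab <- sample(1:3, 30, replace = TRUE)
    if (length(unique(lab)) < 3) next
    expect_equal(calinskiHarabasz(m, lab), chOracle(m, lab))
    expect_equal(daviesBouldin(m, lab), dbOracle(m, lab))
  }
})

test_that("criterion-based selection finds planted blob counts", {
  m2 <- blobMatrix(50, 50, d = 8, sep = 0.4, sd = 0.05, seed = 11)
  sel2 <- selectK(m2, kRange = 2:6, seed = 2)
  expect_equal(sel2@k, 2L)
  expect_equal(sel2@kDb, 2L)
  expect_false(sel2@disagreement)
  set.seed(12)
  m3 <- rbind(matrix(rnorm(40 * 8, 0.15, 0.04), 40, 8),
              matrix(rnorm(40 * 8, 0.50, 0.04), 40, 8),
              matrix(rnorm(40 * 8, 0.85, 0.04), 40, 8))
  sel3 <- selectK(pmin(pmax(m3, 0), 1), kRange = 2:6, seed = 2)
  expect_equal(sel3@k, 3L)
  expect_error(selectK(matrix(0.5, 20, 5)), "zero dispersion")
})

test_that("reported summaries are invariant to cluster relabelling", {
  m <- blobMatrix(30, 40, d = 10, sep = 0.35, sd = 0.06, seed = 13)
  fit1 <- kmeansScores(m, 2, seed = 3)
  fit2 <- kmeansScores(m[nrow(m):1, ], 2, seed = 8)
  # canonical ordering by centroid mean: same partition, same centroids
  expect_equal(fit1$centroids, fit2$centroids, tolerance = 1e-8)
  expect_equal(unname(fit1$labels), rev(unname(fit2$labels)))
})

test_that("nested sub-clustering splits and orders the default cohort", {
  se <- defaultCohortFixture(1L)
  m <- scoreMatrix(se)
  mod <- selectK(m, kRange = 2:6, seed = 21)
  expect_equal(mod@k, 2L)
  mod <- subcluster(m, mod, kRange = 2:6, seed = 22)
  expect_equal(sort(unique(mod@subLabels)),
               c("1.1", "1.2", "2.1", "2.2"))
  # graded transition: mean scores strictly increasing across C1.1 ... C2.2
  means <- tapply(globalScore(se), mod@subLabels, mean)
  means <- means[sort(names(means))]
  expect_true(all(diff(means) > 0))
  # too-small cluster is kept whole
  tiny <- blobMatrix(5, 60, d = 6, sep = 0.5, sd = 0.04, seed = 14)
  tmod <- selectK(tiny, kRange = 2:3, seed = 4)
  expect_message(subcluster(tiny, tmod, kRange = 3:6, seed = 5),
                 "too small")
})

test_that("profiles flag planted depressed tests and scale constantly", {
  se <- defaultCohortFixture(1L)
  m <- scoreMatrix(se)
  labels <- plantedTruth(se)$labels$true_cluster
  # depress three tests in cluster 1 far below its own profile trend
  m2 <- m
  bad <- c(5L, 7L, 21L)
  m2[labels == 1, bad] <- pmax(m2[labels == 1, bad] - 0.3, 0)
  prof <- clusterProfiles(m2, labels)
  expect_equal(sort(prof$flagged$cluster1), bad)
  expect_length(prof$flagged$cluster2, 0L)
  # scaled-down profiles: cluster ratio roughly constant across tests
  profClean <- clusterProfiles(m, labels)$profiles
  ratio <- profClean$mean[profClean$cluster == 1] /
    profClean$mean[profClean$cluster == 2]
  expect_lt(sd(ratio) / mean(ratio), 0.15)
  expect_error(clusterProfiles(m, rep(1L, nrow(m))), NA)
})

test_that("centroid separation tracks the planted between-cluster offset", {
  # synthetic two-group design with full control of the offset
  set.seed(77)
  n <- 700
  a <- sample(30:71, n, replace = TRUE)
  grp <- binAgeGroups(a)
  labels <- rep(c(1L, 2L), length.out = n)
  base <- matrix(rnorm(n * 52, 0.45, 0.08), n, 52)
  # constant offset: flat |difference| across age groups
  mFlat <- base
  mFlat[labels == 2, ] <- mFlat[labels == 2, ] + 0.2
  resFlat <- centroidDistanceByAge(pmin(pmax(mFlat, 0), 1), labels, grp)
  expect_length(resFlat$meanAbsDiff, 7L)
  expect_gt(resFlat$trend[["p"]], 0.05)
  # offset growing with age: positive significant trend
  mGrow <- base
  grow <- 0.08 + (a - 30) / 41 * 0.25
  mGrow[labels == 2, ] <- mGrow[labels == 2, ] + grow[labels == 2]
  resGrow <- centroidDistanceByAge(pmin(pmax(mGrow, 0), 1), labels, grp)
  expect_lt(resGrow$trend[["p"]], 0.05)
  expect_gt(resGrow$trend[["slope"]], 0)
  # single age group: one centroid pair, no trend
  one <- centroidDistanceByAge(pmin(pmax(base, 0), 1), labels,
                               rep(1L, n))
  expect_length(one$meanAbsDiff, 1L)
  expect_null(one$trend)
  # a group missing one cluster is skipped with a message
  lab2 <- labels; lab2[grp == 7] <- 1L
  expect_message(
    skipRes <- centroidDistanceByAge(pmin(pmax(base, 0), 1), lab2, grp),
    "lacks")
  expect_length(skipRes$meanAbsDiff, 6L)
})
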