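# Cluster discovery: seeded k-means, Calinski-Harabasz / Davies-Bouldin
# model selection, nested sub-clustering and cluster summaries.

# k-means++ seeding: first center uniform, then D^2-weighted draws.
kmeansppInit <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  centers[1, ] <- m[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(m, 2, centers[1, ])^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- m[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(m, 2, centers[j, ])^2))
    }
  }
  centers
}

#' Seeded best-of-restarts k-means
#'
#' Lloyd iterations (squared Euclidean distance) from k-means++ starting
#' centers, repeated `nRestarts` times; the solution with the smallest
#' within-cluster sum of squares wins. Clusters are relabelled by ascending
#' centroid mean so that cluster 1 is always the lowest-scoring group.
#' Deterministic given `seed`.
#'
#' @param scores Complete-case [ScoreExperiment-class] or children x tests
#'   matrix.
#' @param k Number of clusters (`1 <= k <= n`).
#' @param seed,nRestarts Reproducibility and restart count (default 10).
#' @return List with `labels` (integer per child), `centroids` (k x tests),
#'   and `withinss` (total within-cluster sum of squares).
#' @export
kmeansScores <- function(scores, k, seed = 1L, nRestarts = 10L) {
  m <- asChildMatrix(scores)
  n <- nrow(m)
  if (k > n) stop("k (", k, ") cannot exceed the number of children (", n, ")")
  if (k == 1L) {
    cen <- matrix(colMeans(m), 1, ncol(m),
                  dimnames = list(NULL, colnames(m)))
    return(list(labels = rep(1L, n), centroids = cen,
                withinss = sum(sweep(m, 2, cen[1, ])^2)))
  }
  set.seed(deriveSeed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    init <- kmeansppInit(m, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(m, centers = init, iter.max = 300L,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("k-means failed for every restart (k = ", k, ")")
  ord <- order(rowMeans(best$centers))
  relabel <- match(seq_len(k), ord)
  labels <- relabel[best$cluster]
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- NULL
  names(labels) <- rownames(m)
  list(labels = labels, centroids = centroids,
       withinss = best$tot.withinss)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion, normalized by degrees of
#' freedom: `(B / (k - 1)) / (W / (n - k))`, with
#' `B = sum_c n_c ||mu_c - mu||^2` and `W = sum_i ||x_i - mu_{c(i)}||^2`.
#' Larger is better.
#'
#' @param m Children x tests matrix.
#' @param labels Integer cluster labels.
#' @return The CH value.
#' @export
calinskiHarabasz <- function(m, labels) {
  m <- as.matrix(m)
  n <- nrow(m)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) stop("CH requires at least 2 clusters")
  mu <- colMeans(m)
  B <- 0; W <- 0
  for (c in ks) {
    mc <- m[labels == c, , drop = FALSE]
    muc <- colMeans(mc)
    B <- B + nrow(mc) * sum((muc - mu)^2)
    W <- W + sum(sweep(mc, 2, muc)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-pair similarity
#' `max_{j != i} (S_i + S_j) / M_ij`, with `S_i` the mean Euclidean distance
#' of cluster i's points to its centroid and `M_ij` the distance between
#' centroids. Smaller is better.
#'
#' @inheritParams calinskiHarabasz
#' @return The DB value.
#' @export
daviesBouldin <- function(m, labels) {
  m <- as.matrix(m)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) stop("DB requires at least 2 clusters")
  cen <- t(vapply(ks, function(c) colMeans(m[labels == c, , drop = FALSE]),
                  numeric(ncol(m))))
  S <- vapply(seq_len(k), function(i) {
    mc <- m[labels == ks[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(mc, 2, cen[i, ])^2)))
  }, numeric(1))
  Rmax <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (S[i] + S[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(Rmax)
}

#' Select the number of clusters
#'
#' Fits seeded k-means for every candidate k and evaluates both criteria.
#' The selected k maximizes Calinski-Harabasz; the Davies-Bouldin argmin is
#' reported alongside with a disagreement flag (when the criteria disagree,
#' CH decides).
#'
#' @param scores Complete-case [ScoreExperiment-class] or matrix.
#' @param kRange Candidate cluster counts (default 2:10).
#' @param seed,nRestarts Passed to [kmeansScores()].
#' @return A [ClusterModel-class] with labels/centroids at the selected k
#'   and the full CH/DB traces.
#' @export
selectK <- function(scores, kRange = 2:10, seed = 1L, nRestarts = 10L) {
  m <- asChildMatrix(scores)
  if (all(apply(m, 2, function(x) length(unique(x)) == 1L))) {
    stop("all children have identical scores: zero dispersion, ",
         "cluster criteria are undefined")
  }
  kRange <- as.integer(kRange[kRange <= nrow(m) - 1L & kRange >= 2L])
  if (!length(kRange)) stop("no feasible k in kRange for n = ", nrow(m))
  fits <- list()
  ch <- db <- setNames(numeric(length(kRange)), paste0("k", kRange))
  for (i in seq_along(kRange)) {
    fit <- kmeansScores(m, kRange[i], seed = seed + i - 1L,
                        nRestarts = nRestarts)
    fits[[i]] <- fit
    ch[i] <- calinskiHarabasz(m, fit$labels)
    db[i] <- daviesBouldin(m, fit$labels)
  }
  iCh <- which.max(ch)
  iDb <- which.min(db)
  best <- fits[[iCh]]
  new("ClusterModel",
      k = kRange[iCh], kDb = kRange[iDb],
      disagreement = kRange[iCh] != kRange[iDb],
      labels = best$labels, centroids = best$centroids,
      chByK = ch, dbByK = db,
      subLabels = character(0), subModels = list(),
      seed = as.integer(seed), nRestarts = as.integer(nRestarts))
}

#' Nested sub-clustering
#'
#' Re-runs [selectK()] independently inside each top-level cluster and
#' records nested labels (`"1.1"`, `"1.2"`, ...; sub-clusters relabelled by
#' ascending mean). Clusters too small to split (`n < 2 * min(kRange)`) are
#' kept whole with a message. A graded-transition check verifies that mean
#' scores increase along the nested ordering and messages when they do not.
#'
#' @param scores The complete-case scores the model was fitted on.
#' @param model A fitted [ClusterModel-class].
#' @param kRange Candidate sub-cluster counts (default 2:10).
#' @param seed,nRestarts Passed down to the nested selection.
#' @return The model with `subLabels` and `subModels` filled in.
#' @export
subcluster <- function(scores, model, kRange = 2:10, seed = 1L,
                       nRestarts = 10L) {
  m <- asChildMatrix(scores)
  subLabels <- character(nrow(m))
  subModels <- list()
  for (c in seq_len(model@k)) {
    idx <- which(model@labels == c)
    if (length(idx) < 2L * min(kRange)) {
      message("cluster ", c, " too small to sub-split (n = ", length(idx),
              "); kept whole")
      subLabels[idx] <- paste0(c, ".1")
      next
    }
    sub <- selectK(m[idx, , drop = FALSE], kRange = kRange,
                   seed = deriveSeed(seed, paste0("sub", c)) %% 100000L,
                   nRestarts = nRestarts)
    subModels[[as.character(c)]] <- sub
    subLabels[idx] <- paste0(c, ".", sub@labels)
  }
  names(subLabels) <- rownames(m)
  model@subLabels <- subLabels
  model@subModels <- subModels
  means <- tapply(rowMeans(m), subLabels, mean)
  means <- means[order(names(means))]
  if (is.unsorted(means)) {
    message("sub-cluster mean scores are not graded along the nested ",
            "ordering")
  }
  model
}

#' Per-cluster test profiles
#'
#' Mean and standard error of the mean for every test within every cluster,
#' in battery order or any supplied ordering (e.g. from
#' [sortBySummedCorrelation()]). For each cluster the profile is compared
#' against its own linear trend along the ordering: tests whose cluster
#' mean falls more than `nSd` population standard deviations (the SD of the
#' per-test population means) below that trend are flagged as outliers.
#'
#' @param scores Complete-case scores.
#' @param labels Integer cluster labels per child.
#' @param battery Battery metadata.
#' @param ordering Optional test ordering (integer indices); default
#'   battery order.
#' @param nSd Flagging depth in population SDs (default 1.5).
#' @return List with `profiles` (data.frame: cluster, test_id, mean, sem)
#'   and `flagged` (per-cluster integer vectors of flagged test ids).
#' @export
clusterProfiles <- function(scores, labels, battery = defaultBattery(),
                            ordering = NULL, nSd = 1.5) {
  m <- asChildMatrix(scores)
  if (is.null(ordering)) ordering <- seq_len(ncol(m))
  ks <- sort(unique(labels))
  if (any(tabulate(labels) == 0L)) stop("empty cluster in labels")
  popSd <- sd(colMeans(m))
  profiles <- do.call(rbind, lapply(ks, function(c) {
    mc <- m[labels == c, , drop = FALSE]
    if (!nrow(mc)) stop("cluster ", c, " is empty")
    data.frame(cluster = c, test_id = battery$test_id,
               mean = colMeans(mc),
               sem = apply(mc, 2, sd) / sqrt(nrow(mc)),
               row.names = NULL)
  }))
  flagged <- lapply(ks, function(c) {
    y <- profiles$mean[profiles$cluster == c][ordering]
    rank <- seq_along(y)
    trend <- lm(y ~ rank)$fitted.values
    battery$test_id[ordering][y < trend - nSd * popSd]
  })
  names(flagged) <- paste0("cluster", ks)
  list(profiles = profiles, flagged = flagged)
}

#' Cluster centroid separation by age group
#'
#' Per age group, the centroids of the two (or more) clusters and the
#' absolute per-test centroid difference, plus a linear trend test of the
#' mean |difference| over group index (flat when the planted offset is
#' constant with age). Groups missing a cluster are skipped with a message.
#'
#' @param scores Complete-case scores.
#' @param labels Cluster labels per child.
#' @param ageGroupsVec Age-group label per child.
#' @return List with `centroids` (per-group list of cluster x tests
#'   matrices), `absDiff` (per-group per-test |centroid difference| for the
#'   first cluster pair), `meanAbsDiff`, and `trend` (slope, se, p) when
#'   at least 3 groups are available.
#' @export
centroidDistanceByAge <- function(scores, labels, ageGroupsVec) {
  m <- asChildMatrix(scores)
  ks <- sort(unique(labels))
  groups <- sort(unique(ageGroupsVec))
  centroids <- list(); absDiff <- list(); meanAbsDiff <- numeric(0)
  for (g in groups) {
    idx <- which(ageGroupsVec == g)
    if (!all(ks %in% labels[idx])) {
      message("age group ", g, " lacks at least one cluster; skipped")
      next
    }
    cen <- t(vapply(ks, function(c) {
      colMeans(m[idx[labels[idx] == c], , drop = FALSE])
    }, numeric(ncol(m))))
    centroids[[as.character(g)]] <- cen
    d <- abs(cen[2, ] - cen[1, ])
    absDiff[[as.character(g)]] <- d
    meanAbsDiff[as.character(g)] <- mean(d)
  }
  trend <- NULL
  if (length(meanAbsDiff) >= 3L) {
    gi <- as.numeric(names(meanAbsDiff))
    co <- summary(lm(meanAbsDiff ~ gi))$coefficients
    trend <- c(slope = co["gi", "Estimate"], se = co["gi", "Std. Error"],
               p = co["gi", "Pr(>|t|)"])
  }
  list(centroids = centroids, absDiff = absDiff,
       meanAbsDiff = meanAbsDiff, trend = trend)
}
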