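# KNN classification of cluster membership with stratified cross-validation
# and centrality-ranked feature subsets.
#
# The classifier is implemented directly (squared Euclidean distances on
# normalized scores) because the pipeline fixes deterministic tie rules:
# distance ties are broken by the smallest training index, vote ties by the
# label of the single nearest neighbour.

# Squared Euclidean cross-distance matrix: rows = test points, cols = train.
crossDist2 <- function(test, train) {
  outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) -
    2 * tcrossprod(test, train)
}

# Predict labels for `test` given `train` rows and their labels.
knnPredict <- function(train, trainLabels, test, k) {
  d2 <- crossDist2(test, train)
  trainLabels <- as.character(trainLabels)
  apply(d2, 1, function(d) {
    ord <- order(d, seq_along(d))
    nn <- trainLabels[ord[seq_len(min(k, length(d)))]]
    votes <- table(nn)
    winners <- names(votes)[votes == max(votes)]
    if (length(winners) == 1L) winners else nn[1L]
  })
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratifiedFolds <- function(labels, nFolds) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < nFolds) {
      stop("class '", cl, "' has only ", length(idx), " members, fewer ",
           "than nFolds = ", nFolds, "; reduce nFolds or merge classes")
    }
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  }
  fold
}

#' Cross-validated KNN misclassification loss
#'
#' Stratified k-fold cross-validation (default tenfold) of a k-nearest
#' neighbour classifier over a grid of neighbour counts. Loss is the
#' held-out misclassification rate. Deterministic given `seed`.
#'
#' @param features Children x features matrix (normalized scores).
#' @param labels Class label per child (at least 2 classes, each with at
#'   least `nFolds` members).
#' @param kValues Neighbour counts to evaluate.
#' @param nFolds Folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Named numeric vector of losses, one per entry of `kValues`.
#' @export
knnCvLoss <- function(features, labels, kValues = c(1, 5, 10, 20, 40),
                      nFolds = 10L, seed = 1L) {
  m <- asChildMatrix(features)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("at least 2 classes are required")
  if (nrow(m) < nFolds) stop("n must be at least nFolds")
  set.seed(deriveSeed(seed, "knn-folds"))
  fold <- stratifiedFolds(labels, nFolds)
  wrong <- setNames(numeric(length(kValues)), paste0("k", kValues))
  for (f in seq_len(nFolds)) {
    test <- fold == f
    for (i in seq_along(kValues)) {
      pred <- knnPredict(m[!test, , drop = FALSE], labels[!test],
                         m[test, , drop = FALSE], kValues[i])
      wrong[i] <- wrong[i] + sum(pred != labels[test])
    }
  }
  wrong / nrow(m)
}

#' Select the neighbour count
#'
#' The neighbour count minimizing cross-validation loss; ties go to the
#' smallest k.
#'
#' @param cvLossByK Named loss vector from [knnCvLoss()] (names `"k<n>"`)
#'   or a numeric vector with `kValues` as names/indices.
#' @return The optimal neighbour count (integer).
#' @examples
#' selectNeighbors(c(k5 = 0.2, k20 = 0.1, k40 = 0.1))  # 20
#' @export
selectNeighbors <- function(cvLossByK) {
  if (!length(cvLossByK)) stop("empty loss map")
  ks <- as.integer(sub("^k", "", names(cvLossByK)))
  if (any(is.na(ks))) ks <- seq_along(cvLossByK)
  ord <- order(cvLossByK, ks)
  ks[ord[1L]]
}

#' KNN performance over centrality-ranked feature groups
#'
#' For each percentile group of a [CentralityResult-class] (nested test
#' sets of increasing summed betweenness), cross-validates a KNN classifier
#' on just those tests and reports overall accuracy and per-class recall.
#' Supports 2-class (main cluster) and 4-class (sub-cluster) targets and
#' arbitrary cohort subsets (e.g. one nationality) via prior subsetting.
#' Empty feature groups are skipped with a message.
#'
#' @param scores Complete-case [ScoreExperiment-class] or matrix.
#' @param labels Cluster or sub-cluster label per child.
#' @param centrality A [CentralityResult-class].
#' @param nNeighbors Neighbour count (default 20).
#' @param nFolds,seed Cross-validation parameters.
#' @return List of reports, one per percentile group, each with
#'   `featureSetId`, `nFeatures`, `accuracy` and `perClassAccuracy`
#'   (recall per class); plus attribute `"summary"` data.frame.
#' @export
bcSubsetPerformance <- function(scores, labels, centrality,
                                nNeighbors = 20L, nFolds = 10L, seed = 1L) {
  m <- asChildMatrix(scores)
  labels <- as.character(labels)
  reports <- list()
  for (gname in names(centrality@percentileGroups)) {
    tests <- centrality@percentileGroups[[gname]]
    if (!length(tests)) {
      message("feature group ", gname, " is empty; skipped")
      next
    }
    feat <- m[, tests, drop = FALSE]
    set.seed(deriveSeed(seed, paste0("bc-", gname)))
    fold <- stratifiedFolds(labels, nFolds)
    pred <- character(nrow(feat))
    for (f in seq_len(nFolds)) {
      test <- fold == f
      pred[test] <- knnPredict(feat[!test, , drop = FALSE], labels[!test],
                               feat[test, , drop = FALSE], nNeighbors)
    }
    classes <- sort(unique(labels))
    recall <- vapply(classes, function(cl) {
      mean(pred[labels == cl] == cl)
    }, numeric(1))
    reports[[gname]] <- list(
      featureSetId = gname, nFeatures = length(tests),
      accuracy = mean(pred == labels),
      perClassAccuracy = recall)
  }
  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(featureSetId = r$featureSetId, nFeatures = r$nFeatures,
               accuracy = r$accuracy, row.names = NULL)
  }))
  attr(reports, "summary") <- summary
  reports
}
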