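# Ability network: thresholded binary graph on the 52 tests and its
# betweenness centrality.

#' Binary adjacency from a correlation matrix
#'
#' Edge (i, j) present iff `r(i, j) >= threshold` for `i != j`; no
#' self-loops. Missing correlations yield no edge.
#'
#' @param cm A [CorrMatrix-class] or plain symmetric correlation matrix.
#' @param threshold Correlation cutoff in (-1, 1); default 0.5, the value
#'   used for the binary centrality analysis.
#' @return Logical adjacency matrix (undirected, no self-loops).
#' @examples
#' r <- matrix(0.9, 3, 3); diag(r) <- 1
#' thresholdAdjacency(r, 0.5)
#' @export
thresholdAdjacency <- function(cm, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= -1 || threshold >= 1) {
    stop("threshold must lie strictly inside (-1, 1)")
  }
  r <- if (is(cm, "CorrMatrix")) cm@r else cm
  adj <- !is.na(r) & r >= threshold
  diag(adj) <- FALSE
  adj | t(adj)
}

#' Betweenness centrality of an unweighted graph
#'
#' Unnormalized node betweenness computed with Brandes' accumulation:
#' for every unordered pair (s, t) of distinct nodes, each intermediate
#' node v accrues the fraction of shortest s-t paths passing through it.
#' Disconnected components are handled independently; isolated nodes score
#' 0. A path a-b-c gives BC(b) = 1; a star with L leaves gives the center
#' choose(L, 2).
#'
#' @param adj Logical/0-1 symmetric adjacency matrix without self-loops.
#' @return Numeric vector of betweenness values (all `>= 0`), one per node.
#' @examples
#' path <- matrix(0, 3, 3); path[1, 2] <- path[2, 3] <- 1
#' betweennessCentrality(path | t(path))
#' @export
betweennessCentrality <- function(adj) {
  adj <- unname(as.matrix(adj)) != 0
  n <- nrow(adj)
  if (n != ncol(adj)) stop("adjacency matrix must be square")
  if (!identical(adj, t(adj))) stop("adjacency matrix must be symmetric")
  diag(adj) <- FALSE
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  bc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    stack <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      stack <- c(stack, v)
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(stack)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  bc / 2
}

#' Betweenness centrality per age group
#'
#' For each 6-month age group: correlation matrix of that group's children,
#' binary graph at `threshold`, Brandes betweenness per test.
#'
#' @param scores Complete-case [ScoreExperiment-class] or matrix.
#' @param ageGroupsVec Group label per child; defaults to [ageGroups()].
#' @param threshold Correlation cutoff (default 0.5).
#' @return Groups x tests matrix of betweenness values.
#' @export
bcByAgeGroup <- function(scores, ageGroupsVec = NULL, threshold = 0.5) {
  if (is.null(ageGroupsVec)) ageGroupsVec <- ageGroups(scores)
  m <- asChildMatrix(scores)
  groups <- sort(unique(ageGroupsVec))
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(m),
                dimnames = list(paste0("g", groups), colnames(m)))
  for (i in seq_along(groups)) {
    idx <- which(ageGroupsVec == groups[i])
    cmg <- correlationMatrix(m[idx, , drop = FALSE])
    out[i, ] <- betweennessCentrality(thresholdAdjacency(cmg, threshold))
  }
  out
}

#' Summed betweenness and percentile feature groups
#'
#' Sums each test's betweenness over the age-group networks and defines
#' nested groups of tests at increasing percentile cutoffs of the
#' summed-BC distribution (a higher cutoff gives a subset of any lower
#' one; the 0th percentile group is the whole battery). Also reports the
#' ten tests with the highest and the ten with the lowest summed BC for
#' developmental-profile comparisons.
#'
#' @param bcGroupMatrix Groups x tests betweenness matrix from
#'   [bcByAgeGroup()].
#' @param percentiles Increasing percentile cutoffs (default
#'   `c(0, 20, 40, 60, 80)`, five nested groups).
#' @param threshold Correlation cutoff recorded in the result.
#' @return A [CentralityResult-class].
#' @export
summedBcAndGroups <- function(bcGroupMatrix,
                              percentiles = c(0, 20, 40, 60, 80),
                              threshold = 0.5) {
  if (!length(percentiles)) stop("percentile list must not be empty")
  if (is.unsorted(percentiles)) percentiles <- sort(percentiles)
  summed <- colSums(bcGroupMatrix)
  groups <- lapply(percentiles, function(p) {
    cut <- quantile(summed, p / 100, names = FALSE, type = 7)
    which(summed >= cut)
  })
  names(groups) <- paste0("p", percentiles)
  nTests <- length(summed)
  nTop <- min(10L, nTests)
  ordDesc <- order(-summed, seq_along(summed))
  ordAsc <- order(summed, seq_along(summed))
  new("CentralityResult",
      bcByGroup = bcGroupMatrix, summedBc = summed,
      threshold = threshold, percentiles = as.numeric(percentiles),
      percentileGroups = groups,
      topTests = as.integer(ordDesc[seq_len(nTop)]),
      bottomTests = as.integer(ordAsc[seq_len(nTop)]))
}
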