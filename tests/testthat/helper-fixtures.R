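# Shared fixtures, built in code. Heavier cohorts are cached per session so
# several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# Study-replica cohort at a fixed seed, complete cases only.
defaultCohortFixture <- function(seed = 1L) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- filterComplete(generateCohort(
      defaultCohortConfig(seed = seed)))
  }
  .fixtures[[key]]
}

# Small two-blob matrix with well-separated clusters (children x tests).
blobMatrix <- function(n1 = 40, n2 = 40, d = 10, sep = 0.4, sd = 0.05,
                       seed = 42) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(n1 * d, 0.3, sd), n1, d),
    matrix(rnorm(n2 * d, 0.3 + sep, sd), n2, d))
  pmin(pmax(m, 0), 1)
}

# Independent brute-force betweenness oracle: exhaustive enumeration of all
# shortest paths per node pair (recursive), counting interior visits.
bruteForceBC <- function(adj) {
  adj <- as.matrix(adj) != 0
  n <- nrow(adj)
  # BFS distances from each source
  distFrom <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ])) {
          if (is.infinite(d[w])) { d[w] <- d[v] + 1; nxt <- c(nxt, w) }
        }
      }
      frontier <- nxt
    }
    d
  }
  D <- t(vapply(seq_len(n), distFrom, numeric(n)))
  bc <- numeric(n)
  enumerate <- function(s, t) {
    # all shortest s-t paths as vectors of interior nodes
    paths <- list()
    walk <- function(v, interior) {
      if (v == t) { paths[[length(paths) + 1L]] <<- interior; return() }
      for (w in which(adj[v, ])) {
        if (D[s, w] == D[s, v] + 1 && D[w, t] == D[s, t] - D[s, w]) {
          walk(w, if (w == t) interior else c(interior, w))
        }
      }
    }
    walk(s, integer(0))
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(D[s, t])) next
      paths <- enumerate(s, t)
      if (!length(paths)) next
      visits <- table(unlist(paths))
      if (length(visits)) {
        ids <- as.integer(names(visits))
        bc[ids] <- bc[ids] + as.numeric(visits) / length(paths)
      }
    }
  }
  bc
}

# Random symmetric adjacency matrix without self-loops.
randomAdjacency <- function(n, p) {
  a <- matrix(rbinom(n * n, 1, p), n, n)
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  diag(a) <- 0
  a
}
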