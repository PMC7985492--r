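# Internal helpers shared across modules.

# Clamp values into the normalized score range [0, 1]; NA passes through.
clip01 <- function(x) {
  x[!is.na(x) & x < 0] <- 0
  x[!is.na(x) & x > 1] <- 1
  x
}

#' Derive a stream seed from a root seed
#'
#' All stochastic stages derive their own seed from one root seed and a
#' purpose label, so that a single integer reproduces a whole pipeline run
#' while keeping the streams of different stages decoupled. The rule is a
#' fixed multiplicative hash of the label mixed with the root seed, reduced
#' modulo 2^31 - 1 (so the result is always a valid 32-bit seed).
#'
#' @param root Integer root seed.
#' @param purpose Character label naming the consuming stage
#'   (e.g. `"ages"`, `"kmeans"`).
#' @return A single integer seed.
#' @examples
#' deriveSeed(1L, "kmeans")
#' @export
deriveSeed <- function(root, purpose) {
  stopifnot(is.numeric(root), length(root) == 1L, !is.na(root),
            is.character(purpose), length(purpose) == 1L)
  codes <- utf8ToInt(purpose)
  h <- sum(codes * seq_along(codes) * 1009)
  as.integer((abs(root) * 48271 + h) %% 2147483647)
}

# Coerce the various accepted score representations to a complete-case
# children x tests numeric matrix. Errors on missing values unless
# allowNA = TRUE.
asChildMatrix <- function(scores, allowNA = FALSE) {
  if (is(scores, "ScoreExperiment") || is(scores, "SummarizedExperiment")) {
    m <- t(assay(scores, "scores"))
  } else if (is.matrix(scores)) {
    m <- scores
  } else if (is.data.frame(scores)) {
    m <- as.matrix(scores)
  } else {
    stop("'scores' must be a ScoreExperiment or a children x tests matrix")
  }
  storage.mode(m) <- "double"
  if (!allowNA && anyNA(m)) {
    stop("scores contain missing values; apply filterComplete() first")
  }
  m
}

# Mean of the off-diagonal entries of a square matrix (NA-tolerant).
meanOffDiag <- function(r) {
  mean(r[row(r) != col(r)], na.rm = TRUE)
}

# Empirical two-sided permutation p-value with the +1 correction, so the
# minimal attainable value is 1/(nSurrogates + 1).
empiricalP <- function(countGE, nSurrogates) {
  (1 + countGE) / (1 + nSurrogates)
}
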