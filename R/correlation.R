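# Correlation structure of the battery: Pearson matrices, surrogate
# significance, sorting, per-function contrasts and age-group trends.

#' Pairwise test-correlation matrix
#'
#' Pearson product-moment correlations between every pair of the 52 tests
#' over complete-case children. "Peak global cross-correlation" reduces to
#' the plain Pearson correlation of score vectors for cross-sectional data
#' (there are no lags to scan).
#'
#' @param scores A [ScoreExperiment-class] or children x tests matrix; rows
#'   with any missing score are dropped (at least 3 must remain).
#' @return A [CorrMatrix-class] (no significance mask; see
#'   [surrogateSignificance()]). Tests with zero variance get `NA`
#'   correlations and a warning.
#' @examples
#' m <- cbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(0, 1, 0))
#' correlationMatrix(m)@r
#' @export
correlationMatrix <- function(scores) {
  m <- asChildMatrix(scores, allowNA = TRUE)
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) stop("at least 3 complete-case children are required")
  sds <- apply(m, 2, sd)
  degenerate <- which(sds == 0 | is.na(sds))
  r <- suppressWarnings(cor(m))
  if (length(degenerate)) {
    warning("tests with zero variance: ",
            paste(degenerate, collapse = ", "),
            "; their correlations are set to missing")
    r[degenerate, ] <- NA_real_
    r[, degenerate] <- NA_real_
  }
  diag(r) <- 1
  new("CorrMatrix", r = r, pValues = matrix(numeric(0), 0, 0),
      sigMask = matrix(logical(0), 0, 0), nSurrogates = 0L,
      alpha = NA_real_, nChildren = nrow(m))
}

#' Surrogate-permutation significance of test correlations
#'
#' Builds an empirical null for every correlation pair by shuffling each
#' child's scores across the 52 tests (each surrogate permutes every row of
#' the children x tests matrix independently), recomputing the full
#' correlation matrix per surrogate. The two-sided empirical p-value per
#' pair is `(1 + #{|r_surr| >= |r_obs|}) / (1 + nSurrogates)`, so the
#' minimal attainable value is `1/(nSurrogates + 1)`.
#'
#' @param scores Complete-case [ScoreExperiment-class] or children x tests
#'   matrix.
#' @param nSurrogates Number of surrogate datasets (default 1000).
#' @param alpha Significance level for the mask (default 0.05).
#' @param seed Seed for the permutation stream.
#' @return A [CorrMatrix-class] with `pValues` and `sigMask` filled in.
#' @export
surrogateSignificance <- function(scores, nSurrogates = 1000L, alpha = 0.05,
                                  seed = 1L) {
  if (nSurrogates < 1L) stop("nSurrogates must be >= 1")
  m <- asChildMatrix(scores)
  cm <- correlationMatrix(m)
  absObs <- abs(cm@r)
  nT <- ncol(m)
  count <- matrix(0L, nT, nT)
  set.seed(deriveSeed(seed, "surrogates"))
  for (s in seq_len(nSurrogates)) {
    perm <- t(vapply(seq_len(nrow(m)),
                     function(i) m[i, sample.int(nT)], numeric(nT)))
    rs <- suppressWarnings(cor(perm))
    count <- count + (abs(rs) >= absObs)
  }
  p <- empiricalP(count, nSurrogates)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(cm@r)
  mask <- !is.na(p) & p < alpha
  new("CorrMatrix", r = cm@r, pValues = p, sigMask = mask,
      nSurrogates = as.integer(nSurrogates), alpha = alpha,
      nChildren = cm@nChildren)
}

#' Order tests by summed correlation
#'
#' Descending order of the row sums of the correlation matrix (diagonal
#' excluded); ties broken by test id, so an all-equal matrix returns the
#' identity ordering.
#'
#' @param cm A [CorrMatrix-class] or plain correlation matrix.
#' @return Integer vector: test indices from highest to lowest summed
#'   correlation.
#' @export
sortBySummedCorrelation <- function(cm) {
  r <- if (is(cm, "CorrMatrix")) cm@r else cm
  sums <- rowSums(r, na.rm = TRUE) - ifelse(is.na(diag(r)), 0, diag(r))
  order(-sums, seq_along(sums))
}

#' Per-function correlation contrast
#'
#' For each neuropsychological function, a one-tailed Wilcoxon rank-sum
#' test of whether the off-diagonal correlations involving that function's
#' tests are smaller than the remaining off-diagonal correlations (the
#' direction in which attention/memory stood out in the source design).
#'
#' @param cm A [CorrMatrix-class].
#' @param battery Battery metadata aligning tests to functions.
#' @return Named list of [StatTestResult-class], one per function.
#' @export
functionCorrelationContrast <- function(cm, battery = defaultBattery()) {
  r <- cm@r
  ut <- upper.tri(r)
  fns <- as.character(battery$fn)
  out <- list()
  for (f in levels(battery$fn)) {
    inFn <- fns == f
    involves <- outer(inFn, inFn, "|") & ut
    rest <- !outer(inFn, inFn, "|") & ut
    wt <- suppressWarnings(
      wilcox.test(r[involves], r[rest], alternative = "less", exact = FALSE))
    out[[f]] <- StatTestResult(wt$statistic, wt$p.value,
                               "wilcoxon_rank_sum", tails = "one")
  }
  out
}

#' Correlation trend over age groups
#'
#' Splits the cohort by 6-month age group, computes one correlation matrix
#' per group, and summarizes each by its mean off-diagonal correlation; a
#' least-squares line over the group index quantifies the developmental
#' trend. Groups with fewer than 3 children are skipped with a message.
#'
#' @param scores Complete-case [ScoreExperiment-class] or matrix.
#' @param ageGroupsVec Group label per child; defaults to [ageGroups()] of
#'   the object.
#' @return List with `perGroup` (CorrMatrix per retained group), `means`
#'   (named mean off-diagonal correlation per group), `slope`, `intercept`
#'   and `slopeSe` of the linear fit of mean on group index.
#' @export
ageGroupCorrelationTrend <- function(scores, ageGroupsVec = NULL) {
  if (is.null(ageGroupsVec)) ageGroupsVec <- ageGroups(scores)
  m <- asChildMatrix(scores)
  groups <- sort(unique(ageGroupsVec))
  perGroup <- list()
  means <- numeric(0)
  for (g in groups) {
    idx <- which(ageGroupsVec == g)
    if (length(idx) < 3L) {
      message("age group ", g, " has fewer than 3 children; skipped")
      next
    }
    cmg <- correlationMatrix(m[idx, , drop = FALSE])
    perGroup[[as.character(g)]] <- cmg
    means[as.character(g)] <- meanOffDiag(cmg@r)
  }
  if (length(means) >= 2L) {
    gi <- as.numeric(names(means))
    fit <- lm(means ~ gi)
    co <- summary(fit)$coefficients
    slope <- co["gi", "Estimate"]
    slopeSe <- co["gi", "Std. Error"]
    intercept <- co["(Intercept)", "Estimate"]
  } else {
    slope <- intercept <- slopeSe <- NA_real_
  }
  list(perGroup = perGroup, means = means, slope = slope,
       intercept = intercept, slopeSe = slopeSe)
}

#' First derivative of the correlation trend
#'
#' Differences of the mean correlation between contiguous age groups,
#' `diff[g] = mean[g+1] - mean[g]`.
#'
#' @param perGroupMeans Numeric vector of per-group mean correlations
#'   (length >= 2).
#' @return Numeric vector of length `length(perGroupMeans) - 1`.
#' @examples
#' correlationDerivative(c(0.1, 0.2, 0.3))
#' @export
correlationDerivative <- function(perGroupMeans) {
  if (length(perGroupMeans) < 2L) {
    stop("at least two age groups are needed to take differences")
  }
  diff(perGroupMeans)
}
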