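# Developmental trajectories: global score, per-group OLS on age in months,
# bootstrap contrasts and size-matched subsample regressions.

#' Per-child global score
#'
#' Arithmetic mean of the 52 normalized test scores. Requires complete
#' cases (run [filterComplete()] first).
#'
#' @param scores A complete-case [ScoreExperiment-class] or children x
#'   tests matrix.
#' @return Numeric vector, one global score per child.
#' @export
globalScore <- function(scores) {
  m <- asChildMatrix(scores)
  rowMeans(m)
}

# Closed-form simple OLS of y on x with coefficient standard errors.
olsLine <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("at least 3 observations per group are required")
  if (var(x) == 0) stop("zero age variance in group; slope is undefined")
  xc <- x - mean(x)
  m <- sum(xc * y) / sum(xc^2)
  b <- mean(y) - m * mean(x)
  res <- y - (b + m * x)
  s2 <- sum(res^2) / (n - 2)
  mSe <- sqrt(s2 / sum(xc^2))
  bSe <- sqrt(s2 * (1 / n + mean(x)^2 / sum(xc^2)))
  c(m = m, b = b, mSe = mSe, bSe = bSe, n = n)
}

#' Linear age trajectories per group
#'
#' Ordinary least squares of the global score on age in months within each
#' group (cluster or nationality), with coefficient standard errors. When
#' more than one group is present, slopes and intercepts are contrasted
#' between groups through bootstrap resampling: per bootstrap replicate the
#' children of each group are resampled and refitted, and the two-sided
#' empirical p-value of each pairwise contrast is computed from the
#' bootstrap distribution of the coefficient difference (Bonferroni
#' corrected across pairs).
#'
#' @param globalScores Numeric vector from [globalScore()].
#' @param agesMonths Ages in months (same length).
#' @param groupLabels Group label per child (single group when `NULL`).
#' @param nBoot Bootstrap replicates for the contrasts (default 1000).
#' @param seed Seed for the bootstrap stream.
#' @return List with `fits` (data.frame: group, m, b, mSe, bSe, n),
#'   `slopeContrast` and `interceptContrast` (data.frames of pairwise
#'   empirical p-values, `NULL` for a single group) and `boot` (long
#'   data.frame of bootstrap coefficients).
#' @export
fitTrajectory <- function(globalScores, agesMonths, groupLabels = NULL,
                          nBoot = 1000L, seed = 1L) {
  if (is.null(groupLabels)) groupLabels <- rep("all", length(globalScores))
  groupLabels <- as.character(groupLabels)
  groups <- sort(unique(groupLabels))
  fits <- do.call(rbind, lapply(groups, function(g) {
    idx <- groupLabels == g
    co <- olsLine(agesMonths[idx], globalScores[idx])
    data.frame(group = g, m = co["m"], b = co["b"], mSe = co["mSe"],
               bSe = co["bSe"], n = co["n"], row.names = NULL)
  }))
  slopeContrast <- interceptContrast <- NULL
  boot <- NULL
  if (length(groups) > 1L && nBoot > 0L) {
    set.seed(deriveSeed(seed, "trajectory-boot"))
    boot <- do.call(rbind, lapply(groups, function(g) {
      idx <- which(groupLabels == g)
      reps <- t(vapply(seq_len(nBoot), function(b) {
        take <- sample(idx, length(idx), replace = TRUE)
        olsLine(agesMonths[take], globalScores[take])[c("m", "b")]
      }, numeric(2)))
      data.frame(group = g, m = reps[, 1], b = reps[, 2])
    }))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    contrast <- function(coefName) {
      out <- do.call(rbind, lapply(pairs, function(pr) {
        d <- boot[boot$group == pr[1], coefName] -
          boot[boot$group == pr[2], coefName]
        p <- 2 * min(empiricalP(sum(d <= 0), nBoot),
                     empiricalP(sum(d >= 0), nBoot))
        data.frame(group1 = pr[1], group2 = pr[2], p = min(p, 1))
      }))
      out$pAdjusted <- pmin(out$p * length(pairs), 1)
      out
    }
    slopeContrast <- contrast("m")
    interceptContrast <- contrast("b")
  }
  list(fits = fits, slopeContrast = slopeContrast,
       interceptContrast = interceptContrast, boot = boot)
}

#' Size-matched subsample regressions
#'
#' For each fraction, repeatedly draws equal-size subsamples (without
#' replacement; size = fraction x smallest group) from every group, fits
#' the OLS line of global score on age, and summarizes the coefficient
#' distributions. Group differences per fraction are assessed with a
#' Kruskal-Wallis test across the subsample coefficient distributions
#' (the paper-style contrast for size-matched regressions). Fractions whose
#' subsample size falls below 3 are skipped with a message.
#'
#' @param globalScores,agesMonths,groupLabels As in [fitTrajectory()].
#' @param fractions Subsample fractions (default `seq(0.2, 0.9, 0.1)`).
#' @param nIter Iterations per fraction (default 1000).
#' @param seed Seed for the subsampling stream.
#' @return List with `draws` (long data.frame: fraction, iter, group, m,
#'   b), `summary` (mean and SD of m and b per group per fraction) and
#'   `contrasts` (per fraction, KW p-values for slopes and intercepts; only
#'   with >1 group).
#' @export
subsampleRegressions <- function(globalScores, agesMonths, groupLabels,
                                 fractions = seq(0.2, 0.9, by = 0.1),
                                 nIter = 1000L, seed = 1L) {
  groupLabels <- as.character(groupLabels)
  groups <- sort(unique(groupLabels))
  minN <- min(table(groupLabels))
  set.seed(deriveSeed(seed, "subsample"))
  feasible <- fractions[floor(fractions * minN) >= 3L]
  for (f in setdiff(fractions, feasible)) {
    message("fraction ", f, " gives subsamples of size ",
            floor(f * minN), " (< 3); skipped")
  }
  if (!length(feasible)) stop("no feasible fraction; nothing to report")
  total <- length(feasible) * nIter * length(groups)
  coefs <- matrix(NA_real_, total, 2L)
  fracv <- numeric(total); iterv <- integer(total); groupv <- character(total)
  row <- 0L
  groupIdx <- split(seq_along(groupLabels), groupLabels)
  for (f in feasible) {
    size <- floor(f * minN)
    for (it in seq_len(nIter)) {
      for (g in groups) {
        idx <- sample(groupIdx[[g]], size)
        co <- olsLine(agesMonths[idx], globalScores[idx])
        row <- row + 1L
        coefs[row, ] <- co[c("m", "b")]
        fracv[row] <- f; iterv[row] <- it; groupv[row] <- g
      }
    }
  }
  draws <- data.frame(fraction = fracv, iter = iterv, group = groupv,
                      m = coefs[, 1], b = coefs[, 2])
  agg <- aggregate(cbind(m, b) ~ fraction + group, draws,
                   function(v) c(mean = mean(v), sd = sd(v)))
  summaryTab <- data.frame(
    fraction = agg$fraction, group = agg$group,
    mMean = agg$m[, "mean"], mSd = agg$m[, "sd"],
    bMean = agg$b[, "mean"], bSd = agg$b[, "sd"])
  contrasts <- NULL
  if (length(groups) > 1L) {
    contrasts <- do.call(rbind, lapply(unique(draws$fraction), function(f) {
      d <- draws[draws$fraction == f, ]
      data.frame(
        fraction = f,
        pSlope = kruskal.test(d$m, factor(d$group))$p.value,
        pIntercept = kruskal.test(d$b, factor(d$group))$p.value)
    }))
  }
  list(draws = draws, summary = summaryTab, contrasts = contrasts)
}
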