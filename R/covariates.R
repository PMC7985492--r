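# Domestic/educational predictors: conditional probabilities, group
# comparisons, and the multivariable linear regression (MLRM) with
# permutation surrogates.

schoolLevels <- c("none", "public", "private")
householdLevels <- c("mother_only", "mother_stepfather", "both_parents")

#' Build the six-predictor table
#'
#' Extracts the predictors Pr1-Pr6 from child metadata with ordinal coding
#' for the categorical ones: school none=0, public=1, private=2 (Pr1);
#' household mother_only=0, mother_stepfather=1, both_parents=2 (Pr2);
#' parent ages (Pr3, Pr4) and years of schooling (Pr5, Pr6) as given.
#' Children with any missing predictor are dropped with a message.
#'
#' @param x A [ScoreExperiment-class] with demographic `colData`, or a
#'   data.frame with the demographic columns.
#' @return A data.frame with columns Pr1-Pr6 and rownames = child ids;
#'   attribute `"codingScheme"` documents the ordinal coding.
#' @export
predictorTable <- function(x) {
  cd <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x)) else
    as.data.frame(x)
  need <- c("school", "household", "father_age", "mother_age",
            "father_edu", "mother_edu")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) stop("missing demographic columns: ",
                         paste(miss, collapse = ", "))
  X <- data.frame(
    Pr1 = as.numeric(factor(as.character(cd$school), schoolLevels)) - 1,
    Pr2 = as.numeric(factor(as.character(cd$household), householdLevels)) - 1,
    Pr3 = as.numeric(cd$father_age),
    Pr4 = as.numeric(cd$mother_age),
    Pr5 = as.numeric(cd$father_edu),
    Pr6 = as.numeric(cd$mother_edu),
    row.names = if (!is.null(cd$child_id)) as.character(cd$child_id) else NULL)
  keep <- complete.cases(X)
  if (any(!keep)) {
    message(sum(!keep), " children with missing predictors excluded")
    X <- X[keep, , drop = FALSE]
  }
  attr(X, "codingScheme") <- c(
    Pr1 = "school: none=0, public=1, private=2",
    Pr2 = "household: mother_only=0, mother_stepfather=1, both_parents=2",
    Pr3 = "father age (years)", Pr4 = "mother age (years)",
    Pr5 = "father schooling (years)", Pr6 = "mother schooling (years)")
  X
}

#' Cluster-conditional category probabilities
#'
#' P(category | cluster) for school or household, with the cross-cluster
#' prevalence ratio per category (cluster 2 relative to cluster 1 for
#' two-cluster models). Zero denominators give an infinite ratio with a
#' flag rather than an error.
#'
#' @param x A [ScoreExperiment-class] or data.frame of demographics.
#' @param labels Cluster label per child.
#' @param variable `"school"` or `"household"`.
#' @return List with `probs` (clusters x categories, rows sum to 1),
#'   `ratio` (per-category P(.|C2)/P(.|C1)) and `degenerate` (logical per
#'   category, `TRUE` where the ratio involved a zero cell).
#' @export
conditionalProbabilities <- function(x, labels, variable = c("school",
                                                             "household")) {
  variable <- match.arg(variable)
  cd <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x)) else
    as.data.frame(x)
  lev <- if (variable == "school") schoolLevels else householdLevels
  v <- factor(as.character(cd[[variable]]), levels = lev)
  ks <- sort(unique(labels))
  if (any(!tabulate(factor(labels, ks)))) stop("empty cluster")
  counts <- table(cluster = labels, category = v)
  if (any(rowSums(counts) == 0)) stop("empty cluster")
  probs <- sweep(counts, 1, rowSums(counts), "/")
  ratio <- degenerate <- NULL
  if (length(ks) == 2L) {
    p1 <- probs[1, ]; p2 <- probs[2, ]
    ratio <- ifelse(p1 > 0, p2 / p1, ifelse(p2 > 0, Inf, NaN))
    names(ratio) <- lev
    degenerate <- p1 == 0 | p2 == 0
  }
  list(probs = unclass(probs), ratio = ratio, degenerate = degenerate)
}

#' Parent covariates across groups
#'
#' Omnibus comparison (Kruskal-Wallis by default, or one-way ANOVA) of
#' parent ages and educational levels across a grouping (school type or
#' cluster), with Bonferroni-corrected pairwise Wilcoxon follow-ups.
#' Groups with fewer than 2 members are excluded with a message.
#'
#' @param x A [ScoreExperiment-class] or data.frame of demographics.
#' @param grouping Group label per child, or the name of a demographic
#'   column (e.g. `"school"`).
#' @param method `"kruskal"` or `"anova"`.
#' @return Named list (father_age, mother_age, father_edu, mother_edu) of
#'   lists with `omnibus` ([StatTestResult-class]) and `pairwise`
#'   (Bonferroni-corrected p-value matrix).
#' @export
parentGroupComparisons <- function(x, grouping = "school",
                                   method = c("kruskal", "anova")) {
  method <- match.arg(method)
  cd <- if (is(x, "SummarizedExperiment")) as.data.frame(colData(x)) else
    as.data.frame(x)
  g <- if (length(grouping) == 1L && is.character(grouping)) {
    cd[[grouping]]
  } else grouping
  g <- factor(as.character(g))
  small <- names(which(table(g) < 2L))
  if (length(small)) {
    message("groups excluded (n < 2): ", paste(small, collapse = ", "))
    keep <- !g %in% small
    cd <- cd[keep, , drop = FALSE]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("at least 2 groups with n >= 2 are required")
  vars <- c("father_age", "mother_age", "father_edu", "mother_edu")
  out <- lapply(vars, function(v) {
    y <- as.numeric(cd[[v]])
    omnibus <- if (method == "kruskal") {
      kt <- kruskal.test(y, g)
      StatTestResult(kt$statistic, kt$p.value, "kruskal_wallis")
    } else {
      a <- anova(aov(y ~ g))
      StatTestResult(a[["F value"]][1], a[["Pr(>F)"]][1], "anova_oneway")
    }
    pw <- suppressWarnings(
      pairwise.wilcox.test(y, g, p.adjust.method = "bonferroni",
                           exact = FALSE))$p.value
    list(omnibus = omnibus, pairwise = pw)
  })
  names(out) <- vars
  out
}

# Standardize the predictor matrix: z-score the continuous Pr3-Pr6, keep
# the ordinal Pr1/Pr2 as coded. Returns the design matrix (no intercept).
standardizePredictors <- function(X) {
  X <- as.matrix(X)
  cont <- intersect(colnames(X), c("Pr3", "Pr4", "Pr5", "Pr6"))
  for (v in cont) {
    s <- sd(X[, v])
    if (s > 0) X[, v] <- (X[, v] - mean(X[, v])) / s
  }
  X
}

#' Fit the multivariable linear regression model
#'
#' Least-squares fit of an outcome (per-child global score, or the cluster
#' label coded 0/1) on the six standardized predictors, intercept included.
#' Continuous predictors are z-scored; ordinal ones enter as coded. A
#' rank-deficient design raises an error naming the collinear columns.
#'
#' @param X Predictor data.frame from [predictorTable()].
#' @param y Outcome: numeric global scores, or cluster labels (coerced to
#'   0/1 for two-level inputs).
#' @return Named coefficient vector (`(Intercept)`, Pr1-Pr6).
#' @export
mlrmFit <- function(X, y) {
  Xs <- standardizePredictors(X)
  if (is.factor(y) || (length(unique(y)) == 2L && !is.numeric(y)) ||
      (is.numeric(y) && length(unique(y)) == 2L && all(y %in% c(1, 2)))) {
    y <- as.numeric(factor(y)) - 1
  }
  y <- as.numeric(y)
  if (length(y) != nrow(Xs)) stop("outcome length must match predictor rows")
  design <- cbind(`(Intercept)` = 1, Xs)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  co <- qr.coef(qrd, y)
  names(co) <- colnames(design)
  co
}

#' Permutation significance of the MLRM coefficients
#'
#' Contrasts each observed coefficient against surrogate fits in which the
#' predictor rows are permuted jointly: the permutation preserves the
#' inter-predictor correlation structure exactly while breaking the link
#' between predictors and outcome. Two-sided empirical p-value per
#' coefficient: `(1 + #{|beta_surr| >= |beta_obs|}) / (1 + nSurrogates)`.
#'
#' @param X Predictor data.frame from [predictorTable()].
#' @param y Outcome as in [mlrmFit()].
#' @param nSurrogates Number of surrogate fits (default 1000).
#' @param seed Seed for the permutation stream.
#' @return A [MlrmResult-class].
#' @export
mlrmPermutationSignificance <- function(X, y, nSurrogates = 1000L,
                                        seed = 1L) {
  if (nSurrogates < 1L) stop("nSurrogates must be >= 1")
  obs <- mlrmFit(X, y)
  coefNames <- setdiff(names(obs), "(Intercept)")
  absObs <- abs(obs[coefNames])
  Xs <- standardizePredictors(X)
  if (is.factor(y) || (is.numeric(y) && length(unique(y)) == 2L &&
                       all(y %in% c(1, 2)))) {
    y <- as.numeric(factor(y)) - 1
  }
  y <- as.numeric(y)
  n <- nrow(Xs)
  count <- setNames(integer(length(coefNames)), coefNames)
  set.seed(deriveSeed(seed, "mlrm-surrogates"))
  for (s in seq_len(nSurrogates)) {
    perm <- sample.int(n)
    design <- cbind(1, Xs[perm, , drop = FALSE])
    co <- qr.coef(qr(design), y)[-1]
    count <- count + (abs(co) >= absObs)
  }
  new("MlrmResult",
      coefficients = obs,
      empiricalP = empiricalP(count, nSurrogates),
      nSurrogates = as.integer(nSurrogates),
      outcome = if (all(y %in% c(0, 1))) "cluster_label" else "global_score",
      n = as.integer(n))
}
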