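#' ScoreExperiment: normalized battery scores with child metadata
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one assay `"scores"`: a tests x children matrix of normalized scores in
#' \[0, 1\] (missing allowed). `rowData` is the battery metadata (see
#' [defaultBattery()]); `colData` carries one row per child (age, sex,
#' nationality, school, household, parent covariates and - for synthetic
#' cohorts - the planted latent labels).
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("ScoreExperiment", contains = "SummarizedExperiment")

setValidity("ScoreExperiment", function(object) {
  if (!"scores" %in% assayNames(object)) {
    return("assay 'scores' is required")
  }
  m <- assay(object, "scores")
  if (any(!is.na(m) & (m < 0 | m > 1))) {
    return("all non-missing scores must lie in [0, 1]")
  }
  rd <- rowData(object)
  if (!all(c("test_id", "fn", "max_raw") %in% colnames(rd))) {
    return("rowData must carry battery metadata (test_id, fn, max_raw)")
  }
  TRUE
})

#' Construct a ScoreExperiment from a normalized score matrix
#'
#' @param scores Children x tests matrix of normalized scores in \[0, 1\]
#'   (missing values allowed). Columns must align with `battery` rows.
#' @param colData Data frame / DataFrame of per-child metadata (one row per
#'   child). Must contain `age_months` for age-binned analyses.
#' @param battery Battery metadata; defaults to [defaultBattery()].
#' @return A [ScoreExperiment-class] object.
#' @examples
#' m <- matrix(runif(5 * 52), nrow = 5)
#' se <- ScoreExperiment(m, data.frame(age_months = c(30, 40, 50, 60, 70)))
#' dim(se)
#' @export
ScoreExperiment <- function(scores, colData, battery = defaultBattery()) {
  checkBattery(battery)
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (ncol(m) != nrow(battery)) {
    stop("score matrix must have one column per battery test (",
         nrow(battery), ")")
  }
  cd <- as(colData, "DataFrame")
  if (is.null(rownames(m))) {
    rownames(m) <- if (!is.null(cd$child_id)) as.character(cd$child_id) else
      sprintf("child%04d", seq_len(nrow(m)))
  }
  a <- t(m)
  rownames(a) <- sprintf("t%02d", battery$test_id)
  new("ScoreExperiment", SummarizedExperiment(
    assays = list(scores = a), rowData = battery, colData = cd
  ))
}

#' @describeIn ScoreExperiment Battery metadata stored in `rowData`.
#' @param x A `ScoreExperiment`.
#' @export
battery <- function(x) rowData(x)

#' @describeIn ScoreExperiment The children x tests normalized score matrix.
#' @export
scoreMatrix <- function(x) t(assay(x, "scores"))

#' @describeIn ScoreExperiment Ages in completed months, one per child.
#' @export
ages <- function(x) colData(x)$age_months

setMethod("show", "ScoreExperiment", function(object) {
  m <- assay(object, "scores")
  cat("ScoreExperiment:", ncol(object), "children x", nrow(object),
      "tests\n")
  cat("  missing scores:", sum(is.na(m)), " incomplete children:",
      sum(!complete.cases(t(m))), "\n")
  if (!is.null(colData(object)$age_months)) {
    cat("  age range (months):",
        paste(range(colData(object)$age_months), collapse = "-"), "\n")
  }
  if (!is.null(colData(object)$true_cluster)) {
    cat("  synthetic cohort with planted labels\n")
  }
})

#' CorrMatrix: pairwise test correlations with surrogate significance
#'
#' @slot r Symmetric tests x tests Pearson correlation matrix (unit
#'   diagonal; entries for zero-variance tests are `NA`).
#' @slot pValues Empirical two-sided permutation p-values per pair (empty
#'   until [surrogateSignificance()] is run).
#' @slot sigMask Logical matrix, `TRUE` where `pValues < alpha`.
#' @slot nSurrogates Number of surrogates used (0 if none).
#' @slot alpha Significance level for the mask.
#' @slot nChildren Number of complete-case children used.
#' @export
setClass("CorrMatrix", representation(
  r = "matrix", pValues = "matrix", sigMask = "matrix",
  nSurrogates = "integer", alpha = "numeric", nChildren = "integer"
))

setValidity("CorrMatrix", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("r must be square")
  if (!isTRUE(all.equal(unname(r), unname(t(r)), tolerance = 1e-10,
                        check.attributes = FALSE))) {
    return("r must be symmetric")
  }
  if (any(abs(r[!is.na(r)]) > 1 + 1e-8)) return("correlations must lie in [-1, 1]")
  if (any(!is.na(diag(r)) & abs(diag(r) - 1) > 1e-8)) {
    return("diagonal of r must be 1")
  }
  TRUE
})

setMethod("show", "CorrMatrix", function(object) {
  cat("CorrMatrix: ", nrow(object@r), " tests, n = ", object@nChildren,
      " children\n", sep = "")
  cat("  mean off-diagonal r:", round(meanOffDiag(object@r), 3), "\n")
  if (object@nSurrogates > 0L) {
    cat("  surrogates:", object@nSurrogates, " alpha:", object@alpha,
        " significant pairs:",
        sum(object@sigMask[upper.tri(object@sigMask)]), "\n")
  }
})

#' ClusterModel: k-means solution with CH/DB selection traces
#'
#' @slot k Selected number of clusters (argmax of Calinski-Harabasz).
#' @slot kDb Davies-Bouldin argmin, reported alongside.
#' @slot disagreement `TRUE` when the two criteria disagree on k.
#' @slot labels Integer cluster label per child (1 = lowest-scoring
#'   cluster; relabelled by ascending centroid mean).
#' @slot centroids k x tests matrix of cluster centroids.
#' @slot chByK,dbByK Criterion traces over the candidate k values.
#' @slot subLabels Nested labels such as `"1.1"` after [subcluster()]
#'   (empty otherwise).
#' @slot subModels Per-cluster nested `ClusterModel`s from [subcluster()].
#' @slot seed,nRestarts Reproducibility parameters.
#' @export
setClass("ClusterModel", representation(
  k = "integer", kDb = "integer", disagreement = "logical",
  labels = "integer", centroids = "matrix",
  chByK = "numeric", dbByK = "numeric",
  subLabels = "character", subModels = "list",
  seed = "integer", nRestarts = "integer"
))

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k =", object@k, "(CH)")
  if (length(object@kDb)) cat(", DB argmin =", object@kDb)
  if (isTRUE(object@disagreement)) cat(" [criteria disagree]")
  cat("\n  cluster sizes:", paste(tabulate(object@labels, object@k),
                                  collapse = "/"), "\n")
  if (length(object@subLabels)) {
    cat("  sub-clusters:",
        paste(names(table(object@subLabels)), collapse = ", "), "\n")
  }
})

#' CentralityResult: betweenness centrality of the test network
#'
#' @slot bcByGroup age-groups x tests matrix of unnormalized betweenness
#'   values from the thresholded per-age-group correlation networks.
#' @slot summedBc Per-test betweenness summed over age groups.
#' @slot threshold Correlation cutoff that defined the binary graphs.
#' @slot percentiles Percentile cutoffs defining the nested feature groups.
#' @slot percentileGroups Named list mapping percentile to the test ids at
#'   or above that summed-BC quantile (nested: higher cutoff is a subset).
#' @slot topTests,bottomTests Ten tests with highest / lowest summed BC.
#' @export
setClass("CentralityResult", representation(
  bcByGroup = "matrix", summedBc = "numeric", threshold = "numeric",
  percentiles = "numeric", percentileGroups = "list",
  topTests = "integer", bottomTests = "integer"
))

setValidity("CentralityResult", function(object) {
  if (any(object@bcByGroup < 0)) return("betweenness values must be >= 0")
  if (!isTRUE(all.equal(unname(object@summedBc),
                        unname(colSums(object@bcByGroup))))) {
    return("summedBc must equal the column sums of bcByGroup")
  }
  TRUE
})

setMethod("show", "CentralityResult", function(object) {
  cat("CentralityResult:", ncol(object@bcByGroup), "tests x",
      nrow(object@bcByGroup), "age groups (threshold",
      object@threshold, ")\n")
  cat("  top summed-BC tests:", paste(head(object@topTests, 5),
                                      collapse = ", "), "...\n")
})

#' StatTestResult: a single hypothesis-test outcome
#'
#' Lightweight container for delegated statistical tests (rank-sum,
#' Kruskal-Wallis, ANOVA) so pipeline stages report a uniform shape.
#'
#' @slot statistic Test statistic value.
#' @slot pValue p-value in \[0, 1\].
#' @slot testName Name of the procedure used.
#' @slot tails `"one"` or `"two"`.
#' @slot correction `"none"` or `"bonferroni"`.
#' @export
setClass("StatTestResult", representation(
  statistic = "numeric", pValue = "numeric", testName = "character",
  tails = "character", correction = "character"
))

StatTestResult <- function(statistic, pValue, testName,
                           tails = "two", correction = "none") {
  new("StatTestResult", statistic = unname(as.numeric(statistic)),
      pValue = unname(as.numeric(pValue)), testName = testName,
      tails = tails, correction = correction)
}

setValidity("StatTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("pValue must be in [0,1]")
  TRUE
})

setMethod("show", "StatTestResult", function(object) {
  cat(object@testName, " (", object@tails, "-tailed, correction: ",
      object@correction, "): statistic = ", signif(object@statistic, 4),
      ", p = ", signif(object@pValue, 4), "\n", sep = "")
})

#' MlrmResult: multivariable regression with permutation significance
#'
#' @slot coefficients Named coefficients (intercept + Pr1-Pr6) on the
#'   standardized predictor scale.
#' @slot empiricalP Two-sided permutation p-value per predictor
#'   coefficient, each in \[1/(nSurrogates+1), 1\].
#' @slot nSurrogates Number of row-permuted surrogate fits.
#' @slot outcome `"global_score"` or `"cluster_label"`.
#' @slot n Number of children fitted.
#' @export
setClass("MlrmResult", representation(
  coefficients = "numeric", empiricalP = "numeric",
  nSurrogates = "integer", outcome = "character", n = "integer"
))

setMethod("show", "MlrmResult", function(object) {
  cat("MlrmResult (outcome:", object@outcome, ", n =", object@n, ",",
      object@nSurrogates, "surrogates)\n")
  tab <- data.frame(coef = signif(object@coefficients[-1], 3),
                    p = signif(object@empiricalP, 3))
  print(tab)
})
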