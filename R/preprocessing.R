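# Preprocessing: normalization, age binning, complete-case filtering and the
# pooled-sex gate.

#' Normalize raw battery scores to the 0-1 scale
#'
#' Divides each test's raw scores by the maximum attainable raw score from
#' the battery metadata (not by an observed min-max, so the scale is stable
#' across cohorts). Missing values propagate. Applying it to an already
#' normalized matrix with `max_raw = 1` is the identity.
#'
#' @param raw Children x tests matrix of raw scores (`>= 0`; integers or
#'   already-normalized values).
#' @param battery Battery metadata providing `max_raw`; default
#'   [defaultBattery()].
#' @param colData Optional per-child metadata for the returned object.
#' @return A [ScoreExperiment-class] with scores in \[0, 1\].
#' @examples
#' bat <- defaultBattery()
#' raw <- matrix(5, nrow = 2, ncol = 52)
#' se <- normalizeScores(raw, bat, data.frame(age_months = c(30, 40)))
#' scoreMatrix(se)[1, 1]  # 5 / max_raw of test 1
#' @export
normalizeScores <- function(raw, battery = defaultBattery(), colData = NULL) {
  checkBattery(battery)
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (ncol(m) != nrow(battery)) {
    stop("raw matrix must have one column per battery test (",
         nrow(battery), ")")
  }
  if (any(m < 0, na.rm = TRUE)) stop("raw scores must be >= 0")
  maxRaw <- as.numeric(battery$max_raw)
  over <- which(sweep(m, 2, maxRaw, ">"), arr.ind = TRUE)
  if (nrow(over)) {
    i <- over[1, 1]; j <- over[1, 2]
    child <- if (!is.null(rownames(m))) rownames(m)[i] else paste("row", i)
    stop("raw score exceeds max_raw for child '", child, "', test ",
         battery$test_id[j], " (", battery$name[j], "): ", m[i, j], " > ",
         maxRaw[j])
  }
  norm <- sweep(m, 2, maxRaw, "/")
  if (is.null(colData)) {
    colData <- DataFrame(child_id = rownames(norm) %||%
                           sprintf("child%04d", seq_len(nrow(norm))))
  }
  ScoreExperiment(norm, colData, battery)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bin ages into the seven 6-month groups
#'
#' Maps ages in completed months to groups 1-7 covering 30-35, 36-41,
#' 42-47, 48-53, 54-59, 60-65 and 66-71 months:
#' `g = floor((age - 30) / 6) + 1`.
#'
#' @param agesMonths Integer ages in months, all within \[30, 71\].
#' @return Integer group labels 1-7.
#' @examples
#' binAgeGroups(c(30, 35, 36, 71))
#' @export
binAgeGroups <- function(agesMonths) {
  if (any(is.na(agesMonths)) ||
      any(agesMonths < 30 | agesMonths > 71)) {
    bad <- which(is.na(agesMonths) | agesMonths < 30 | agesMonths > 71)[1]
    stop("age out of the study range [30, 71] months at position ", bad,
         " (value ", agesMonths[bad], ")")
  }
  as.integer(floor((agesMonths - 30) / 6) + 1)
}

#' Age-group label per child of a ScoreExperiment
#'
#' @param x A [ScoreExperiment-class] with `age_months` in `colData`.
#' @return Integer vector of group labels 1-7.
#' @export
ageGroups <- function(x) {
  a <- colData(x)$age_months
  if (is.null(a)) stop("colData lacks 'age_months'")
  binAgeGroups(a)
}

#' Keep only completely scored children
#'
#' Complete-case filter: children missing any of the 52 scores are dropped
#' (the pipeline never imputes). The number of discarded children is stored
#' in `metadata()$nDiscarded` and also available via [nDiscarded()].
#'
#' @param x A [ScoreExperiment-class].
#' @return The filtered `ScoreExperiment`.
#' @examples
#' se <- generateCohort(defaultCohortConfig(seed = 1))
#' cc <- filterComplete(se)
#' nDiscarded(cc)  # 32 with the study-replica defaults
#' @export
filterComplete <- function(x) {
  keep <- complete.cases(t(assay(x, "scores")))
  out <- x[, keep]
  if (!any(keep)) warning("all children have partial scores; result is empty")
  metadata(out)$nDiscarded <- sum(!keep)
  out
}

#' @describeIn filterComplete Number of children discarded by the last
#'   `filterComplete()` call (0 for unfiltered objects).
#' @export
nDiscarded <- function(x) metadata(x)$nDiscarded %||% 0L

#' Two-tailed rank-sum check for sex differences
#'
#' Compares the per-child averaged scores of girls and boys with a
#' two-tailed Wilcoxon rank-sum test. The pipeline pools the sexes when
#' `p >= 0.05`; pooling is a logged decision gate, not an automatic branch.
#'
#' @param x A [ScoreExperiment-class] with `sex` in `colData`, or a
#'   children x tests matrix (then supply `sex`).
#' @param sex Optional factor with two levels; taken from `colData` when
#'   missing.
#' @return A [StatTestResult-class].
#' @export
sexDifferenceTest <- function(x, sex = NULL) {
  m <- asChildMatrix(x, allowNA = TRUE)
  if (is.null(sex)) sex <- colData(x)$sex
  sex <- droplevels(factor(sex))
  if (nlevels(sex) != 2L || any(tabulate(sex) == 0L)) {
    stop("exactly two non-empty sex groups are required")
  }
  avg <- rowMeans(m, na.rm = TRUE)
  wt <- suppressWarnings(
    wilcox.test(avg[sex == levels(sex)[1]], avg[sex == levels(sex)[2]],
                alternative = "two.sided", exact = FALSE, correct = TRUE))
  StatTestResult(wt$statistic, wt$p.value, "wilcoxon_rank_sum", tails = "two")
}
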