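# Cohort CSV dialect: header row, UTF-8, '.' decimal separator, empty
# string for missing scores; columns child_id, age_months, sex, nationality,
# school, household, father_age, mother_age, father_edu, mother_edu,
# t01...t52. Latent truth goes to a separate sidecar CSV.

cohortDemoCols <- c("child_id", "age_months", "sex", "nationality",
                    "school", "household", "father_age", "mother_age",
                    "father_edu", "mother_edu")

#' Write a cohort to CSV
#'
#' Writes the documented cohort dialect. For synthetic cohorts the planted
#' labels are written to a sidecar file (`truthPath`), never into the main
#' table, so analysis stages cannot see them by accident.
#'
#' @param x A [ScoreExperiment-class].
#' @param path Output CSV path.
#' @param truthPath Optional sidecar CSV path for planted labels.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(x, path, truthPath = NULL) {
  cd <- as.data.frame(colData(x))
  m <- scoreMatrix(x)
  colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
  demo <- cd[, intersect(cohortDemoCols, colnames(cd)), drop = FALSE]
  out <- cbind(demo, as.data.frame(m))
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  if (!is.null(truthPath) && !is.null(cd$true_cluster)) {
    truth <- cd[, c("child_id", "true_cluster", "true_subcluster")]
    write.csv(truth, truthPath, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a cohort CSV
#'
#' Parses the cohort dialect with schema validation: missing required
#' columns raise a schema error listing them; out-of-range ages name the
#' offending row; an empty file is an explicit error. Scores are returned
#' raw (possibly already normalized) for [normalizeScores()] to handle.
#'
#' @param path CSV path.
#' @return List with `children` (DataFrame of demographics) and `scores`
#'   (children x 52 numeric matrix, `NA` for empty cells).
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA"))
  if (nrow(df) == 0L) stop("empty cohort: ", path, " contains no children")
  scoreCols <- grep("^t[0-9]{2}$", colnames(df), value = TRUE)
  missing <- setdiff(c("child_id", "age_months"), colnames(df))
  if (length(missing) || length(scoreCols) == 0L) {
    stop("cohort schema error; missing required columns: ",
         paste(c(missing, if (!length(scoreCols)) "t01...t52"),
               collapse = ", "))
  }
  bad <- which(is.na(df$age_months) | df$age_months < 30 |
                 df$age_months > 71)
  if (length(bad)) {
    stop("age out of range [30, 71] at row ", bad[1],
         " (child ", df$child_id[bad[1]], ", age ",
         df$age_months[bad[1]], ")")
  }
  demo <- df[, intersect(cohortDemoCols, colnames(df)), drop = FALSE]
  scores <- as.matrix(df[, scoreCols, drop = FALSE])
  storage.mode(scores) <- "double"
  rownames(scores) <- as.character(df$child_id)
  list(children = DataFrame(demo), scores = scores)
}

#' Pipeline configuration
#'
#' One structured object drives [runAll()]: either a path to a cohort CSV
#' or a simulate block ([CohortConfig-class]), per-stage toggles and
#' parameters, a root seed and an output directory. Round-trips losslessly
#' through YAML via [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param simulate A `CohortConfig` to generate the cohort, or `NULL` when
#'   reading from `input`.
#' @param input Path to a cohort CSV (ignored when `simulate` is given).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param threshold Correlation cutoff for the network stage.
#' @param nSurrogates Surrogates for correlation and MLRM significance.
#' @param kRange Candidate cluster numbers.
#' @param fractions Subsample fractions for trajectory regressions.
#' @param nIter Subsample iterations.
#' @param nNeighbors KNN neighbour count.
#' @param percentiles Summed-BC percentile cutoffs.
#' @param seed Root seed (every stage derives its own stream from it).
#' @param outDir Output directory, or `NULL` for in-memory results only.
#' @return A list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(simulate = defaultCohortConfig(),
                           input = NULL,
                           stages = c("preprocess", "correlate", "cluster",
                                      "trajectories", "network",
                                      "classify", "covariates"),
                           threshold = 0.5, nSurrogates = 1000L,
                           kRange = 2:10,
                           fractions = seq(0.2, 0.9, by = 0.1),
                           nIter = 1000L, nNeighbors = 20L,
                           percentiles = c(0, 20, 40, 60, 80),
                           seed = 1L, outDir = NULL) {
  structure(list(
    simulate = simulate, input = input, stages = stages,
    threshold = threshold, nSurrogates = as.integer(nSurrogates),
    kRange = as.integer(kRange), fractions = fractions,
    nIter = as.integer(nIter), nNeighbors = as.integer(nNeighbors),
    percentiles = percentiles, seed = as.integer(seed), outDir = outDir
  ), class = "PipelineConfig")
}

#' @describeIn pipelineConfig Serialize a configuration to YAML.
#' @param config A `PipelineConfig`.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  lst <- unclass(config)
  if (is(lst$simulate, "CohortConfig")) {
    cc <- lst$simulate
    lst$simulate <- list(
      nChildren = cc@nChildren, ageGroupSizes = cc@ageGroupSizes,
      clusterShares = cc@clusterShares,
      clusterIntercepts = cc@clusterIntercepts,
      clusterSlopes = cc@clusterSlopes, clusterMeans = cc@clusterMeans,
      subclusterShares = cc@subclusterShares,
      subclusterOffsets = cc@subclusterOffsets,
      domainLoading = cc@domainLoading, noiseSd = cc@noiseSd,
      latentSd = cc@latentSd, loadingRange = cc@loadingRange,
      nationalityProbs = cc@nationalityProbs,
      schoolProbs = as.vector(cc@schoolProbs),
      householdProbs = as.vector(cc@householdProbs),
      parentAgeMeans = as.vector(cc@parentAgeMeans),
      parentEduMeans = as.vector(cc@parentEduMeans),
      parentAgeSd = cc@parentAgeSd, parentEduSd = cc@parentEduSd,
      nPartial = cc@nPartial, seed = cc@seed)
  }
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' @describeIn pipelineConfig Read a configuration back from YAML.
#' @export
readPipelineConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$simulate)) {
    s <- lst$simulate
    C <- length(s$clusterShares)
    lst$simulate <- cohortConfig(
      nChildren = s$nChildren, ageGroupSizes = s$ageGroupSizes,
      clusterShares = s$clusterShares,
      clusterIntercepts = s$clusterIntercepts,
      clusterSlopes = s$clusterSlopes,
      clusterMeans = as.numeric(unlist(s$clusterMeans)),
      subclusterShares = lapply(s$subclusterShares, as.numeric),
      subclusterOffsets = lapply(s$subclusterOffsets, as.numeric),
      domainLoading = s$domainLoading, noiseSd = s$noiseSd,
      latentSd = s$latentSd, loadingRange = s$loadingRange,
      nationalityProbs = s$nationalityProbs,
      schoolProbs = matrix(s$schoolProbs, nrow = C,
                           dimnames = list(NULL, schoolLevels)),
      householdProbs = matrix(s$householdProbs, nrow = C,
                              dimnames = list(NULL, householdLevels)),
      parentAgeMeans = matrix(s$parentAgeMeans, nrow = C,
                              dimnames = list(NULL, c("father", "mother"))),
      parentEduMeans = matrix(s$parentEduMeans, nrow = C,
                              dimnames = list(NULL, c("father", "mother"))),
      parentAgeSd = s$parentAgeSd, parentEduSd = s$parentEduSd,
      nPartial = s$nPartial, seed = s$seed)
  }
  do.call(pipelineConfig, lst[setdiff(names(lst), character(0))])
}
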