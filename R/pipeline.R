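# The run-all orchestrator: preprocessing -> correlation/surrogates ->
# clustering/sub-clustering -> trajectories -> network/BC ->
# classification -> covariates, with per-stage logging, CSV outputs and a
# JSON manifest.

#' Run the full analysis pipeline
#'
#' Executes every enabled stage on a simulated or loaded cohort, in the
#' order the analyses build on each other. Each stage derives its seed from
#' the root seed, so identical configurations give identical bundles. When
#' a stage fails, the bundle is marked partial and dependent stages are
#' skipped with a recorded reason. With `outDir` set, stage tables are
#' written as CSV plus a JSON manifest (versions, seeds, parameters,
#' per-stage child counts).
#'
#' @param config A [pipelineConfig()] object.
#' @return A list (class `"PipelineBundle"`) with one entry per executed
#'   stage, `manifest`, and `partial` flag.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simulate = defaultCohortConfig(seed = 1),
#'                       nSurrogates = 100, nIter = 100)
#' bundle <- runAll(cfg)
#' names(bundle)
#' }
#' @export
runAll <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- Sys.time()
  log <- list()
  results <- list()
  partial <- FALSE
  note <- function(stage, msg) {
    log[[stage]] <<- c(log[[stage]], msg)
    message("[", stage, "] ", msg)
  }

  # --- cohort ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- generateCohort(config$simulate)
    note("cohort", paste("simulated", ncol(cohort), "children"))
  } else {
    raw <- readCohort(config$input)
    cohort <- normalizeScores(raw$scores, defaultBattery(), raw$children)
    note("cohort", paste("read", ncol(cohort), "children from",
                         config$input))
  }
  results$cohort <- cohort

  # --- preprocess --------------------------------------------------------
  sex <- if (!is.null(colData(cohort)$sex)) {
    sexDifferenceTest(cohort)
  } else NULL
  complete <- filterComplete(cohort)
  note("preprocess", paste(nDiscarded(complete),
                           "partially scored children discarded;",
                           ncol(complete), "complete cases"))
  if (!is.null(sex)) {
    note("preprocess", paste0("sex difference p = ",
                              signif(sex@pValue, 3),
                              if (sex@pValue >= 0.05) "; sexes pooled" else
                                "; pooling decision left to the analyst"))
  }
  results$preprocess <- list(complete = complete, nDiscarded =
                               nDiscarded(complete), sexTest = sex)
  m <- scoreMatrix(complete)
  grp <- ageGroups(complete)
  gs <- globalScore(complete)

  run <- function(stage, expr) {
    if (!stage %in% config$stages) {
      note(stage, "disabled by configuration; skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) {
      note(stage, paste("FAILED:", conditionMessage(e)))
      partial <<- TRUE
      NULL
    })
    if (!is.null(res)) results[[stage]] <<- res
    invisible(res)
  }

  # --- correlate ---------------------------------------------------------
  run("correlate", {
    cm <- surrogateSignificance(m, nSurrogates = config$nSurrogates,
                                seed = deriveSeed(config$seed, "correlate"))
    ordering <- sortBySummedCorrelation(cm)
    trend <- ageGroupCorrelationTrend(m, grp)
    list(corr = cm, ordering = ordering,
         fnContrast = functionCorrelationContrast(cm),
         trend = trend,
         derivative = correlationDerivative(trend$means))
  })

  # --- cluster -----------------------------------------------------------
  model <- run("cluster", {
    mod <- selectK(m, kRange = config$kRange,
                   seed = deriveSeed(config$seed, "cluster") %% 100000L)
    mod <- subcluster(m, mod, kRange = config$kRange,
                      seed = deriveSeed(config$seed, "subcluster") %% 100000L)
    mod
  })
  if (!is.null(model) && "cluster" %in% config$stages) {
    ordering <- if (!is.null(results$correlate)) {
      results$correlate$ordering
    } else NULL
    results$cluster <- list(
      model = model,
      profiles = clusterProfiles(m, model@labels, ordering = ordering),
      centroidByAge = centroidDistanceByAge(m, model@labels, grp))
    note("cluster", paste("k =", model@k, "clusters; sizes",
                          paste(tabulate(model@labels), collapse = "/")))
  }

  # --- trajectories ------------------------------------------------------
  run("trajectories", {
    labels <- if (!is.null(model)) model@labels else rep(1L, ncol(complete))
    fit <- fitTrajectory(gs, ages(complete), labels,
                         nBoot = min(config$nIter, 1000L),
                         seed = deriveSeed(config$seed, "traj") %% 100000L)
    byNat <- if (!is.null(colData(complete)$nationality)) {
      subsampleRegressions(gs, ages(complete),
                           as.character(colData(complete)$nationality),
                           fractions = config$fractions,
                           nIter = config$nIter,
                           seed = deriveSeed(config$seed, "subs") %% 100000L)
    } else NULL
    list(byCluster = fit, byNationality = byNat)
  })

  # --- network -----------------------------------------------------------
  centrality <- run("network", {
    bcg <- bcByAgeGroup(m, grp, threshold = config$threshold)
    summedBcAndGroups(bcg, percentiles = config$percentiles,
                      threshold = config$threshold)
  })

  # --- classify ----------------------------------------------------------
  run("classify", {
    if (is.null(model)) stop("clustering unavailable; cannot classify")
    if (is.null(centrality)) stop("network unavailable; cannot classify")
    loss <- knnCvLoss(m, model@labels,
                      kValues = c(1, 5, 10, 20, 40),
                      seed = deriveSeed(config$seed, "knn") %% 100000L)
    reports2 <- bcSubsetPerformance(m, model@labels, centrality,
                                    nNeighbors = config$nNeighbors,
                                    seed = deriveSeed(config$seed, "bc2") %%
                                      100000L)
    reports4 <- if (length(model@subLabels)) {
      bcSubsetPerformance(m, model@subLabels, centrality,
                          nNeighbors = config$nNeighbors,
                          seed = deriveSeed(config$seed, "bc4") %% 100000L)
    } else NULL
    list(cvLossByK = loss, optimalK = selectNeighbors(loss),
         twoClass = reports2, fourClass = reports4)
  })

  # --- covariates --------------------------------------------------------
  run("covariates", {
    if (is.null(model)) stop("clustering unavailable; cannot relate covariates")
    X <- predictorTable(complete)
    keep <- rownames(X)
    idx <- match(keep, colData(complete)$child_id)
    list(
      school = conditionalProbabilities(complete, model@labels, "school"),
      household = conditionalProbabilities(complete, model@labels,
                                           "household"),
      parentBySchool = parentGroupComparisons(complete, "school"),
      mlrmScore = mlrmPermutationSignificance(
        X, gs[idx], nSurrogates = config$nSurrogates,
        seed = deriveSeed(config$seed, "mlrm-score")),
      mlrmCluster = mlrmPermutationSignificance(
        X, model@labels[idx] - 1L, nSurrogates = config$nSurrogates,
        seed = deriveSeed(config$seed, "mlrm-cluster")))
  })

  manifest <- list(
    package = "npclust",
    version = as.character(utils::packageVersion("npclust")),
    rVersion = R.version.string,
    seed = config$seed,
    parameters = config[c("threshold", "nSurrogates", "kRange",
                          "fractions", "nIter", "nNeighbors",
                          "percentiles")],
    nChildren = ncol(cohort),
    nComplete = ncol(complete),
    stages = config$stages,
    log = log,
    partial = partial,
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  results$manifest <- manifest
  results$partial <- partial

  if (!is.null(config$outDir)) writeBundle(results, config$outDir)
  class(results) <- "PipelineBundle"
  results
}

# Write the bundle's tables as CSV plus a JSON manifest.
writeBundle <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(outDir, name)
  writeCohort(results$cohort, out("cohort.csv"),
              truthPath = if (!is.null(colData(results$cohort)$true_cluster))
                out("cohort_truth.csv"))
  if (!is.null(results$correlate)) {
    write.csv(results$correlate$corr@r, out("correlation_matrix.csv"))
    write.csv(results$correlate$corr@pValues, out("correlation_pvalues.csv"))
    write.csv(data.frame(group = names(results$correlate$trend$means),
                         meanCorrelation = results$correlate$trend$means),
              out("correlation_trend.csv"), row.names = FALSE)
  }
  if (!is.null(results$cluster)) {
    model <- results$cluster$model
    write.csv(data.frame(child_id = names(model@labels),
                         cluster = model@labels,
                         subcluster = if (length(model@subLabels))
                           model@subLabels else NA),
              out("cluster_labels.csv"), row.names = FALSE)
    write.csv(model@centroids, out("cluster_centroids.csv"))
    write.csv(data.frame(k = as.integer(sub("k", "", names(model@chByK))),
                         ch = model@chByK, db = model@dbByK),
              out("cluster_criteria.csv"), row.names = FALSE)
    write.csv(results$cluster$profiles$profiles, out("cluster_profiles.csv"),
              row.names = FALSE)
  }
  if (!is.null(results$trajectories)) {
    write.csv(results$trajectories$byCluster$fits, out("trajectory_fits.csv"),
              row.names = FALSE)
    if (!is.null(results$trajectories$byNationality)) {
      write.csv(results$trajectories$byNationality$summary,
                out("subsample_regressions.csv"), row.names = FALSE)
    }
  }
  if (!is.null(results$network)) {
    write.csv(results$network@bcByGroup, out("bc_by_group.csv"))
    write.csv(data.frame(test_id = seq_along(results$network@summedBc),
                         summed_bc = results$network@summedBc),
              out("summed_bc.csv"), row.names = FALSE)
  }
  if (!is.null(results$classify)) {
    write.csv(attr(results$classify$twoClass, "summary"),
              out("classifier_two_class.csv"), row.names = FALSE)
    if (!is.null(results$classify$fourClass)) {
      write.csv(attr(results$classify$fourClass, "summary"),
                out("classifier_four_class.csv"), row.names = FALSE)
    }
  }
  if (!is.null(results$covariates)) {
    write.csv(results$covariates$school$probs, out("school_probs.csv"))
    write.csv(data.frame(
      predictor = names(results$covariates$mlrmCluster@empiricalP),
      coefficient = results$covariates$mlrmCluster@coefficients[-1],
      empirical_p = results$covariates$mlrmCluster@empiricalP),
      out("mlrm_cluster.csv"), row.names = FALSE)
  }
  jsonlite::write_json(results$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(outDir)
}
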