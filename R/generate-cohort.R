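# Synthetic cohort generation.
#
# Generative model, per child i with age a_i (months) in latent cluster c
# and sub-cluster s:
#   g_i      = b_c + m_c * a_i + delta_{c,s} + N(0, latentSd)
#   score_ij = clip01( loading_j * g_i + lambda(group_i) * f_{i, fn(j)}
#                      + N(0, noiseSd) )
# with one shared factor f per neuropsychological function per child and a
# loading lambda that grows linearly over age groups, so within-battery
# correlations strengthen with age. Demographics are drawn from
# cluster-conditional distributions.

# Discrete marginal of ages implied by the age-group sizes (uniform within
# each 6-month group). Returns data.frame(age, w).
ageMarginal <- function(config) {
  data.frame(age = 30:71,
             w = rep(config@ageGroupSizes / 6, each = 6) / config@nChildren)
}

# Calibrate a logistic membership rule P(C1 | age) = plogis((a0 - age)/s)
# so that, under the configured age marginal, the cluster-1 share equals
# clusterShares[1] and the cluster-1 mean age equals the value implied by
# the planted trajectory and target mean score:
#   E[age | C1] = (clusterMeans[1] - b1) / m1.
# Two-cluster configs only. Returns the membership function of age.
calibrateMembership <- function(config) {
  if (length(config@clusterShares) != 2L) {
    stop("age-dependent membership (clusterMeans) supports exactly 2 clusters")
  }
  targetShare <- config@clusterShares[1]
  targetAge <- (config@clusterMeans[1] - config@clusterIntercepts[1]) /
    config@clusterSlopes[1]
  if (targetAge < 30 || targetAge > 71) {
    stop("planted cluster means and trajectories imply a cluster-1 mean age ",
         "outside the study range (", round(targetAge, 1), " months)")
  }
  marg <- ageMarginal(config)
  moments <- function(par) {
    p <- plogis((par[1] - marg$age) / exp(par[2]))
    share <- sum(marg$w * p)
    c(share = share, meanAge = sum(marg$w * marg$age * p) / share)
  }
  obj <- function(par) {
    m <- moments(par)
    (m["share"] - targetShare)^2 + ((m["meanAge"] - targetAge) / 41)^2
  }
  fit <- optim(c(45, log(5)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  m <- moments(fit$par)
  if (abs(m["share"] - targetShare) > 1e-3 ||
      abs(m["meanAge"] - targetAge) > 0.25) {
    stop("could not calibrate age-dependent cluster membership to the ",
         "requested share and cluster means")
  }
  a0 <- fit$par[1]; s <- exp(fit$par[2])
  function(age) plogis((a0 - age) / s)
}

# Mean of clip01(N(mu, sd)): truncation at the score bounds shifts the
# mean of bounded scores toward the interior.
clipMean <- function(mu, sd) {
  a <- (0 - mu) / sd
  b <- (1 - mu) / sd
  (1 - pnorm(b)) + mu * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a))
}

# Invert clipMean in mu (vectorized damped Newton): find the pre-clip
# location whose clipped mean equals the target, so planted trajectories
# are realized on the bounded score scale without floor/ceiling bias.
# Targets are capped to an attainable band near the bounds.
invertClipMean <- function(target, sd, lower = 0.005, upper = 0.995) {
  t <- pmin(pmax(target, lower), upper)
  mu <- t
  for (i in seq_len(40L)) {
    grad <- pmax(pnorm((1 - mu) / sd) - pnorm((0 - mu) / sd), 0.05)
    mu <- mu + (t - clipMean(mu, sd)) / grad
  }
  mu
}

# Fixed per-test loadings on the global level: evenly spaced over
# loadingRange (mean exactly 1 for symmetric ranges), scrambled across test
# ids by a fixed bijection so loadings do not align with function blocks.
testLoadings <- function(config, nTests = 52L) {
  vals <- seq(config@loadingRange[1], config@loadingRange[2],
              length.out = nTests)
  ord <- order((seq_len(nTests) * 19L) %% 53L)
  vals[order(ord)]
}

#' Generate a synthetic cohort
#'
#' Draws a full cohort (scores + demographics) from the generative model in
#' a [CohortConfig-class]. With the study-replica defaults
#' ([defaultCohortConfig()]) the output has 643 children in seven age
#' groups, two latent performance clusters split into two sub-clusters
#' each, correlations that strengthen with age, cluster-conditional
#' demographics, and exactly `nPartial` partially scored children.
#' Identical seeds give identical cohorts.
#'
#' When `clusterMeans` is set (the default), cluster membership is drawn
#' from a logistic function of age calibrated so the planted trajectories,
#' cluster shares and cluster mean scores are mutually consistent; the
#' latent labels are stored in `colData` columns `true_cluster` /
#' `true_subcluster` and are never used by the analysis stages.
#'
#' @param config A [CohortConfig-class]; default [defaultCohortConfig()].
#' @return A [ScoreExperiment-class] with demographics and planted labels
#'   in `colData` and the configuration in `metadata()$config`.
#' @examples
#' se <- generateCohort(defaultCohortConfig(seed = 1))
#' dim(se)
#' table(colData(se)$true_cluster)
#' @export
generateCohort <- function(config = defaultCohortConfig()) {
  validObject(config)
  n <- config@nChildren
  C <- length(config@clusterShares)
  battery <- defaultBattery()
  nTests <- nrow(battery)

  # ages: uniform integers within each 6-month group
  set.seed(deriveSeed(config@seed, "ages"))
  age <- unlist(lapply(seq_len(7L), function(g) {
    lo <- 30L + 6L * (g - 1L)
    sample(lo:(lo + 5L), config@ageGroupSizes[g], replace = TRUE)
  }))
  ageGroup <- binAgeGroups(age)

  # latent cluster / sub-cluster membership
  set.seed(deriveSeed(config@seed, "clusters"))
  if (length(config@clusterMeans) && C == 2L) {
    p1 <- calibrateMembership(config)(age)
    cluster <- ifelse(runif(n) < p1, 1L, 2L)
  } else {
    cluster <- sample.int(C, n, replace = TRUE, prob = config@clusterShares)
  }
  subcluster <- rep(1L, n)
  for (cc in seq_len(C)) {
    shares <- config@subclusterShares[[cc]]
    if (length(shares) > 1L) {
      idx <- which(cluster == cc)
      subcluster[idx] <- sample.int(length(shares), length(idx),
                                    replace = TRUE, prob = shares)
    }
  }

  # latent global level and scores
  set.seed(deriveSeed(config@seed, "scores"))
  offsets <- vapply(seq_len(n), function(i) {
    off <- config@subclusterOffsets[[cluster[i]]]
    if (length(off)) off[subcluster[i]] else 0
  }, numeric(1))
  g <- config@clusterIntercepts[cluster] + config@clusterSlopes[cluster] * age +
    offsets + rnorm(n, 0, config@latentSd)
  lambda <- config@domainLoading[1] +
    config@domainLoading[2] * (ageGroup - 1L)
  fns <- as.integer(battery$fn)
  factors <- matrix(rnorm(n * 5L), nrow = n, ncol = 5L)
  loadings <- testLoadings(config, nTests)
  # Per child x test target mean. The per-test perturbation has constant
  # total variance noiseSd^2, split between the shared per-function factor
  # (variance lambda(age)^2, shared within a function) and an idiosyncratic
  # remainder: correlations within a function strengthen with age while the
  # per-test noise level stays flat, as in the emulated design. The combined
  # perturbation is Gaussian with sd noiseSd, so the pre-clip location is
  # corrected for truncation at the score bounds and the planted means are
  # realized exactly on the bounded scale.
  mu <- outer(g, loadings)
  if (config@noiseSd > 0) {
    idioSd <- sqrt(pmax(config@noiseSd^2 - lambda^2, 0))
    noise <- lambda * factors[, fns, drop = FALSE] +
      idioSd * matrix(rnorm(n * nTests), nrow = n)
    scores <- invertClipMean(mu, config@noiseSd) + noise
  } else {
    scores <- mu + lambda * factors[, fns, drop = FALSE]
  }
  scores <- clip01(scores)
  colnames(scores) <- sprintf("t%02d", battery$test_id)

  # demographics
  set.seed(deriveSeed(config@seed, "demographics"))
  sex <- factor(ifelse(runif(n) < 315 / 643, "M", "F"), levels = c("F", "M"))
  nationality <- factor(
    sample(c("MX", "CO", "GT"), n, replace = TRUE,
           prob = config@nationalityProbs),
    levels = c("MX", "CO", "GT"))
  drawCat <- function(probMatrix) {
    lev <- colnames(probMatrix)
    out <- character(n)
    for (cc in seq_len(C)) {
      idx <- which(cluster == cc)
      out[idx] <- sample(lev, length(idx), replace = TRUE,
                         prob = probMatrix[cc, ])
    }
    factor(out, levels = lev)
  }
  school <- drawCat(config@schoolProbs)
  household <- drawCat(config@householdProbs)
  fatherAge <- round(rnorm(n, config@parentAgeMeans[cluster, "father"],
                           config@parentAgeSd[1]), 1)
  motherAge <- round(rnorm(n, config@parentAgeMeans[cluster, "mother"],
                           config@parentAgeSd[2]), 1)
  fatherAge <- pmax(fatherAge, 18)
  motherAge <- pmax(motherAge, 16)
  fatherEdu <- pmin(pmax(round(rnorm(
    n, config@parentEduMeans[cluster, "father"], config@parentEduSd[1])), 0), 22)
  motherEdu <- pmin(pmax(round(rnorm(
    n, config@parentEduMeans[cluster, "mother"], config@parentEduSd[2])), 0), 22)

  # partial records: nPartial children each lose 1-10 scores at random
  set.seed(deriveSeed(config@seed, "missing"))
  if (config@nPartial > 0L) {
    partial <- sample.int(n, config@nPartial)
    for (i in partial) {
      scores[i, sample.int(nTests, sample.int(10L, 1L))] <- NA_real_
    }
  }

  cd <- DataFrame(
    child_id = sprintf("ch%04d", seq_len(n)),
    age_months = age, age_group = ageGroup, sex = sex,
    nationality = nationality, school = school, household = household,
    father_age = fatherAge, mother_age = motherAge,
    father_edu = fatherEdu, mother_edu = motherEdu,
    true_cluster = cluster, true_subcluster = subcluster
  )
  se <- ScoreExperiment(scores, cd, battery)
  metadata(se)$config <- config
  se
}

#' Planted ground truth of a synthetic cohort
#'
#' Returns the latent labels and trajectory parameters that
#' [generateCohort()] planted, for comparison against pipeline estimates.
#' Errors when called on a cohort that this package did not generate.
#'
#' @param x A [ScoreExperiment-class] produced by [generateCohort()].
#' @return A list with `labels` (DataFrame: child_id, true_cluster,
#'   true_subcluster), `intercepts`, `slopes`, `clusterMeans`,
#'   `subclusterMeans` (per-cluster planted sub-cluster mean scores) and
#'   `shares`.
#' @export
plantedTruth <- function(x) {
  cd <- colData(x)
  config <- metadata(x)$config
  if (is.null(config) || !all(c("true_cluster", "true_subcluster") %in%
                              colnames(cd))) {
    stop("plantedTruth() requires a cohort produced by generateCohort(); ",
         "this object carries no planted labels")
  }
  subMeans <- lapply(seq_along(config@clusterShares), function(cc) {
    off <- config@subclusterOffsets[[cc]]
    if (!length(off)) return(numeric(0))
    base <- if (length(config@clusterMeans)) config@clusterMeans[cc] else
      config@clusterIntercepts[cc] +
        config@clusterSlopes[cc] * sum(ageMarginal(config)$age *
                                       ageMarginal(config)$w)
    base + off
  })
  list(
    labels = DataFrame(child_id = cd$child_id,
                       true_cluster = cd$true_cluster,
                       true_subcluster = cd$true_subcluster),
    intercepts = config@clusterIntercepts,
    slopes = config@clusterSlopes,
    clusterMeans = config@clusterMeans,
    subclusterMeans = subMeans,
    shares = config@clusterShares
  )
}
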