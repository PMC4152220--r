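# Synthetic cohorts with the statistical structure of the derivation study:
# ~1629 adult trauma patients across three hospitals, ~6% 24-hour mortality,
# skewed vital-sign marginals with a GCS ceiling at 15, nonlinear (spline)
# SBP/HR and linear GCS associations with mortality log-odds, ~2% early live
# discharges, and hospital-stratified MAR missingness.

.default_sbp_anchors <- list(
  probs = c(0.001, 0.01, 0.05, 0.25, 0.35, 0.50, 0.65, 0.75, 0.95, 0.99,
            0.999),
  values = c(50, 66, 80, 108, 110, 117, 122, 126, 149, 172, 210))
.default_hr_anchors <- list(
  probs = c(0.001, 0.01, 0.05, 0.25, 0.35, 0.50, 0.65, 0.75, 0.95, 0.99,
            0.999),
  values = c(30, 52, 70, 80, 85, 88, 92, 98, 119, 138, 180))
# GCS probability mass on 3..15: ceiling at 15, secondary mass at 3.
.default_gcs_weights <- c(0.06, 0.03, 0.025, 0.025, 0.025, 0.025, 0.03,
                          0.035, 0.04, 0.045, 0.05, 0.06, 0.55)

.default_truth <- c(sbp_basis1 = -0.02, sbp_basis2 = -0.04, sbp_basis3 = 0.38,
                    hr_basis1 = 0.00, hr_basis2 = -0.02, hr_basis3 = 0.22,
                    gcs = -0.23)

#' Specification of a synthetic trauma cohort
#'
#' Bundles every generator parameter: cohort size, hospital mix, marginal
#' vital-sign distributions (quantile anchors mapped through a Gaussian
#' copula), the true outcome model (restricted cubic spline terms for SBP
#' and HR at fixed knots, a linear GCS term), the target 24-hour mortality,
#' the early-live-discharge rate, and the missingness profile
#' (per-variable marginal rates plus per-hospital incomplete-case targets,
#' missing at random given hospital, outcome and age).
#'
#' Defaults reproduce the derivation study's structure: n = 1629, mortality
#' 6\%, early discharges 2\%, missingness 20\% SBP / 18\% HR / 20\% GCS /
#' 6\% time-to-arrival, per-hospital incomplete-case proportions spanning
#' 1--51\%, and true coefficients equal to the published before-shrinkage
#' estimates on the published knots.
#'
#' @param n Cohort size.
#' @param hospital_weights Named proportions per hospital (sum to 1).
#' @param true_coefficients Named vector of generator-side coefficients on
#'   the spline/linear design (`sbp_basis1..3`, `hr_basis1..3`, `gcs`).
#' @param sbp_knots,hr_knots Knot locations defining the truth's spline
#'   bases (also used by [truth_of()]).
#' @param target_mortality Marginal probability of death within 24 h; the
#'   intercept is calibrated by bisection to hit it.
#' @param early_discharge_rate Proportion of the cohort discharged alive
#'   before 24 h (drawn among survivors, independent of vitals).
#' @param missingness List with `rates` (named per-variable marginal
#'   missingness proportions), `incomplete_by_hospital` (per-hospital
#'   incomplete-case proportions, recycled to the hospitals; `NULL` for
#'   homogeneous missingness), `beta_outcome` and `beta_age` (log-odds
#'   shifts making missingness depend on outcome and age — MAR).
#' @param correlations Named list of latent Gaussian copula correlations
#'   `sbp_hr`, `sbp_gcs`, `hr_gcs`.
#' @param seed Integer seed stored in the spec; `generate_cohort()` uses it
#'   unless overridden.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1629,
                        hospital_weights = c(A = 0.20, B = 0.35, C = 0.45),
                        true_coefficients = .default_truth,
                        sbp_knots = c(80, 110, 121, 147),
                        hr_knots = c(70, 86, 92, 118),
                        target_mortality = 0.06,
                        early_discharge_rate = 0.02,
                        missingness = list(
                          rates = c(sbp = 0.20, hr = 0.18, gcs = 0.20,
                                    tti_hours = 0.06),
                          incomplete_by_hospital = c(0.01, 0.30, 0.51),
                          beta_outcome = 0.6, beta_age = 0.2),
                        correlations = list(sbp_hr = -0.15, sbp_gcs = 0.30,
                                            hr_gcs = -0.10),
                        seed = 1L) {
  stopifnot(n >= 1, abs(sum(hospital_weights) - 1) < 1e-8,
            all(hospital_weights >= 0),
            target_mortality > 0, target_mortality < 1,
            early_discharge_rate >= 0, early_discharge_rate < 1)
  if (any(missingness$rates < 0) || any(missingness$rates > 1)) {
    stop("missingness rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n = as.integer(n), hospital_weights = hospital_weights,
                 true_coefficients = true_coefficients,
                 sbp_knots = sbp_knots, hr_knots = hr_knots,
                 target_mortality = target_mortality,
                 early_discharge_rate = early_discharge_rate,
                 missingness = missingness, correlations = correlations,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec: n =", x$n,
      sprintf("| mortality %.1f%% | %d hospitals | seed %d\n",
              100 * x$target_mortality, length(x$hospital_weights), x$seed))
  invisible(x)
}

#' Serialise / restore a cohort spec (JSON)
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns the restored `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  # keep names of atomic vectors by writing them as JSON objects
  x$hospital_weights <- as.list(x$hospital_weights)
  x$true_coefficients <- as.list(x$true_coefficients)
  x$missingness$rates <- as.list(x$missingness$rates)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("hospital_weights", "true_coefficients")) {
    x[[f]] <- unlist(x[[f]])
  }
  x$sbp_knots <- as.numeric(unlist(x$sbp_knots))
  x$hr_knots <- as.numeric(unlist(x$hr_knots))
  x$missingness$rates <- unlist(x$missingness$rates)
  x$missingness$incomplete_by_hospital <-
    unlist(x$missingness$incomplete_by_hospital)
  do.call(cohort_spec, x)
}

#' True generator coefficients
#'
#' Returns the exact coefficient vector used by [generate_cohort()], on the
#' same basis parameterisation the fitting functions use (restricted cubic
#' spline bases at the spec's fixed knots, linear GCS). Serves as the oracle
#' for parameter-recovery tests.
#'
#' @param spec A `cohort_spec`.
#' @return Named numeric vector of length 7.
#' @export
truth_of <- function(spec) {
  spec$true_coefficients
}

# Map latent standard-normal draws to a marginal given by quantile anchors
# (monotone linear interpolation of the quantile function).
.anchor_quantile <- function(u, anchors) {
  stats::approx(anchors$probs, anchors$values, xout = u, rule = 2)$y
}

.discrete_quantile <- function(u, weights, values) {
  values[findInterval(u, cumsum(weights), left.open = TRUE) + 1L]
}

.truth_design <- function(sbp, hr, gcs, spec) {
  cbind(rcs_basis(sbp, knot_set(spec$sbp_knots, "sbp")),
        rcs_basis(hr, knot_set(spec$hr_knots, "hr")),
        gcs = gcs)
}

#' Generate a complete synthetic cohort
#'
#' Draws vital signs from the spec's marginal distributions through a
#' Gaussian copula, descriptive variables from the study marginals, and the
#' 24-hour outcome from a Bernoulli whose logit is the spec's true
#' coefficient vector applied to the spline/linear design. The intercept is
#' found by bisection so that expected mortality equals
#' `spec$target_mortality` (tolerance 0.1 percentage points). Early live
#' discharges are flagged among survivors, independent of vitals.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return A complete `trauma_cohort` (no missing values) with attributes
#'   `true_intercept` and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  set.seed(if (is.null(seed)) spec$seed else seed)
  n <- spec$n
  hw <- spec$hospital_weights
  hospital <- sample(names(hw), n, replace = TRUE, prob = hw)

  rho <- spec$correlations
  R <- matrix(c(1, rho$sbp_hr, rho$sbp_gcs,
                rho$sbp_hr, 1, rho$hr_gcs,
                rho$sbp_gcs, rho$hr_gcs, 1), 3, 3)
  L <- chol(R)
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% L
  u <- stats::pnorm(z)
  sbp <- .anchor_quantile(u[, 1], .default_sbp_anchors)
  hr <- .anchor_quantile(u[, 2], .default_hr_anchors)
  gcs <- .discrete_quantile(u[, 3], .default_gcs_weights, 3:15)

  age <- pmax(15, round(stats::rlnorm(n, log(34), 0.45)))
  sex <- sample(c("male", "female"), n, TRUE, prob = c(0.80, 0.20))
  tti <- stats::rlnorm(n, log(8), 1.7)
  transferred <- stats::runif(n) < 0.68
  mech_w <- c(fall = 0.27, railway = 0.07, road_traffic = 0.46,
              assault = 0.09, burn = 0.06, other = 0.045, unknown = 0.005)
  mechanism <- sample(names(mech_w), n, TRUE, prob = mech_w / sum(mech_w))

  X <- .truth_design(sbp, hr, gcs, spec)
  beta <- spec$true_coefficients
  if (!identical(colnames(X), c(paste0("basis", 1:3), paste0("basis", 1:3), "gcs"))) {
    stop("internal: truth design mismatch")
  }
  eta <- drop(X %*% beta)
  b0 <- .calibrate_intercept(eta, spec$target_mortality)
  p <- stats::plogis(b0 + eta)
  died <- stats::runif(n) < p

  discharged <- rep(FALSE, n)
  if (spec$early_discharge_rate > 0) {
    pr <- min(1, spec$early_discharge_rate / (1 - spec$target_mortality))
    discharged[!died] <- stats::runif(sum(!died)) < pr
  }

  cohort <- as_cohort(data.frame(
    hospital_id = hospital, age = age, sex = sex, tti_hours = tti,
    transferred = transferred, mechanism = mechanism,
    sbp = sbp, hr = hr, gcs = gcs,
    died_24h = died, discharged_early = discharged,
    stringsAsFactors = FALSE), provenance = "synthetic")
  attr(cohort, "true_intercept") <- b0
  attr(cohort, "spec") <- spec
  cohort
}

.calibrate_intercept <- function(eta, target, tol = 1e-3) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -30; hi <- 30
  if (f(lo) > 0 || f(hi) < 0) {
    stop("intercept calibration failed: target mortality unreachable",
         call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < tol * 0.1) break
  }
  (lo + hi) / 2
}

#' Impose MAR missingness on a complete cohort
#'
#' Each patient is first drawn as "incomplete-prone" with a probability
#' set by hospital (to match the per-hospital incomplete-case targets) and
#' tilted on the log-odds scale by the observed outcome and age (missing at
#' random: the probability of missingness depends only on always-observed
#' fields). Given proneness, each variable is independently set missing
#' with a conditional rate calibrated by fixed-point iteration so that the
#' marginal per-variable missing fractions match `spec$missingness$rates`.
#' With `incomplete_by_hospital = NULL` the per-variable rates are applied
#' homogeneously (still MAR-tilted).
#'
#' @param cohort A complete `trauma_cohort`.
#' @param spec The [cohort_spec()] carrying the missingness profile.
#' @param seed Optional seed (defaults to `spec$seed + 1`).
#' @return The cohort with missing values in `sbp`, `hr`, `gcs`,
#'   `tti_hours`.
#' @export
impose_missingness <- function(cohort, spec = attr(cohort, "spec"),
                               seed = NULL) {
  set.seed(if (is.null(seed)) spec$seed + 1L else seed)
  ms <- spec$missingness
  rates <- ms$rates
  if (any(rates > 1)) stop("missingness rate > 1", call. = FALSE)
  if (all(rates == 0)) return(cohort)
  vars <- names(rates)
  n <- nrow(cohort)
  y <- primary_outcome(cohort)
  age_z <- as.numeric(scale(cohort$age))
  hosp <- as.character(cohort$hospital_id)
  hosp_levels <- names(spec$hospital_weights)

  if (is.null(ms$incomplete_by_hospital)) {
    for (v in vars) {
      lp <- stats::qlogis(pmin(pmax(rates[[v]], 1e-12), 1 - 1e-12)) +
        ms$beta_outcome * (y - mean(y)) + ms$beta_age * age_z
      miss <- stats::runif(n) < stats::plogis(lp)
      if (rates[[v]] >= 1) miss <- rep(TRUE, n)
      cohort[[v]][miss] <- NA
    }
    return(cohort)
  }

  q_target <- rep_len(ms$incomplete_by_hospital, length(hosp_levels))
  names(q_target) <- hosp_levels
  w <- spec$hospital_weights[hosp_levels]
  # Fixed point: conditional per-variable rates c_v given proneness, and
  # prone probabilities q_h, such that marginal rates and per-hospital
  # incomplete-case proportions both hit their targets.
  p_any <- 1
  for (i in 1:50) {
    q_h <- pmin(q_target / p_any, 1)
    cv <- pmin(rates / sum(w * q_h), 0.999)
    p_any_new <- 1 - prod(1 - cv)
    if (abs(p_any_new - p_any) < 1e-10) break
    p_any <- p_any_new
  }
  lp <- stats::qlogis(pmin(pmax(q_h[hosp], 1e-12), 1 - 1e-12)) +
    ms$beta_outcome * (y - mean(y)) + ms$beta_age * age_z
  prone <- stats::runif(n) < stats::plogis(lp)
  for (v in vars) {
    miss <- prone & (stats::runif(n) < cv[[v]])
    if (rates[[v]] >= 1) miss <- rep(TRUE, n)
    cohort[[v]][miss] <- NA
  }
  cohort
}
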