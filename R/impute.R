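# Hospital-stratified multiple imputation by chained equations.
# Continuous vitals use predictive mean matching (or Bayesian linear
# regression), GCS an ordinal logistic model (proportional odds) with a
# PMM fallback, categorical variables a multinomial model. The outcome is
# always part of every imputation model. Each hospital is imputed
# separately; the completed per-hospital sets are concatenated.

#' Number of imputed datasets from the incomplete-case rule
#'
#' Computes, per hospital, the proportion of patients with at least one
#' missing value in the modelled variables, and returns the ceiling of the
#' largest proportion expressed as a percentage (so 51\% incomplete cases
#' in the worst hospital gives m = 51). A complete cohort returns 0; any
#' missingness returns at least 2.
#'
#' @param cohort A `trauma_cohort`.
#' @param modelled_variables Columns inspected for missingness.
#' @return Integer m; attribute `by_hospital` carries the per-hospital
#'   incomplete-case proportions.
#' @export
choose_m <- function(cohort,
                     modelled_variables = c("sbp", "hr", "gcs", "tti_hours",
                                            "age", "sex", "transferred",
                                            "mechanism")) {
  modelled_variables <- intersect(modelled_variables, names(cohort))
  incomplete <- rowSums(is.na(cohort[, modelled_variables, drop = FALSE])) > 0
  props <- tapply(incomplete, cohort$hospital_id, mean)
  m <- if (!any(incomplete)) 0L else max(2L, as.integer(ceiling(100 * max(props))))
  structure(m, by_hospital = props)
}

#' Multiple imputation by chained equations, stratified by hospital
#'
#' Runs `n_iter` chained-equations cycles independently within each
#' hospital stratum and repeats the whole procedure `m` times from fresh
#' random starts, giving `m` completed datasets in which the observed cells
#' are untouched. Default per-variable methods: predictive mean matching
#' (donor pool 5, with Bayesian parameter draws) for `sbp`, `hr` and
#' `tti_hours`; ordinal logistic regression for `gcs` (falling back to PMM
#' rounded and clipped to [3, 15] if the proportional-odds fit fails);
#' multinomial logistic regression for categorical variables. The 24-hour
#' outcome enters every conditional model as a predictor. Hospital strata
#' with fewer than 20 rows or a constant outcome fall back to pooled
#' (all-hospital) imputation models with a warning.
#'
#' @param cohort A `trauma_cohort` with missing values.
#' @param m Number of imputations; `"auto"` applies [choose_m()].
#' @param n_iter Chained-equations cycles per imputation.
#' @param methods Named per-variable methods, `"pmm"` or `"norm"` for
#'   continuous variables (`gcs` and categoricals choose their own model).
#' @param outcome_in_model Include the outcome as an imputation predictor
#'   (recommended and default).
#' @param outcome Which outcome recoding drives the imputation models:
#'   `"primary"` or `"worst_case"`.
#' @param seed Master seed; per-hospital, per-imputation substreams are
#'   derived from it deterministically.
#' @return An `imputed_stack`: list with `m`, `datasets` (list of complete
#'   `trauma_cohort`s), `outcome` and `rule_trace`.
#' @export
impute_cohort <- function(cohort, m = "auto", n_iter = 10,
                          methods = c(sbp = "pmm", hr = "pmm",
                                      tti_hours = "pmm"),
                          outcome_in_model = TRUE,
                          outcome = c("primary", "worst_case"),
                          seed = 1L) {
  outcome <- match.arg(outcome)
  auto <- choose_m(cohort)
  if (identical(m, "auto")) m <- as.integer(auto)
  m <- as.integer(m)
  imp_vars <- names(which(vapply(cohort[c("sbp", "hr", "gcs", "tti_hours",
                                          "sex", "transferred", "mechanism",
                                          "age")],
                                 anyNA, logical(1))))
  if (length(imp_vars) == 0 || m == 0L) {
    m_eff <- max(m, 1L)
    return(.new_stack(rep(list(cohort), m_eff), m_eff, outcome, auto))
  }
  if (m < 2L) stop("m must be >= 2 when values are missing", call. = FALSE)
  # order by increasing missingness
  imp_vars <- imp_vars[order(vapply(cohort[imp_vars], function(v) sum(is.na(v)),
                                    numeric(1)))]
  y <- if (outcome == "primary") primary_outcome(cohort) else
    worst_case_outcome(cohort)

  hosp <- as.character(cohort$hospital_id)
  strata <- split(seq_len(nrow(cohort)), hosp)
  pooled_fallback <- vapply(strata, function(idx) {
    length(idx) < 20 || length(unique(y[idx])) < 2
  }, logical(1))
  if (any(pooled_fallback)) {
    warning("stratum collapse: pooled imputation models used for hospital(s) ",
            paste(names(strata)[pooled_fallback], collapse = ", "),
            call. = FALSE)
  }

  set.seed(seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1L,
                                (length(strata) + 1L) * m),
                     nrow = length(strata) + 1L)

  datasets <- vector("list", m)
  for (j in seq_len(m)) {
    filled <- cohort
    for (h in seq_along(strata)) {
      idx <- strata[[h]]
      if (pooled_fallback[[h]]) next
      set.seed(seed_tab[h, j])
      filled[idx, ] <- .chained_impute(cohort[idx, , drop = FALSE], y[idx],
                                       imp_vars, methods, n_iter,
                                       outcome_in_model)
    }
    if (any(pooled_fallback)) {
      set.seed(seed_tab[length(strata) + 1L, j])
      pooled_full <- .chained_impute(cohort, y, imp_vars, methods, n_iter,
                                     outcome_in_model)
      for (h in which(pooled_fallback)) {
        idx <- strata[[h]]
        filled[idx, ] <- pooled_full[idx, , drop = FALSE]
      }
    }
    datasets[[j]] <- filled
  }
  .new_stack(datasets, m, outcome, auto)
}

.new_stack <- function(datasets, m, outcome, auto_m) {
  structure(list(m = m, datasets = datasets, outcome = outcome,
                 rule_trace = list(by_hospital = attr(auto_m, "by_hospital"),
                                   auto_m = as.integer(auto_m))),
            class = "imputed_stack")
}

#' Write an imputed stack as one long-format CSV
#'
#' All m completed datasets are stacked with a leading `imputation` index
#' column (1..m); within each imputation the row order of the original
#' cohort is preserved. This long format (rather than m separate files)
#' keeps the stack a single self-describing artifact.
#'
#' @param stack An `imputed_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  long <- do.call(rbind, lapply(seq_len(stack$m), function(j)
    cbind(imputation = j, as.data.frame(stack$datasets[[j]]))))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack: m =", x$m, "completed datasets of",
      nrow(x$datasets[[1]]), "patients (outcome:", x$outcome, ")\n")
  invisible(x)
}

# One chained-equations run on one stratum; returns the completed frame.
.chained_impute <- function(data, y, imp_vars, methods, n_iter,
                            outcome_in_model) {
  miss_idx <- lapply(data[imp_vars], function(v) which(is.na(v)))
  # random-draw initial fill
  for (v in imp_vars) {
    obs <- data[[v]][!is.na(data[[v]])]
    data[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                       replace = TRUE)
  }
  pred_vars <- setdiff(c("age", "sex", "tti_hours", "transferred", "mechanism",
                         "sbp", "hr", "gcs"), character(0))
  warm <- new.env(parent = emptyenv())
  for (iter in seq_len(n_iter)) {
    for (v in imp_vars) {
      mi <- miss_idx[[v]]
      if (length(mi) == 0) next
      rhs <- setdiff(pred_vars, v)
      X <- .imputation_design(data, rhs, if (outcome_in_model) y else NULL)
      data[[v]] <- .impute_one(data[[v]], X, mi, v,
                               method = if (v %in% names(methods))
                                 methods[[v]] else "pmm", warm = warm)
    }
  }
  data
}

# Numeric design matrix with constant columns dropped (intercept kept).
.imputation_design <- function(data, rhs, y) {
  df <- data[, rhs, drop = FALSE]
  df$transferred <- as.numeric(df$transferred)
  X <- stats::model.matrix(~ ., data = df)
  if (!is.null(y)) X <- cbind(X, outcome = as.numeric(y))
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(col) stats::var(col) > 0))
  X[, keep, drop = FALSE]
}

.impute_one <- function(values, X, mi, varname, method, warm = NULL) {
  obs <- setdiff(seq_along(values), mi)
  if (varname == "gcs") {
    filled <- .impute_ordinal(values, X, mi, obs, warm)
    if (!is.null(filled)) return(filled)
    method <- "pmm"   # proportional-odds fit failed
  }
  if (is.factor(values)) return(.impute_nominal(values, X, mi, obs))
  yobs <- values[obs]
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[mi, , drop = FALSE]
  fit <- stats::lm.fit(Xo, yobs)
  ok <- !is.na(fit$coefficients)
  beta_hat <- fit$coefficients[ok]
  Xo <- Xo[, ok, drop = FALSE]
  Xm <- Xm[, ok, drop = FALSE]
  df_res <- max(length(obs) - sum(ok), 1)
  rss <- sum(fit$residuals^2)
  sigma2_star <- rss / stats::rchisq(1, df_res)
  XtX_inv <- chol2inv(chol(crossprod(Xo) + diag(1e-8, ncol(Xo))))
  beta_star <- beta_hat + drop(chol(sigma2_star * XtX_inv +
                                      diag(1e-12, ncol(Xo))) %*%
                                 stats::rnorm(ncol(Xo)))
  if (method == "norm") {
    imp <- drop(Xm %*% beta_star) + stats::rnorm(length(mi),
                                                 sd = sqrt(sigma2_star))
  } else {  # pmm, donor pool 5
    yhat_obs <- drop(Xo %*% beta_hat)
    yhat_mis <- drop(Xm %*% beta_star)
    imp <- .pmm_match(yhat_obs, yhat_mis, yobs, donors = 5L)
  }
  if (varname == "gcs") imp <- pmin(pmax(round(imp), 3), 15)
  if (varname %in% c("sbp", "hr")) imp <- pmax(imp, 1)
  if (varname == "tti_hours") imp <- pmax(imp, 0)
  values[mi] <- imp
  values
}

# Nearest-neighbour matching on sorted predicted values: for each missing
# prediction, the `donors` closest observed predictions form the pool and
# one donor's observed value is drawn.
.pmm_match <- function(yhat_obs, yhat_mis, yobs, donors = 5L) {
  donors <- min(donors, length(yobs))
  o <- order(yhat_obs)
  ys <- yhat_obs[o]; vs <- yobs[o]
  n <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  vapply(seq_along(yhat_mis), function(i) {
    lo <- max(1L, pos[i] - donors); hi <- min(n, pos[i] + donors)
    win <- lo:hi
    d <- win[order(abs(ys[win] - yhat_mis[i]))[seq_len(donors)]]
    vs[d[sample.int(length(d), 1L)]]
  }, numeric(1))
}

.impute_ordinal <- function(values, X, mi, obs, warm = NULL) {
  if (length(unique(values[obs])) < 3) return(NULL)
  df <- data.frame(X[obs, -1, drop = FALSE])
  df$.y <- droplevels(factor(values[obs], levels = 3:15, ordered = TRUE))
  start <- if (!is.null(warm)) warm$polr_start else NULL
  n_par <- (ncol(df) - 1L) + (nlevels(df$.y) - 1L)
  args <- list(.y ~ ., data = df, Hess = FALSE, model = FALSE)
  if (!is.null(start) && length(start) == n_par) args$start <- start
  fit <- tryCatch(
    suppressWarnings(do.call(MASS::polr, args)),
    error = function(e) NULL)
  if (!is.null(fit) && !is.null(warm)) {
    warm$polr_start <- c(fit$coefficients, fit$zeta)
  }
  if (is.null(fit)) return(NULL)
  nd <- data.frame(X[mi, -1, drop = FALSE])
  pr <- tryCatch(suppressWarnings(stats::predict(fit, newdata = nd,
                                                 type = "probs")),
                 error = function(e) NULL)
  if (is.null(pr)) return(NULL)
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = length(mi),
                                     dimnames = list(NULL, levels(df$.y)))
  lev <- as.numeric(colnames(pr))
  values[mi] <- apply(pr, 1, function(p) sample(lev, 1, prob = pmax(p, 0)))
  values
}

.impute_nominal <- function(values, X, mi, obs) {
  df <- data.frame(y = droplevels(factor(values[obs])), X[obs, -1, drop = FALSE])
  fit <- tryCatch(
    nnet::multinom(y ~ ., data = df, trace = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {  # degenerate stratum: draw from observed margin
    values[mi] <- sample(values[obs], length(mi), replace = TRUE)
    return(values)
  }
  nd <- data.frame(X[mi, -1, drop = FALSE])
  pr <- stats::predict(fit, newdata = nd, type = "probs")
  if (is.null(dim(pr))) pr <- cbind(1 - pr, pr)
  lev <- levels(df$y)
  values[mi] <- apply(pr, 1, function(p) sample(lev, 1, prob = pmax(p, 0)))
  values
}
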