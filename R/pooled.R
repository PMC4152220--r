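# Logistic modelling on an imputed stack: per-dataset maximum likelihood,
# Rubin's-rules pooling, grouped (joint) Wald tests, lowess screening of
# functional form, and grouped backward selection at the 0.2 level.

#' Declarative model specification
#'
#' Describes each candidate predictor and its functional form: `"linear"`
#' or `"rcs3"`/`"rcs4"`/`"rcs5"` (restricted cubic spline with that many
#' knots). Extra covariates (for the full-model sensitivity analysis) are
#' always entered untransformed: `age` linear, `sex`, `transferred` and
#' `mechanism` as indicator contrasts.
#'
#' @param ... Named forms, e.g. `model_spec(sbp = "rcs4", hr = "rcs4",
#'   gcs = "linear")`.
#' @param extras Character vector of forced-in covariates from
#'   `c("age", "sex", "transferred", "mechanism")`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(..., extras = character(0)) {
  terms <- c(...)
  if (length(terms) > 0) {
    stopifnot(!is.null(names(terms)), !anyDuplicated(names(terms)),
              all(terms %in% c("linear", "rcs3", "rcs4", "rcs5")))
  }
  stopifnot(all(extras %in% c("age", "sex", "transferred", "mechanism")))
  structure(list(terms = terms, extras = extras), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  if (length(x$terms) == 0) cat("Model spec: intercept only\n")
  else cat("Model spec:", paste(names(x$terms), x$terms, sep = ":",
                                collapse = ", "), "\n")
  if (length(x$extras)) cat("  forced-in:", paste(x$extras, collapse = ", "), "\n")
  invisible(x)
}

.spec_knot_count <- function(form) {
  if (form == "linear") return(0L)
  as.integer(sub("rcs", "", form))
}

# Design matrix (no intercept column) for one complete dataset.
# knots: named list of knot_set per spline variable; when NULL, knots are
# placed from this dataset's values at equally spaced percentiles.
.build_design <- function(data, spec, knots = NULL) {
  blocks <- list()
  used_knots <- list()
  groups <- character(0)
  for (v in names(spec$terms)) {
    form <- spec$terms[[v]]
    if (form == "linear") {
      col <- matrix(as.numeric(data[[v]]), dimnames = list(NULL, v))
      blocks[[v]] <- col
      groups <- c(groups, v)
    } else {
      k <- .spec_knot_count(form)
      ks <- if (!is.null(knots) && !is.null(knots[[v]])) knots[[v]] else
        place_knots(data[[v]], k, variable = v)
      if (length(ks$locations) != k) {
        ks <- place_knots(data[[v]], k, variable = v)
      }
      B <- rcs_basis(data[[v]], ks)
      colnames(B) <- paste0(v, "_", colnames(B))
      blocks[[v]] <- B
      used_knots[[v]] <- ks
      groups <- c(groups, rep(v, ncol(B)))
    }
  }
  for (ev in spec$extras) {
    col <- switch(ev,
      age = matrix(as.numeric(data$age), dimnames = list(NULL, "age")),
      sex = matrix(as.numeric(data$sex == "female"),
                   dimnames = list(NULL, "sex_female")),
      transferred = matrix(as.numeric(data$transferred),
                           dimnames = list(NULL, "transferred")),
      mechanism = {
        lev <- levels(data$mechanism)[-1]
        M <- vapply(lev, function(l) as.numeric(data$mechanism == l),
                    numeric(nrow(data)))
        colnames(M) <- paste0("mechanism_", lev)
        M <- M[, colSums(M) > 0, drop = FALSE]
        M
      })
    blocks[[ev]] <- col
    groups <- c(groups, rep(ev, ncol(col)))
  }
  X <- if (length(blocks)) do.call(cbind, blocks) else
    matrix(numeric(0), nrow(data), 0)
  list(X = X, groups = groups, knots = used_knots)
}

#' Fit a logistic model on an imputed stack with Rubin's-rules pooling
#'
#' Fits a maximum-likelihood logistic regression on each completed dataset
#' (spline knots placed per dataset at equally spaced percentiles, unless
#' frozen via `knots`) and pools across the `m` fits: pooled coefficients
#' are the mean, pooled covariance is \eqn{\bar W + (1 + 1/m) B} with
#' \eqn{\bar W} the mean within-imputation covariance and \eqn{B} the
#' between-imputation covariance of the coefficients. Grouped joint Wald
#' p-values are computed per variable on the pooled fit.
#'
#' @param stack An `imputed_stack` (or a single complete `trauma_cohort`,
#'   treated as a stack with m = 1).
#' @param spec A [model_spec()].
#' @param knots Optional named list of `knot_set`s to freeze knot
#'   locations (e.g. for evaluating a model on new data).
#' @param outcome Outcome recoding; defaults to the stack's.
#' @return A `pooled_fit` object: pooled `coefficients` (with intercept),
#'   `covariance`, per-variable `group_p` and `nonlinear_p`, `knots`
#'   (per-dataset and median), `spec`, `m`.
#' @export
fit_pooled <- function(stack, spec, knots = NULL, outcome = NULL) {
  stack <- .as_stack(stack)
  if (is.null(outcome)) outcome <- stack$outcome
  m <- stack$m
  coefs <- NULL; vcovs <- list(); knots_by_imp <- list(); groups <- NULL
  for (j in seq_len(m)) {
    data <- stack$datasets[[j]]
    y <- if (outcome == "primary") primary_outcome(data) else
      worst_case_outcome(data)
    if (length(unique(y)) < 2) {
      stop("imputation ", j, ": outcome has a single class", call. = FALSE)
    }
    d <- .build_design(data, spec, knots)
    X <- cbind(`(Intercept)` = rep(1, nrow(data)), d$X)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      stop("singular design in imputation ", j, call. = FALSE)
    }
    fit <- suppressWarnings(stats::glm.fit(X, y,
                                           family = stats::binomial()))
    if (!fit$converged || max(abs(fit$coefficients)) > 50) {
      stop("fit failure (separation?) in imputation ", j, call. = FALSE)
    }
    eta <- drop(X %*% fit$coefficients)
    w <- stats::plogis(eta) * (1 - stats::plogis(eta))
    V <- chol2inv(chol(crossprod(X * sqrt(w))))
    dimnames(V) <- list(colnames(X), colnames(X))
    coefs <- cbind(coefs, fit$coefficients)
    vcovs[[j]] <- V
    knots_by_imp[[j]] <- d$knots
    groups <- d$groups
  }
  pooled <- rubin_pool(coefs, vcovs)
  qbar <- pooled$coefficients
  fit <- structure(list(coefficients = qbar, covariance = pooled$covariance,
                        within = pooled$within, between = pooled$between,
                        m = m, spec = spec,
                        groups = c("(Intercept)", groups),
                        knots_by_imp = knots_by_imp,
                        knots = .median_knots(knots_by_imp),
                        n = nrow(stack$datasets[[1]]), outcome = outcome),
                   class = "pooled_fit")
  fit$group_p <- vapply(names(spec$terms), function(v) joint_wald(fit, v),
                        numeric(1))
  fit$nonlinear_p <- vapply(names(spec$terms), function(v) {
    if (spec$terms[[v]] == "linear") NA_real_ else
      joint_wald(fit, v, nonlinear_only = TRUE)
  }, numeric(1))
  fit
}

#' Combine estimates across imputations by Rubin's rules
#'
#' Pooled coefficients are the mean across imputations; the pooled
#' covariance is \eqn{\bar W + (1 + 1/m) B}, where \eqn{\bar W} is the
#' mean within-imputation covariance and \eqn{B} the between-imputation
#' covariance of the coefficient vectors. With m = 1 the pooled quantities
#' collapse to the single fit.
#'
#' @param coefficients p x m matrix, one column per imputation.
#' @param covariances List of m p x p within-imputation covariances.
#' @return List with `coefficients`, `covariance`, `within`, `between`.
#' @export
rubin_pool <- function(coefficients, covariances) {
  coefficients <- as.matrix(coefficients)
  m <- ncol(coefficients)
  stopifnot(length(covariances) == m)
  qbar <- rowMeans(coefficients)
  names(qbar) <- rownames(coefficients)
  Wbar <- Reduce(`+`, covariances) / m
  if (m > 1) {
    B <- stats::cov(t(coefficients))
    Tcov <- Wbar + (1 + 1 / m) * B
  } else {
    B <- 0 * Wbar
    Tcov <- Wbar
  }
  list(coefficients = qbar, covariance = Tcov, within = Wbar, between = B)
}

.as_stack <- function(x) {
  if (inherits(x, "imputed_stack")) return(x)
  if (inherits(x, "trauma_cohort")) {
    if (anyNA(x[c("sbp", "hr", "gcs", "tti_hours")])) {
      stop("cohort has missing values; impute first", call. = FALSE)
    }
    return(.new_stack(list(x), 1L, "primary", 0L))
  }
  stop("expected an imputed_stack or complete trauma_cohort", call. = FALSE)
}

# Median knot locations across imputations, per spline variable.
.median_knots <- function(knots_by_imp) {
  if (length(knots_by_imp) == 0 || length(knots_by_imp[[1]]) == 0) {
    return(list())
  }
  out <- list()
  for (v in names(knots_by_imp[[1]])) {
    locs <- vapply(knots_by_imp, function(k) k[[v]]$locations,
                   numeric(length(knots_by_imp[[1]][[v]]$locations)))
    locs <- if (is.null(dim(locs))) matrix(locs, nrow = 1) else locs
    out[[v]] <- knot_set(apply(locs, 1, stats::median), variable = v,
                         percentiles = knots_by_imp[[1]][[v]]$percentiles)
  }
  out
}

#' Joint Wald test of a variable's coefficient block
#'
#' Tests all coefficients belonging to one variable (every spline basis
#' function, or the single linear term) being simultaneously zero, using
#' the quadratic form \eqn{c' \Sigma^{-1} c} on the pooled fit against a
#' chi-square reference with df equal to the block size. With
#' `nonlinear_only = TRUE` only the basis functions beyond the first
#' (the nonlinear components) are tested.
#'
#' @param fit A `pooled_fit`.
#' @param variable Variable name in the fit's spec.
#' @param nonlinear_only Test only the nonlinear spline components.
#' @return P-value; the statistic and df are attached as attributes.
#' @export
joint_wald <- function(fit, variable, nonlinear_only = FALSE) {
  idx <- which(fit$groups == variable)
  if (length(idx) == 0) stop("variable '", variable, "' not in fit",
                             call. = FALSE)
  if (nonlinear_only) {
    if (length(idx) < 2) stop("'", variable, "' has no nonlinear components",
                              call. = FALSE)
    idx <- idx[-1]
  }
  cc <- fit$coefficients[idx]
  Sig <- fit$covariance[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(Sig), error = function(e)
    stop("singular block covariance for '", variable, "'", call. = FALSE))
  stat <- drop(crossprod(backsolve(ch, cc, transpose = TRUE)))
  p <- stats::pchisq(stat, df = length(idx), lower.tail = FALSE)
  structure(p, statistic = stat, df = length(idx))
}

#' Lowess screening of a vital sign's association with early mortality
#'
#' Smooths the binary outcome against the observed values of one variable
#' with lowess, transforms the smoothed probabilities to the log-odds scale
#' (clipped away from 0 and 1), and summarises departure from linearity as
#' `1 - R^2` of the best straight-line fit to the smoothed log-odds. The
#' index supports, but does not automate, the linear-versus-spline choice.
#'
#' @param cohort A `trauma_cohort`.
#' @param variable Variable name.
#' @param outcome `"primary"` or `"worst_case"`.
#' @param f Lowess smoother span.
#' @param threshold Flag threshold on the linearity index.
#' @return List with `grid`, `prob`, `log_odds`, `linearity_index`,
#'   `flagged`.
#' @export
lowess_screen <- function(cohort, variable, outcome = "primary", f = 2/3,
                          threshold = 0.2) {
  y <- if (outcome == "primary") primary_outcome(cohort) else
    worst_case_outcome(cohort)
  x <- cohort[[variable]]
  ok <- !is.na(x)
  x <- x[ok]; y <- as.numeric(y[ok])
  if (length(x) < 100) stop("fewer than 100 observed pairs", call. = FALSE)
  if (length(unique(x)) < 2) stop("'", variable, "' is constant", call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome is constant", call. = FALSE)
  # iter = 0: robustness iterations would discard the rare events as
  # outliers and flatten the smooth of a binary outcome
  sm <- stats::lowess(x, y, f = f, iter = 0)
  p <- pmin(pmax(sm$y, 1e-4), 1 - 1e-4)
  lo <- stats::qlogis(p)
  line <- stats::lm.fit(cbind(1, sm$x), lo)
  ssr <- sum(line$residuals^2)
  sst <- sum((lo - mean(lo))^2)
  index <- if (sst < 1e-12) 0 else ssr / sst
  list(grid = sm$x, prob = p, log_odds = lo, linearity_index = index,
       flagged = index > threshold)
}

#' Grouped backward selection at the 0.2 level
#'
#' Starting from the full specification, iteratively (a) reduces the knot
#' count of any spline variable whose nonlinear components are jointly
#' non-significant at `alpha` (rcs4 to rcs3 to linear), then (b) removes
#' the variable with the largest grouped joint Wald p-value at or above
#' `alpha`, refitting after each step. Terminates when every remaining
#' grouped p-value is below `alpha`. Ties break towards the largest p,
#' then towards the variable listed later in the spec.
#'
#' @param stack An `imputed_stack` (or complete cohort).
#' @param full_spec The starting [model_spec()].
#' @param alpha Retention level (default 0.2).
#' @param reduce_knots Apply the spline-reduction step (a).
#' @return The selected `model_spec`; attribute `trace` records every step
#'   and attribute `fit` holds the final `pooled_fit`.
#' @export
backward_select <- function(stack, full_spec, alpha = 0.2,
                            reduce_knots = TRUE) {
  stack <- .as_stack(stack)
  spec <- full_spec
  trace <- list()
  repeat {
    if (length(spec$terms) == 0) {
      warning("backward selection removed every variable; intercept-only model",
              call. = FALSE)
      attr(spec, "trace") <- trace
      return(spec)
    }
    fit <- fit_pooled(stack, spec)
    stepped <- FALSE
    if (reduce_knots) {
      nl <- fit$nonlinear_p
      cand <- names(nl)[!is.na(nl) & nl >= alpha]
      if (length(cand) > 0) {
        v <- cand[order(-nl[cand], match(cand, rev(names(spec$terms))))][1]
        old <- spec$terms[[v]]
        spec$terms[[v]] <- switch(old, rcs5 = "rcs4", rcs4 = "rcs3",
                                  rcs3 = "linear")
        trace[[length(trace) + 1]] <- list(action = "reduce", variable = v,
                                           from = old, to = spec$terms[[v]],
                                           p = unname(nl[v]))
        stepped <- TRUE
      }
    }
    if (!stepped) {
      gp <- fit$group_p
      cand <- names(gp)[gp >= alpha]
      if (length(cand) > 0) {
        v <- cand[order(-gp[cand], match(cand, rev(names(spec$terms))))][1]
        trace[[length(trace) + 1]] <- list(action = "remove", variable = v,
                                           p = unname(gp[v]))
        spec$terms <- spec$terms[setdiff(names(spec$terms), v)]
        stepped <- TRUE
      }
    }
    if (!stepped) {
      attr(spec, "trace") <- trace
      attr(spec, "fit") <- fit
      return(spec)
    }
  }
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("Pooled logistic fit (m =", x$m, "imputations, n =", x$n, ")\n")
  print(round(stats::setNames(x$coefficients, names(x$coefficients)), 4))
  if (length(x$group_p)) {
    cat("Grouped Wald p-values:\n")
    print(round(x$group_p, 4))
  }
  invisible(x)
}

#' @export
coef.pooled_fit <- function(object, ...) object$coefficients

#' @export
vcov.pooled_fit <- function(object, ...) object$covariance
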