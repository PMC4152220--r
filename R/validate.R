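# Bootstrap internal validation: the complete modelling procedure
# (separate imputation, grouped backward selection, pooled fit) replicated
# in bootstrap samples drawn with replacement; selection stability,
# AUROCC optimism, and the linear shrinkage factor.

#' Bootstrap replication of the modelling procedure
#'
#' Each replicate resamples patients with replacement from the original
#' (incomplete) cohort, imputes the bootstrap sample afresh with
#' `m_boot` imputations, runs grouped backward selection from `full_spec`,
#' fits the selected model, and evaluates the replicate model's AUROCC in
#' its own stack and in the original stack (median across imputed
#' datasets) together with the calibration slope of its linear predictor
#' in the original stack. Optimism is the mean difference between
#' bootstrap-sample and original-sample AUROCC; the linear shrinkage
#' factor is the mean original-sample calibration slope.
#'
#' @param cohort The original (possibly incomplete) `trauma_cohort`.
#' @param full_spec Starting [model_spec()] for selection.
#' @param B Number of bootstrap replicates (study value 300).
#' @param m_boot Imputations per bootstrap sample (reduced relative to the
#'   original-sample m for tractability).
#' @param seed Master seed.
#' @param orig_stack Imputed stack of the original cohort; imputed here
#'   with `m_boot` imputations when not supplied.
#' @param alpha Selection level.
#' @param n_iter Chained-equations cycles per imputation.
#' @param outcome `"primary"` or `"worst_case"`.
#' @return A `bootstrap_report`: `B`, `per_replicate` data frame
#'   (`auc_boot`, `auc_orig`, `cal_slope`, selected spec), per-variable
#'   `inclusion_frequency`, `optimism`, `shrinkage`, `n_failed`.
#' @export
bootstrap_validate <- function(cohort, full_spec, B = 300, m_boot = 5,
                               seed = 1L, orig_stack = NULL, alpha = 0.2,
                               n_iter = 10, outcome = "primary") {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, B + 1L)
  if (is.null(orig_stack)) {
    orig_stack <- impute_cohort(cohort, m = min(m_boot, max(choose_m(cohort), 1)),
                                n_iter = n_iter, outcome = outcome,
                                seed = seeds[B + 1L])
  }
  y_orig <- lapply(orig_stack$datasets, function(d) {
    if (outcome == "primary") primary_outcome(d) else worst_case_outcome(d)
  })
  n <- nrow(cohort)
  vars <- names(full_spec$terms)
  recs <- vector("list", B)
  for (b in seq_len(B)) {
    recs[[b]] <- tryCatch({
      set.seed(seeds[b])
      idx <- sample.int(n, n, replace = TRUE)
      boot <- cohort[idx, , drop = FALSE]
      class(boot) <- class(cohort)
      stack_b <- impute_cohort(boot, m = m_boot, n_iter = n_iter,
                               outcome = outcome,
                               seed = seeds[b])
      sel <- backward_select(stack_b, full_spec, alpha = alpha)
      fit_b <- if (!is.null(attr(sel, "fit"))) attr(sel, "fit") else
        fit_pooled(stack_b, sel)
      mod_b <- .fit_as_model(fit_b)
      auc_boot <- stats::median(vapply(seq_len(stack_b$m), function(j) {
        d <- stack_b$datasets[[j]]
        yb <- if (outcome == "primary") primary_outcome(d) else
          worst_case_outcome(d)
        auroc(.score(mod_b, d), yb)
      }, numeric(1)))
      eval_orig <- vapply(seq_along(orig_stack$datasets), function(j) {
        d <- orig_stack$datasets[[j]]
        lp <- .score(mod_b, d)
        c(auroc(lp, y_orig[[j]]), calibration_slope(lp, y_orig[[j]]))
      }, numeric(2))
      list(auc_boot = auc_boot,
           auc_orig = stats::median(eval_orig[1, ]),
           cal_slope = stats::median(eval_orig[2, ]),
           selected = names(sel$terms),
           spec_string = paste(names(sel$terms), sel$terms, sep = ":",
                               collapse = ","))
    }, error = function(e) {
      message("bootstrap replicate ", b, " failed: ", conditionMessage(e))
      NULL
    })
  }
  failed <- vapply(recs, is.null, logical(1))
  if (mean(failed) > 0.2) {
    stop("more than 20% of bootstrap replicates failed (",
         sum(failed), "/", B, ")", call. = FALSE)
  }
  ok <- recs[!failed]
  per <- data.frame(
    replicate = which(!failed),
    auc_boot = vapply(ok, `[[`, numeric(1), "auc_boot"),
    auc_orig = vapply(ok, `[[`, numeric(1), "auc_orig"),
    cal_slope = vapply(ok, `[[`, numeric(1), "cal_slope"),
    spec = vapply(ok, `[[`, character(1), "spec_string"),
    stringsAsFactors = FALSE)
  incl <- vapply(vars, function(v)
    mean(vapply(ok, function(r) v %in% r$selected, logical(1))), numeric(1))
  structure(list(B = B, per_replicate = per,
                 inclusion_frequency = incl,
                 optimism = mean(per$auc_boot - per$auc_orig),
                 shrinkage = mean(per$cal_slope),
                 n_failed = sum(failed)),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("Bootstrap validation:", nrow(x$per_replicate), "of", x$B,
      "replicates usable\n")
  cat(sprintf("  optimism (mean AUROCC boot - orig): %.4f\n", x$optimism))
  cat(sprintf("  linear shrinkage factor (mean calibration slope): %.4f\n",
              x$shrinkage))
  cat("  inclusion frequency:",
      paste(sprintf("%s %.2f", names(x$inclusion_frequency),
                    x$inclusion_frequency), collapse = ", "), "\n")
  invisible(x)
}

# Turn a pooled_fit into a scoring triage_model (median knots, unshrunk).
.fit_as_model <- function(fit) {
  cf <- fit$coefficients
  triage_model(fit$spec, fit$knots, cf[names(cf) != "(Intercept)"],
               intercept = unname(cf["(Intercept)"]), shrinkage = 1,
               provenance = "fitted")
}

#' Stability filter on bootstrap inclusion frequencies
#'
#' The final model keeps only variables selected both in the original
#' sample and in more than `threshold` (strictly) of the bootstrap
#' samples.
#'
#' @param original_spec The spec selected in the original sample.
#' @param report A `bootstrap_report` covering the candidate variables.
#' @param threshold Inclusion-frequency threshold (default 0.5, strict).
#' @return The filtered `model_spec`.
#' @export
stability_filter <- function(original_spec, report, threshold = 0.5) {
  freq <- report$inclusion_frequency
  missing_vars <- setdiff(names(original_spec$terms), names(freq))
  if (length(missing_vars) > 0) {
    stop("report lacks inclusion frequencies for: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  keep <- names(original_spec$terms)[freq[names(original_spec$terms)] > threshold]
  if (length(keep) == 0) {
    warning("no variable survives the stability filter; intercept-only model",
            call. = FALSE)
  }
  out <- original_spec
  out$terms <- original_spec$terms[keep]
  out
}

#' Apply the linear shrinkage factor and re-estimate the intercept
#'
#' Multiplies every non-intercept coefficient of the stability-filtered
#' pooled fit by the bootstrap shrinkage factor, then re-estimates the
#' intercept by refitting, in each imputed dataset, an intercept-only
#' logistic model with the shrunk linear predictor as a fixed offset,
#' pooled by Rubin's rules. This recalibrates absolute risk after
#' shrinkage (the shrunk constant cannot be taken from the unshrunk fit).
#'
#' @param fit The `pooled_fit` of the final (stability-filtered) spec.
#' @param report A `bootstrap_report` (its `shrinkage` is used), or a
#'   bare numeric shrinkage factor.
#' @param stack The original `imputed_stack` used to re-estimate the
#'   intercept.
#' @return A `triage_model` with shrunk coefficients, re-estimated
#'   intercept and provenance `"fitted"`.
#' @export
shrink <- function(fit, report, stack) {
  s <- if (inherits(report, "bootstrap_report")) report$shrinkage else
    as.numeric(report)
  if (!is.finite(s) || s <= 0) {
    stop("pathological shrinkage factor (s <= 0)", call. = FALSE)
  }
  stack <- .as_stack(stack)
  cf <- fit$coefficients
  beta <- cf[names(cf) != "(Intercept)"] * s
  model0 <- triage_model(fit$spec, fit$knots, beta, intercept = 0,
                         shrinkage = s, provenance = "fitted")
  ints <- vapply(seq_len(stack$m), function(j) {
    d <- stack$datasets[[j]]
    y <- if (fit$outcome == "primary") primary_outcome(d) else
      worst_case_outcome(d)
    off <- .score(model0, d)
    f <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial(),
                                     offset = off))
    c(stats::coef(f)[1], stats::vcov(f)[1, 1])
  }, numeric(2))
  b0 <- mean(ints[1, ])
  model0$intercept <- b0
  attr(model0, "intercept_se") <- sqrt(mean(ints[2, ]) +
    (if (stack$m > 1) (1 + 1 / stack$m) * stats::var(ints[1, ]) else 0))
  model0
}
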