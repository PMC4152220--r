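# The full derivation pipeline as one fitting function: impute, screen,
# select, bootstrap-validate, stability-filter, shrink, and summarise
# performance; plus the four sensitivity analyses.

#' Derive and internally validate a vital-signs mortality model
#'
#' Runs the complete derivation on a patient-level cohort:
#' \enumerate{
#'   \item multiple imputation by chained equations, stratified by
#'     hospital, with m set by the incomplete-case rule (\code{m = "auto"});
#'   \item lowess screening of each candidate vital sign's functional form;
#'   \item grouped backward selection at level `alpha` starting from the
#'     candidate specification (four-knot restricted cubic splines for SBP
#'     and HR, linear GCS by default);
#'   \item bootstrap replication of the whole procedure (`B` replicates,
#'     each separately imputed with `m_boot` imputations) giving selection
#'     stability, AUROCC optimism and the linear shrinkage factor;
#'   \item stability filtering (variables kept only if selected in the
#'     original sample and in >50\% of bootstrap samples), refit, uniform
#'     shrinkage of the coefficients and Rubin-pooled re-estimation of the
#'     intercept;
#'   \item discrimination and calibration summaries (median/IQR across
#'     imputed datasets).
#' }
#'
#' @param data A `trauma_cohort` or a data frame with the canonical
#'   columns (see [as_cohort()]).
#' @param outcome `"primary"` (patients discharged alive before 24 h count
#'   as alive) or `"worst_case"` (they count as dead).
#' @param candidates Starting [model_spec()] for selection.
#' @param m Number of imputations, or `"auto"` for the incomplete-case
#'   rule ([choose_m()]).
#' @param B Bootstrap replicates (study value 300).
#' @param m_boot Imputations per bootstrap replicate.
#' @param alpha Selection level (study value 0.2).
#' @param stability_threshold Bootstrap inclusion-frequency threshold.
#' @param n_iter Chained-equations cycles.
#' @param seed Master seed; every random stage derives its stream from it.
#' @return An object of class `trauma24` with components `cohort`, `stack`,
#'   `screen`, `selection` (spec + trace), `bootstrap`
#'   (`bootstrap_report`), `fit` (`pooled_fit` of the final spec),
#'   `final_model` (`triage_model`), `performance`, `m`, `seed`, `call`.
#' @examples
#' \donttest{
#' coh <- impose_missingness(generate_cohort(cohort_spec(n = 800, seed = 7)))
#' fit <- trauma24(coh, m = 3, B = 10, m_boot = 2, seed = 7)
#' print(fit)
#' }
#' @export
trauma24 <- function(data, outcome = c("primary", "worst_case"),
                     candidates = model_spec(sbp = "rcs4", hr = "rcs4",
                                             gcs = "linear"),
                     m = "auto", B = 300, m_boot = 5, alpha = 0.2,
                     stability_threshold = 0.5, n_iter = 10, seed = 1L) {
  outcome <- match.arg(outcome)
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]", call. = FALSE)
  cohort <- if (inherits(data, "trauma_cohort")) data else as_cohort(data)
  y <- if (outcome == "primary") primary_outcome(cohort) else
    worst_case_outcome(cohort)
  if (length(unique(y)) < 2) {
    stop("cohort needs at least one event and one non-event", call. = FALSE)
  }
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  stack <- impute_cohort(cohort, m = m, n_iter = n_iter, outcome = outcome,
                         seed = stage_seeds[1])
  screen <- lapply(stats::setNames(nm = names(candidates$terms)), function(v)
    tryCatch(lowess_screen(cohort, v, outcome = outcome),
             error = function(e) NULL))

  selected <- backward_select(stack, candidates, alpha = alpha)
  boot <- bootstrap_validate(cohort, candidates, B = B, m_boot = m_boot,
                             seed = stage_seeds[2], orig_stack = stack,
                             alpha = alpha, n_iter = n_iter,
                             outcome = outcome)
  stable <- stability_filter(selected, boot, threshold = stability_threshold)
  fit <- fit_pooled(stack, stable)
  final <- shrink(fit, boot, stack)
  perf <- .performance_summary(final, stack, outcome)
  perf$optimism <- boot$optimism
  perf$auroc_corrected <- unname(perf$auroc["median"]) - boot$optimism

  structure(list(cohort = cohort, stack = stack, screen = screen,
                 selection = selected, bootstrap = boot, fit = fit,
                 final_model = final, performance = perf,
                 outcome = outcome, m = stack$m, seed = seed,
                 alpha = alpha, call = match.call()),
            class = "trauma24")
}

# Median/IQR performance of a scoring model across an imputed stack.
.performance_summary <- function(model, stack, outcome,
                                 sensitivities = seq(95, 50, -5)) {
  stack <- .as_stack(stack)
  per <- lapply(stack$datasets, function(d) {
    y <- if (outcome == "primary") primary_outcome(d) else
      worst_case_outcome(d)
    lp <- .score(model, d)
    p <- stats::plogis(lp)
    list(auc = auroc(p, y),
         hl = suppressWarnings(hosmer_lemeshow(p, y)$p_value),
         slope = calibration_slope(lp, y),
         bins = calibration_bins(p, y),
         cuts = cutoff_table(p, y, sensitivities))
  })
  cuts <- lapply(per, `[[`, "cuts")
  med_cuts <- cuts[[1]]
  for (col in setdiff(names(med_cuts), "sensitivity")) {
    med_cuts[[col]] <- apply(vapply(cuts, `[[`, numeric(nrow(med_cuts)), col),
                             1, stats::median)
  }
  bins1 <- lapply(per, `[[`, "bins")
  list(auroc = pooled_metric(vapply(per, `[[`, numeric(1), "auc")),
       hl_p = pooled_metric(vapply(per, `[[`, numeric(1), "hl")),
       calibration_slope = stats::median(vapply(per, `[[`, numeric(1),
                                                "slope")),
       calibration_bins = bins1[[which(order(vapply(per, `[[`, numeric(1),
                                                    "auc")) ==
                                         ceiling(length(per) / 2))]],
       cutoff_table = med_cuts)
}

#' @export
print.trauma24 <- function(x, ...) {
  cat("24-hour trauma mortality model (derivation + internal validation)\n")
  cat("  n =", nrow(x$cohort), "| events =",
      sum(if (x$outcome == "primary") primary_outcome(x$cohort) else
        worst_case_outcome(x$cohort)),
      "| m =", x$m, "imputations | B =", x$bootstrap$B, "replicates\n")
  cat("  final terms:", paste(names(x$final_model$spec$terms),
                              x$final_model$spec$terms, sep = ":",
                              collapse = ", "), "\n")
  cat(sprintf("  apparent AUROCC %.3f (IQR %.3f-%.3f) | optimism %.3f | corrected %.3f\n",
              x$performance$auroc["median"], x$performance$auroc["q25"],
              x$performance$auroc["q75"], x$performance$optimism,
              x$performance$auroc_corrected))
  cat(sprintf("  shrinkage factor %.3f | calibration slope %.3f | HL median p %.3f\n",
              x$bootstrap$shrinkage, x$performance$calibration_slope,
              x$performance$hl_p["median"]))
  invisible(x)
}

#' @export
summary.trauma24 <- function(object, ...) {
  fit <- object$fit
  cf <- fit$coefficients
  se <- sqrt(diag(fit$covariance))
  s <- object$final_model$shrinkage
  shr <- ifelse(names(cf) == "(Intercept)", NA, cf * s)
  tab <- data.frame(
    coefficient = round(cf, 4), lcl = round(cf - 1.96 * se, 4),
    ucl = round(cf + 1.96 * se, 4),
    p_group = round(fit$group_p[object$fit$groups], 4)[seq_along(cf)],
    shrunk = round(shr, 4))
  tab$p_group[names(cf) == "(Intercept)"] <- NA
  out <- list(table = tab, shrinkage = s,
              intercept_shrunk = object$final_model$intercept,
              performance = object$performance,
              inclusion = object$bootstrap$inclusion_frequency)
  class(out) <- "summary.trauma24"
  out
}

#' @export
print.summary.trauma24 <- function(x, ...) {
  cat("Final model estimates (before and after shrinkage, factor ",
      sprintf("%.3f", x$shrinkage), ")\n", sep = "")
  print(x$table)
  cat(sprintf("Re-estimated shrunk intercept: %.4f\n", x$intercept_shrunk))
  cat("Bootstrap inclusion frequencies:",
      paste(sprintf("%s %.2f", names(x$inclusion), x$inclusion),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.trauma24 <- function(object, shrunk = TRUE, ...) {
  if (shrunk) coef(object$final_model) else object$fit$coefficients
}

#' @export
predict.trauma24 <- function(object, newdata,
                             type = c("response", "link"), ...) {
  predict(object$final_model, newdata, type = match.arg(type))
}

#' Calibration plot of a derived model
#'
#' Observed mortality across quantile bins of predicted probability, with
#' the identity (perfect calibration) line.
#'
#' @param x A `trauma24` fit.
#' @param ... Passed to `plot()`.
#' @export
plot.trauma24 <- function(x, ...) {
  b <- x$performance$calibration_bins
  lim <- range(c(b$mean_predicted, b$observed, 0))
  graphics::plot(b$mean_predicted, b$observed, xlim = lim, ylim = lim,
                 xlab = "Predicted probability of 24-h mortality",
                 ylab = "Observed proportion", pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("calibration slope %.2f",
                                    x$performance$calibration_slope))
  invisible(x)
}

#' @export
simulate.trauma24 <- function(object, nsim = 1, seed = NULL, newdata = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(newdata)) newdata <- object$stack$datasets[[1]]
  p <- predict(object$final_model, newdata, type = "response")
  out <- as.data.frame(replicate(nsim, stats::runif(length(p)) < p))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Sensitivity analyses around a derived model
#'
#' Reproduces the study's four sensitivity analyses:
#' \describe{
#'   \item{reduced}{refit with only the two strongest predictors (smallest
#'     grouped Wald p in the final fit), compared to the final model by a
#'     paired DeLong AUROCC test per imputed dataset (median p).}
#'   \item{full}{age, sex, transfer status and mechanism of injury forced
#'     in regardless of significance, same comparison.}
#'   \item{worst_case}{the whole pipeline rerun with patients discharged
#'     alive before 24 h recoded as dead (selection + fit, no bootstrap).}
#'   \item{complete_case}{selection + fit on rows with no missing modelled
#'     values, no imputation.}
#' }
#'
#' @param object A `trauma24` fit.
#' @param which Analyses to run.
#' @param seed Seed for the re-imputation in `worst_case`.
#' @return Named list; each element reports the refit spec, median AUROCC
#'   and (for reduced/full) the median paired DeLong p-value.
#' @export
sensitivity_analysis <- function(object,
                                 which = c("reduced", "full", "worst_case",
                                           "complete_case"),
                                 seed = object$seed + 1L) {
  which <- match.arg(which, several.ok = TRUE)
  stack <- object$stack
  out <- list()
  final_spec <- object$fit$spec

  if ("reduced" %in% which) {
    gp <- sort(object$fit$group_p)
    keep <- names(gp)[seq_len(min(2, length(gp)))]
    spec_r <- final_spec
    spec_r$terms <- final_spec$terms[keep]
    fit_r <- fit_pooled(stack, spec_r)
    out$reduced <- .compare_models(object, fit_r, stack)
  }
  if ("full" %in% which) {
    spec_f <- final_spec
    spec_f$extras <- c("age", "sex", "transferred", "mechanism")
    fit_f <- fit_pooled(stack, spec_f)
    out$full <- .compare_models(object, fit_f, stack)
  }
  if ("worst_case" %in% which) {
    stack_w <- impute_cohort(object$cohort, m = object$stack$m,
                             outcome = "worst_case", seed = seed)
    sel_w <- backward_select(stack_w, model_spec(sbp = "rcs4", hr = "rcs4",
                                                 gcs = "linear"),
                             alpha = object$alpha)
    fit_w <- if (!is.null(attr(sel_w, "fit"))) attr(sel_w, "fit") else
      fit_pooled(stack_w, sel_w)
    mod_w <- .fit_as_model(fit_w)
    aucs <- vapply(stack_w$datasets, function(d)
      auroc(.score(mod_w, d), worst_case_outcome(d)), numeric(1))
    out$worst_case <- list(spec = sel_w, auroc = pooled_metric(aucs))
  }
  if ("complete_case" %in% which) {
    cc <- object$cohort[stats::complete.cases(
      object$cohort[, c("sbp", "hr", "gcs", "tti_hours")]), , drop = FALSE]
    class(cc) <- class(object$cohort)
    y_cc <- if (object$outcome == "primary") primary_outcome(cc) else
      worst_case_outcome(cc)
    if (length(unique(y_cc)) < 2) {
      stop("complete-case subset has no events (or no non-events)",
           call. = FALSE)
    }
    sel_c <- backward_select(cc, model_spec(sbp = "rcs4", hr = "rcs4",
                                            gcs = "linear"),
                             alpha = object$alpha)
    fit_c <- if (!is.null(attr(sel_c, "fit"))) attr(sel_c, "fit") else
      fit_pooled(cc, sel_c)
    mod_c <- .fit_as_model(fit_c)
    out$complete_case <- list(spec = sel_c, n = nrow(cc),
                              auroc = auroc(.score(mod_c, cc), y_cc))
  }
  out
}

# Paired per-dataset AUROCC comparison of an alternative fit vs the final
# model (DeLong test via pROC when available; median p across imputations).
.compare_models <- function(object, alt_fit, stack) {
  mod_alt <- .fit_as_model(alt_fit)
  final <- object$final_model
  outc <- object$outcome
  per <- vapply(stack$datasets, function(d) {
    y <- if (outc == "primary") primary_outcome(d) else worst_case_outcome(d)
    lp_f <- .score(final, d)
    lp_a <- .score(mod_alt, d)
    p <- if (requireNamespace("pROC", quietly = TRUE)) {
      rt <- pROC::roc.test(
        pROC::roc(y, lp_f, quiet = TRUE, direction = "<"),
        pROC::roc(y, lp_a, quiet = TRUE, direction = "<"),
        method = "delong", paired = TRUE)
      rt$p.value
    } else NA_real_
    c(auroc(lp_a, y), auroc(lp_f, y), p)
  }, numeric(3))
  list(spec = alt_fit$spec,
       auroc = pooled_metric(per[1, ]),
       auroc_final = pooled_metric(per[2, ]),
       delong_p_median = stats::median(per[3, ]))
}
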