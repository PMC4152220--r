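# Discrimination and calibration metrics, pooled across imputations by
# median and interquartile range.

#' Area under the ROC curve (concordance form)
#'
#' Probability that a randomly chosen event receives a higher prediction
#' than a randomly chosen non-event, ties counted one half (the
#' Mann-Whitney statistic), computed from ranks in O(n log n).
#'
#' @param predicted Numeric predictions (any monotone score).
#' @param outcome Logical (or 0/1) outcome vector.
#' @return AUROCC in [0, 1].
#' @export
auroc <- function(predicted, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(predicted) == length(outcome), !anyNA(predicted),
            !anyNA(outcome))
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) {
    stop("AUROCC undefined: only one outcome class present", call. = FALSE)
  }
  r <- rank(predicted, ties.method = "average")
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups patients into `groups` quantile bins of predicted probability
#' ("deciles of risk" by default), compares observed and expected event
#' counts with the statistic \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))},
#' and refers it to a chi-square distribution with `groups - 2` degrees of
#' freedom. Bins whose expected count is zero are merged with a neighbour.
#'
#' @param predicted Predicted probabilities.
#' @param outcome Logical outcome vector.
#' @param groups Number of risk groups (default 10; must be > 2).
#' @return List with `statistic`, `df`, `p_value` and the per-group table.
#' @export
hosmer_lemeshow <- function(predicted, outcome, groups = 10) {
  outcome <- as.logical(outcome)
  if (groups <= 2) stop("groups must exceed 2 (df = groups - 2)", call. = FALSE)
  n <- length(predicted)
  if (n < 10 * groups) {
    warning("fewer than 10 observations per risk group", call. = FALSE)
  }
  br <- unique(stats::quantile(predicted, seq(0, 1, length.out = groups + 1)))
  g <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(g)), function(k) {
    sel <- g == k
    data.frame(n = sum(sel), observed = sum(outcome[sel]),
               expected = sum(predicted[sel]),
               mean_predicted = mean(predicted[sel]))
  }))
  # merge empty-expectation groups upward
  while (nrow(tab) > 1 && any(tab$expected < 1e-12)) {
    k <- which(tab$expected < 1e-12)[1]
    into <- if (k == 1) 2 else k - 1
    tab[into, c("n", "observed", "expected")] <-
      tab[into, c("n", "observed", "expected")] + tab[k, c("n", "observed", "expected")]
    tab <- tab[-k, , drop = FALSE]
    message("Hosmer-Lemeshow: merged an empty risk group")
  }
  stat <- sum((tab$observed - tab$expected)^2 /
                (tab$expected * (1 - tab$expected / tab$n)))
  df <- nrow(tab) - 2
  if (df < 1) stop("too few usable risk groups (df < 1)", call. = FALSE)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Calibration slope
#'
#' Slope from a logistic refit of the outcome on a model's linear
#' predictor, intercept free. A slope of 1 indicates well-scaled
#' predictions; below 1, overfitting.
#'
#' @param linear_predictor Linear predictor (log-odds scale).
#' @param outcome Logical outcome vector.
#' @return Scalar slope.
#' @export
calibration_slope <- function(linear_predictor, outcome) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2) {
    stop("calibration slope undefined: single outcome class", call. = FALSE)
  }
  X <- cbind(1, linear_predictor)
  fit <- suppressWarnings(stats::glm.fit(X, outcome,
                                         family = stats::binomial()))
  if (is.na(fit$coefficients[2])) {
    stop("calibration slope undefined: degenerate linear predictor",
         call. = FALSE)
  }
  if (!fit$converged || abs(fit$coefficients[2]) > 100) {
    stop("calibration refit failed (separation?)", call. = FALSE)
  }
  unname(fit$coefficients[2])
}

#' Calibration bins across quantiles of predicted probability
#'
#' @param predicted Predicted probabilities.
#' @param outcome Logical outcome vector.
#' @param bins Number of quantile bins (default 10).
#' @return Data frame with `mean_predicted`, `observed`, `n` per bin.
#' @export
calibration_bins <- function(predicted, outcome, bins = 10) {
  outcome <- as.logical(outcome)
  br <- unique(stats::quantile(predicted, seq(0, 1, length.out = bins + 1)))
  g <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(g)), function(k) {
    sel <- g == k
    data.frame(mean_predicted = mean(predicted[sel]),
               observed = mean(outcome[sel]), n = sum(sel))
  }))
  out
}

#' Operating characteristics at target sensitivities
#'
#' For each target sensitivity, finds the largest probability cut-off whose
#' sensitivity is at least the target, and reports specificity, the
#' cut-off, and false-positive / false-negative counts. Percentages use
#' the non-event total as the false-positive base and the event total as
#' the false-negative base; raw counts are reported so either convention
#' can be recomputed.
#'
#' @param predicted Predicted probabilities.
#' @param outcome Logical outcome vector.
#' @param sensitivities Target sensitivities in percent (default 95 down
#'   to 50 in steps of 5).
#' @return Data frame with one row per target sensitivity.
#' @export
cutoff_table <- function(predicted, outcome, sensitivities = seq(95, 50, -5)) {
  outcome <- as.logical(outcome)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0) stop("no events: sensitivity targets unattainable", call. = FALSE)
  if (n0 == 0) stop("no non-events", call. = FALSE)
  cand <- sort(unique(c(0, predicted)))
  pe <- sort(predicted[outcome])   # events
  pn <- sort(predicted[!outcome])  # non-events
  rows <- lapply(sensitivities, function(s) {
    # sensitivity at cutoff c: mean(pe >= c); decreasing in c
    sens_at <- (n1 - findInterval(cand, pe, left.open = TRUE)) / n1
    ok <- which(sens_at >= s / 100)
    cutoff <- cand[max(ok)]
    fn <- findInterval(cutoff, pe, left.open = TRUE)
    fp <- n0 - findInterval(cutoff, pn, left.open = TRUE)
    data.frame(sensitivity = s,
               specificity = 100 * (n0 - fp) / n0,
               cutoff = cutoff,
               false_positives = fp, false_positive_pct = 100 * fp / n0,
               false_negatives = fn, false_negative_pct = 100 * fn / n1)
  })
  do.call(rbind, rows)
}

#' Median and interquartile range across imputations
#'
#' The pooling convention for performance metrics: report the median and
#' the 25th/75th percentiles of the per-imputation values.
#'
#' @param values Numeric vector of per-imputation metric values.
#' @return Named vector `median`, `q25`, `q75`.
#' @export
pooled_metric <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}
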