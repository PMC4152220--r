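test_that("AUROCC equals the O(n^2) pairwise concordance oracle", {
  brute_auc <- function(p, y) {
    e <- p[y]; ne <- p[!y]
    tot <- 0
    for (a in e) for (b in ne) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(e) * length(ne))
  }
  set.seed(55)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    y <- c(TRUE, FALSE, runif(n - 2) < 0.4)  # both classes guaranteed
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # ties at low precision
    expect_equal(auroc(p, y), brute_auc(p, y), tolerance = 1e-12)
  }
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auroc(runif(5), rep(TRUE, 5)), "one outcome class")
})

test_that("AUROCC complement symmetry and rank invariance hold", {
  set.seed(66)
  for (i in 1:10) {
    y <- runif(40) < 0.3
    if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
    p <- runif(40)
    expect_equal(auroc(p, y) + auroc(1 - p, y), 1, tolerance = 1e-12)
    expect_equal(auroc(p, y), auroc(qlogis(p), y), tolerance = 1e-12)
  }
})

test_that("AUROCC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  y <- runif(300) < 0.2
  y[1:2] <- c(TRUE, FALSE)
  p <- plogis(rnorm(300) + 2 * y)
  expect_equal(auroc(p, y),
               as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("Hosmer-Lemeshow statistic matches hand arithmetic", {
  # four risk groups of 5, observed/expected tallied by hand
  p <- c(rep(0.1, 5), rep(0.2, 5), rep(0.4, 5), rep(0.8, 5))
  y <- c(TRUE, rep(FALSE, 4),            # O=1, E=0.5
         TRUE, TRUE, rep(FALSE, 3),      # O=2, E=1.0
         TRUE, rep(FALSE, 4),            # O=1, E=2.0
         rep(TRUE, 4), FALSE)            # O=4, E=4.0
  hl <- suppressWarnings(hosmer_lemeshow(p, y, groups = 4))
  stat_hand <- (1 - 0.5)^2 / (0.5 * (1 - 0.5 / 5)) +
    (2 - 1)^2 / (1 * (1 - 1 / 5)) +
    (1 - 2)^2 / (2 * (1 - 2 / 5)) +
    (4 - 4)^2 / (4 * (1 - 4 / 5))
  expect_equal(hl$statistic, stat_hand, tolerance = 1e-12)
  expect_equal(hl$df, 2)
  expect_equal(hl$p_value, pchisq(stat_hand, 2, lower.tail = FALSE))
  expect_error(hosmer_lemeshow(p, y, groups = 2), "df = groups - 2")
})

test_that("Hosmer-Lemeshow holds its type-I error near nominal", {
  # probabilities from a correctly specified fitted model: the g - 2
  # degrees of freedom convention applies to post-fit assessment
  set.seed(88)
  rej <- mean(replicate(120, {
    x <- rnorm(600)
    y <- runif(600) < plogis(-2 + x)
    p <- fitted(glm(y ~ x, family = binomial()))
    suppressWarnings(hosmer_lemeshow(p, y)$p_value) < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.06)
})

test_that("calibration slope detects scaling of the linear predictor", {
  set.seed(99)
  n <- 50000
  lp <- rnorm(n, -2.5, 1.3)
  y <- runif(n) < plogis(lp)
  expect_equal(calibration_slope(lp, y), 1, tolerance = 0.05)
  expect_equal(calibration_slope(2 * lp, y), 0.5, tolerance = 0.05)
  expect_lt(calibration_slope(-lp, y), 0)
  expect_error(calibration_slope(lp, rep(TRUE, n)), "single outcome class")
})

test_that("cutoff table equals a brute-force threshold sweep", {
  set.seed(111)
  p <- round(runif(60), 2)
  y <- runif(60) < p
  if (length(unique(y)) < 2) y[1:2] <- c(TRUE, FALSE)
  tab <- cutoff_table(p, y, sensitivities = c(95, 80, 60))
  n1 <- sum(y); n0 <- sum(!y)
  for (r in seq_len(nrow(tab))) {
    target <- tab$sensitivity[r] / 100
    # brute force: largest cutoff achieving the target sensitivity
    cands <- sort(unique(c(0, p)), decreasing = TRUE)
    best <- NA
    for (cth in cands) {
      if (mean(p[y] >= cth) >= target) { best <- cth; break }
    }
    expect_equal(tab$cutoff[r], best)
    expect_equal(tab$false_positives[r], sum(p[!y] >= best))
    expect_equal(tab$false_negatives[r], sum(p[y] < best))
    expect_equal(tab$specificity[r], 100 * mean(p[!y] < best))
    expect_equal(tab$false_positive_pct[r], 100 * sum(p[!y] >= best) / n0)
    expect_equal(tab$false_negative_pct[r], 100 * sum(p[y] < best) / n1)
  }
  # specificity is non-increasing as target sensitivity rises
  tab_full <- cutoff_table(p, y)
  expect_true(all(diff(tab_full$specificity) >= 0))  # rows go 95 -> 50
})

test_that("cutoff table boundary behaviour", {
  p <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  tab <- cutoff_table(p, y, sensitivities = c(100, 95, 50))
  expect_true(all(tab$specificity == 100))  # perfect separation
  # all-events-caught at cutoff 0 when predictions force it
  p2 <- c(0.5, 0.01, 0.6, 0.4)
  y2 <- c(TRUE, TRUE, FALSE, FALSE)
  tab2 <- cutoff_table(p2, y2, sensitivities = 100)
  expect_equal(tab2$false_negatives, 0)
  expect_error(cutoff_table(numeric(0), logical(0)), "no events")
})

test_that("pooled metrics report median and IQR across imputations", {
  pm <- pooled_metric(c(0.85, 0.85, 0.86))
  expect_equal(unname(pm["median"]), 0.85)
  expect_equal(pooled_metric(0.5),
               c(median = 0.5, q25 = 0.5, q75 = 0.5))
  expect_equal(unname(pooled_metric(seq(0.1, 0.9, 0.1))["median"]), 0.5)
})
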