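test_that("choose_m follows the worst-hospital incomplete-case rule", {
  # build a cohort whose hospitals have incomplete-case proportions
  # 1%, 30% and 51% exactly
  base <- toy_cohort_df(6)
  mk <- function(hosp, n, n_incomplete) {
    df <- base[rep(1, n), ]
    df$hospital_id <- hosp
    df$died_24h <- rep(c(TRUE, FALSE), length.out = n)
    df$sbp[seq_len(n_incomplete)] <- NA
    df
  }
  coh <- as_cohort(rbind(mk("A", 100, 1), mk("B", 100, 30), mk("C", 100, 51)))
  m <- choose_m(coh)
  expect_equal(as.integer(m), 51L)
  expect_equal(as.numeric(round(attr(m, "by_hospital"), 2)),
               c(0.01, 0.30, 0.51))

  # complete cohort needs no imputation
  expect_equal(as.integer(choose_m(as_cohort(toy_cohort_df(10)))), 0L)

  # single hospital, 10% incomplete
  coh1 <- as_cohort(mk("A", 100, 10))
  expect_equal(as.integer(choose_m(coh1)), 10L)

  # any missingness yields at least 2 imputed datasets
  coh2 <- as_cohort(mk("A", 200, 1))
  expect_equal(as.integer(choose_m(coh2)), 2L)
})

test_that("imputation fills every hole, never touches observed cells", {
  cm <- small_missing_cohort(n = 600, seed = 7)
  st <- impute_cohort(cm, m = 3, seed = 11)
  expect_equal(st$m, 3L)
  for (d in st$datasets) {
    expect_false(anyNA(d[c("sbp", "hr", "gcs", "tti_hours")]))
    expect_true(all(d$gcs %in% 3:15))
    for (v in c("sbp", "hr", "gcs", "tti_hours")) {
      obs <- !is.na(cm[[v]])
      expect_equal(d[[v]][obs], cm[[v]][obs])
    }
  }
  # imputations genuinely differ (between-imputation variance > 0)
  means <- sapply(st$datasets, function(d) mean(d$sbp[is.na(cm$sbp)]))
  expect_gt(var(means), 0)
  # deterministic under the same master seed
  st2 <- impute_cohort(cm, m = 3, seed = 11)
  expect_identical(lapply(st$datasets, as.data.frame),
                   lapply(st2$datasets, as.data.frame))
})

test_that("stacks export to a long-format CSV with an imputation index", {
  cm <- small_missing_cohort(n = 120, seed = 5)
  st <- suppressWarnings(impute_cohort(cm, m = 2, seed = 6))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stack(st, path)
  long <- read.csv(path)
  expect_equal(nrow(long), 2 * nrow(cm))
  expect_equal(unique(long$imputation), c(1, 2))
  expect_equal(long$sbp[long$imputation == 2], st$datasets[[2]]$sbp)
})

test_that("a complete cohort passes through imputation unchanged", {
  coh <- generate_cohort(cohort_spec(n = 200, seed = 2))
  st <- impute_cohort(coh, m = 2, seed = 1)
  expect_identical(as.data.frame(st$datasets[[1]]), as.data.frame(coh))
  expect_identical(as.data.frame(st$datasets[[2]]), as.data.frame(coh))
})

test_that("imputed SBP marginal stays close to the pre-masking truth", {
  spec <- cohort_spec(n = 4000, seed = 23)
  coh <- generate_cohort(spec)
  cm <- impose_missingness(coh, spec)
  st <- impute_cohort(cm, m = 5, seed = 23)
  imp_mean <- mean(sapply(st$datasets, function(d) mean(d$sbp)))
  expect_lt(abs(imp_mean - mean(coh$sbp)) / mean(coh$sbp), 0.05)
})

test_that("tiny hospital strata fall back to pooled imputation models", {
  cm <- small_missing_cohort(n = 300, seed = 9)
  cm$hospital_id <- factor(c(rep("tiny", 10),
                             as.character(cm$hospital_id[-(1:10)])))
  expect_warning(st <- impute_cohort(cm, m = 2, seed = 4),
                 "stratum collapse")
  expect_false(anyNA(st$datasets[[1]][c("sbp", "hr", "gcs", "tti_hours")]))
})

test_that("multiple imputation reduces outcome-dependent MAR bias", {
  # missingness loaded on the outcome biases complete-case estimates of
  # the GCS coefficient; Rubin-pooled MI estimates should be closer to
  # truth on average
  n_seeds <- 4
  bias_cc <- bias_mi <- numeric(n_seeds)
  spec_template <- cohort_spec(n = 3000,
                               missingness = list(
                                 rates = c(sbp = 0.20, hr = 0.15, gcs = 0.20,
                                           tti_hours = 0.05),
                                 incomplete_by_hospital = NULL,
                                 beta_outcome = 1.2, beta_age = 0))
  ms <- model_spec(sbp = "rcs4", hr = "rcs4", gcs = "linear")
  truth <- truth_of(spec_template)
  kn <- list(sbp = knot_set(spec_template$sbp_knots, "sbp"),
             hr = knot_set(spec_template$hr_knots, "hr"))
  for (s in seq_len(n_seeds)) {
    sp <- spec_template; sp$seed <- 400L + s
    coh <- generate_cohort(sp)
    cm <- impose_missingness(coh, sp)
    cc <- cm[complete.cases(cm[c("sbp", "hr", "gcs", "tti_hours")]), ]
    class(cc) <- class(cm)
    fit_cc <- fit_pooled(cc, ms, knots = kn)
    st <- impute_cohort(cm, m = 5, seed = 400L + s)
    fit_mi <- fit_pooled(st, ms, knots = kn)
    bias_cc[s] <- abs(fit_cc$coefficients[["gcs"]] - truth[["gcs"]])
    bias_mi[s] <- abs(fit_mi$coefficients[["gcs"]] - truth[["gcs"]])
  }
  expect_lt(mean(bias_mi), mean(bias_cc))
})
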