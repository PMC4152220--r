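test_that("Rubin pooling matches the two-imputation closed form exactly", {
  # hand-crafted coefficient sets with known within-covariances
  co <- cbind(c(0.2, -1.0, 3.5), c(0.4, -1.4, 3.1))
  rownames(co) <- c("a", "b", "c")
  W1 <- diag(c(0.01, 0.04, 0.09))
  W2 <- diag(c(0.03, 0.02, 0.07))
  pooled <- rubin_pool(co, list(W1, W2))
  expect_equal(unname(pooled$coefficients), c(0.3, -1.2, 3.3),
               tolerance = 1e-12)
  Wbar <- (W1 + W2) / 2
  B <- cov(t(co))
  expect_equal(pooled$covariance, Wbar + (1 + 1 / 2) * B, tolerance = 1e-12)
  expect_equal(pooled$within, Wbar, tolerance = 1e-15)
  # total variance never falls below the mean within-imputation variance
  expect_true(all(diag(pooled$covariance) >= diag(pooled$within)))
})

test_that("stack fitting reproduces per-dataset MLEs and their pool", {
  spec <- cohort_spec(n = 500, seed = 19)
  cm <- impose_missingness(generate_cohort(spec), spec)
  st <- impute_cohort(cm, m = 2, seed = 3)
  ms <- model_spec(gcs = "linear")
  pooled <- fit_pooled(st, ms)

  # oracle: per-dataset glm fits pooled by hand (vcov tolerance reflects
  # the IRLS working-weight convention difference in summary.glm)
  fits <- lapply(st$datasets, function(d)
    glm(primary_outcome(d) ~ gcs, family = binomial(), data = d))
  co <- sapply(fits, coef)
  qbar <- rowMeans(co)
  Wbar <- (vcov(fits[[1]]) + vcov(fits[[2]])) / 2
  B <- cov(t(co))
  Tcov <- Wbar + (1 + 1 / 2) * B
  expect_equal(unname(pooled$coefficients), unname(qbar), tolerance = 1e-8)
  expect_equal(unname(pooled$covariance), unname(Tcov), tolerance = 1e-4)

  # m = 1 collapses to the single-dataset MLE
  coh <- generate_cohort(cohort_spec(n = 500, seed = 21))
  one <- fit_pooled(coh, ms)
  ref <- glm(primary_outcome(coh) ~ gcs, family = binomial(), data = coh)
  expect_equal(unname(one$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(one$covariance), unname(vcov(ref)), tolerance = 1e-4)
  expect_equal(unname(one$covariance), unname(one$within))
})

test_that("joint Wald test equals brute-force quadratic forms", {
  # hand-built pooled fit: 3-coefficient block with a chosen covariance
  cc <- c(0.5, -0.2, 0.1)
  Sig <- matrix(c(0.04, 0.01, 0, 0.01, 0.09, 0.02, 0, 0.02, 0.25), 3, 3)
  fake <- structure(list(coefficients = c(`(Intercept)` = 0, a1 = cc[1],
                                          a2 = cc[2], a3 = cc[3]),
                         covariance = rbind(0, cbind(0, Sig)) + diag(1e-9, 4),
                         groups = c("(Intercept)", "a", "a", "a")),
                    class = "pooled_fit")
  p <- joint_wald(fake, "a")
  stat_oracle <- drop(t(cc) %*% solve(Sig + diag(1e-9, 3)) %*% cc)
  expect_equal(attr(p, "statistic"), stat_oracle, tolerance = 1e-9)
  expect_equal(as.numeric(p), pchisq(stat_oracle, 3, lower.tail = FALSE))

  # a 1-df block reproduces the squared z-test
  z <- 1.96
  fake1 <- structure(list(coefficients = c(`(Intercept)` = 0, b = z),
                          covariance = diag(c(1, 1)),
                          groups = c("(Intercept)", "b")),
                     class = "pooled_fit")
  p1 <- joint_wald(fake1, "b")
  expect_equal(attr(p1, "statistic"), z^2, tolerance = 1e-12)
  expect_equal(as.numeric(p1), pchisq(z^2, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(as.numeric(p1), 0.04999579, tolerance = 1e-5)

  # zero coefficients give statistic 0
  fake0 <- structure(list(coefficients = c(`(Intercept)` = 1, c1 = 0, c2 = 0),
                          covariance = diag(3),
                          groups = c("(Intercept)", "c", "c")),
                     class = "pooled_fit")
  expect_equal(attr(joint_wald(fake0, "c"), "statistic"), 0)
  expect_equal(as.numeric(joint_wald(fake0, "c")), 1)
})

test_that("per-imputation fits respect the grouped design", {
  coh <- generate_cohort(cohort_spec(n = 3000, seed = 8))
  fit <- fit_pooled(coh, model_spec(sbp = "rcs4", hr = "rcs4", gcs = "linear"))
  expect_equal(names(fit$coefficients),
               c("(Intercept)", paste0("sbp_basis", 1:3),
                 paste0("hr_basis", 1:3), "gcs"))
  expect_true(all(fit$group_p >= 0 & fit$group_p <= 1))
  expect_error(joint_wald(fit, "age"), "not in fit")
  expect_error(joint_wald(fit, "gcs", nonlinear_only = TRUE),
               "no nonlinear components")
})

test_that("lowess screening separates linear from U-shaped effects", {
  # linear GCS truth: low linearity index
  spec_lin <- cohort_spec(n = 4000, seed = 33)
  coh <- generate_cohort(spec_lin)
  scr_gcs <- lowess_screen(coh, "gcs")
  expect_lt(scr_gcs$linearity_index, 0.2)
  expect_false(scr_gcs$flagged)
  # a strongly U-shaped HR truth: high index
  tc <- truth_of(cohort_spec())
  tc[] <- 0
  tc[["hr_basis1"]] <- -0.10
  tc[["hr_basis2"]] <- 0
  tc[["hr_basis3"]] <- 0.9
  spec_u <- cohort_spec(n = 4000, seed = 34, true_coefficients = tc)
  coh_u <- generate_cohort(spec_u)
  scr_hr <- lowess_screen(coh_u, "hr")
  expect_gt(scr_hr$linearity_index, 0.2)
  expect_true(scr_hr$flagged)
  # degenerate inputs
  tiny <- coh[1:50, ]; class(tiny) <- class(coh)
  expect_error(lowess_screen(tiny, "hr"), "100 observed pairs")
  const <- coh; const$hr <- 90
  expect_error(lowess_screen(const, "hr"), "constant")
})

test_that("backward selection reduces splines, removes noise, keeps signal", {
  spec <- cohort_spec(n = 6000, seed = 44)
  coh <- generate_cohort(spec)
  full <- model_spec(sbp = "rcs4", hr = "rcs4", gcs = "linear")
  sel <- backward_select(coh, full)
  expect_true(all(c("sbp", "gcs") %in% names(sel$terms)))
  expect_equal(sel$terms[["gcs"]], "linear")
  tr <- attr(sel, "trace")
  expect_true(is.list(tr))

  # alpha = 1 keeps the full spec untouched
  sel_all <- backward_select(coh, full, alpha = 1)
  expect_identical(sel_all$terms, full$terms)

  # selection is invariant to the order variables are listed
  sel_rev <- backward_select(coh, model_spec(gcs = "linear", hr = "rcs4",
                                             sbp = "rcs4"))
  expect_identical(sel$terms[sort(names(sel$terms))],
                   sel_rev$terms[sort(names(sel_rev$terms))])
})

test_that("under a null truth, selection usually empties the model", {
  tc <- truth_of(cohort_spec())
  tc[] <- 0
  hits <- 0L
  for (s in 1:8) {
    coh <- generate_cohort(cohort_spec(n = 1500, seed = 600 + s,
                                       true_coefficients = tc))
    sel <- suppressWarnings(
      backward_select(coh, model_spec(sbp = "rcs4", hr = "rcs4",
                                      gcs = "linear")))
    if (length(sel$terms) == 0) hits <- hits + 1L
  }
  # each variable is retained with probability ~alpha = 0.2 under the null
  expect_gte(hits, 2L)
})
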