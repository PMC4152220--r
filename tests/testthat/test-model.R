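test_that("published shrinkage arithmetic reproduces the printed rows", {
  pub_before <- published_model(shrunk = FALSE)
  pub_after <- published_model(shrunk = TRUE)
  s <- pub_after$shrinkage
  expect_equal(s, 0.90)
  # SBP basis 3: 0.38 x 0.90 rounds to the printed 0.34
  expect_equal(round(s * pub_before$coefficients[["sbp_basis3"]], 2),
               pub_after$coefficients[["sbp_basis3"]])
  # HR basis 3: 0.22 x 0.90 rounds to the printed 0.20
  expect_equal(round(s * pub_before$coefficients[["hr_basis3"]], 2),
               pub_after$coefficients[["hr_basis3"]])
  # the GCS row does NOT survive naive rounding: -0.23 x 0.90 = -0.207,
  # which rounds to -0.21, not the printed -0.20 — the authors shrank
  # unrounded coefficients. Documented, not asserted as equality.
  expect_equal(round(s * pub_before$coefficients[["gcs"]], 2), -0.21)
  expect_equal(pub_after$coefficients[["gcs"]], -0.20)
})

test_that("linear predictor matches a step-by-step hand evaluation", {
  mod <- published_model(shrunk = FALSE)  # constant 2.21
  sbp <- 118; hr <- 88; gcs <- 15
  # independent evaluation through the truncated-power oracle
  ks_sbp <- c(80, 110, 121, 147); ks_hr <- c(70, 86, 92, 118)
  lp_hand <- 2.21 +
    (-0.02) * sbp +
    (-0.04) * oracle_rcs_term(sbp, ks_sbp, 1) +
    0.38 * oracle_rcs_term(sbp, ks_sbp, 2) +
    0.00 * hr +
    (-0.02) * oracle_rcs_term(hr, ks_hr, 1) +
    0.22 * oracle_rcs_term(hr, ks_hr, 2) +
    (-0.23) * gcs
  expect_equal(linear_predictor(mod, sbp, hr, gcs), lp_hand,
               tolerance = 1e-12)
  expect_equal(predict_probability(mod, sbp, hr, gcs), plogis(lp_hand))
  # a patient with normal vitals sits in the low-risk band of the
  # published cut-off scale (predicted risk ~1-2%)
  expect_lt(predict_probability(mod, sbp, hr, gcs), 0.05)
})

test_that("degenerate and directional scorer behaviour", {
  spec <- model_spec(sbp = "rcs4", hr = "rcs4", gcs = "linear")
  kn <- list(sbp = knot_set(c(80, 110, 121, 147), "sbp"),
             hr = knot_set(c(70, 86, 92, 118), "hr"))
  zero <- triage_model(spec, kn,
                       setNames(rep(0, 7), names(published_model()$coefficients)),
                       intercept = 1.5)
  expect_equal(linear_predictor(zero, c(80, 200), c(60, 150), c(3, 15)),
               c(1.5, 1.5))
  # lower GCS raises predicted risk (negative published coefficient)
  mod <- published_model(shrunk = FALSE)
  expect_lt(linear_predictor(mod, 118, 88, 15),
            linear_predictor(mod, 118, 88, 3))
  # missing inputs are refused: the scorer does not impute
  expect_error(linear_predictor(mod, NA, 88, 15), "does not impute")
  expect_error(linear_predictor(mod, 118, 88, 17), "\\[3, 15\\]")
  expect_warning(linear_predictor(mod, 300, 88, 15), "outside the plausible")
})

test_that("published model is monotone in GCS, non-monotone in SBP and HR", {
  mod <- published_model(shrunk = FALSE)
  # GCS: probability strictly decreasing everywhere
  for (sbp in c(80, 118, 160)) {
    p <- predict_probability(mod, sbp, 88, 3:15)
    expect_true(all(diff(p) < 0))
  }
  # SBP: J/U-shaped response — find grid points violating monotone order
  p_sbp <- suppressWarnings(predict_probability(mod, seq(60, 220, 5), 88, 15))
  expect_true(any(diff(p_sbp) < 0) && any(diff(p_sbp) > 0))
  p_hr <- suppressWarnings(predict_probability(mod, 118, seq(40, 200, 5), 15))
  expect_true(any(diff(p_hr) < 0) && any(diff(p_hr) > 0))
})

test_that("shrunk published model ranks but refuses probabilities", {
  mod <- published_model(shrunk = TRUE)
  expect_true(is.na(mod$intercept))
  lp <- linear_predictor(mod, c(118, 80), c(88, 130), c(15, 6))
  expect_gt(lp[2], lp[1])
  expect_error(predict_probability(mod, 118, 88, 15), "no intercept")
  # user-supplied re-estimated constant enables probabilities
  mod2 <- published_model(shrunk = TRUE, intercept = 1.8)
  expect_true(predict_probability(mod2, 118, 88, 15) > 0)
  # complete-case knot fixture
  cc <- published_model(shrunk = FALSE, knots = "complete_case")
  expect_equal(cc$knots$sbp$locations, c(80, 110, 122, 149))
  expect_equal(cc$knots$hr$locations, c(70, 85, 92, 119))
})

test_that("batch scoring is vectorised, deterministic and JSON-stable", {
  mod <- published_model(shrunk = FALSE)
  set.seed(7)
  nd <- data.frame(sbp = runif(1000, 60, 200), hr = runif(1000, 50, 180),
                   gcs = sample(3:15, 1000, TRUE))
  p1 <- predict(mod, nd, type = "response")
  p2 <- vapply(seq_len(nrow(nd)), function(i)
    predict_probability(mod, nd$sbp[i], nd$hr[i], nd$gcs[i]), numeric(1))
  expect_equal(p1, p2, tolerance = 1e-14)
  expect_identical(p1, predict(mod, nd, type = "response"))
  expect_true(all(p1 > 0 & p1 < 1))
  # probabilities strictly increasing in the linear predictor
  lp <- predict(mod, nd, type = "link")
  expect_true(all(diff(p1[order(lp)]) >= 0))

  path <- withr::local_tempfile(fileext = ".json")
  write_model(mod, path)
  back <- read_model(path)
  expect_equal(back$coefficients, mod$coefficients)
  expect_equal(back$intercept, mod$intercept)
  expect_equal(back$knots$sbp$locations, mod$knots$sbp$locations)
  expect_identical(predict(back, nd, type = "response"), p1)

  # NA intercept survives the round trip
  shr <- published_model(shrunk = TRUE)
  write_model(shr, path)
  expect_true(is.na(read_model(path)$intercept))
})

test_that("risk heatmap evaluates the grid and respects GCS direction", {
  mod <- published_model(shrunk = FALSE)
  hm <- risk_heatmap(mod, sbp_grid = c(80, 120), gcs_grid = c(3, 9, 15),
                     hr_fixed = 88)
  expect_equal(dim(hm), c(2, 3))
  expect_equal(hm[1, 1], predict_probability(mod, 80, 88, 3))
  # probabilities fall as GCS rises, at every SBP
  expect_true(all(apply(unclass(hm), 1, diff) < 0))
  # 1x1 grid equals a single prediction
  hm1 <- risk_heatmap(mod, 118, 15, 88)
  expect_equal(as.numeric(hm1), predict_probability(mod, 118, 88, 15))
  expect_identical(unclass(hm), unclass(risk_heatmap(mod, c(80, 120),
                                                     c(3, 9, 15), 88)))
})
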