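# Shared fixtures: tiny cohorts built in code.

toy_cohort_df <- function(n = 6) {
  data.frame(
    hospital_id = rep(c("A", "B"), length.out = n),
    age = seq(20, 20 + 5 * (n - 1), by = 5),
    sex = rep(c("male", "female"), length.out = n),
    tti_hours = rep(c(2.5, 10), length.out = n),
    transferred = rep(c(TRUE, FALSE), length.out = n),
    mechanism = rep(c("fall", "road_traffic", "assault"), length.out = n),
    sbp = seq(90, 90 + 8 * (n - 1), by = 8),
    hr = seq(70, 70 + 6 * (n - 1), by = 6),
    gcs = rep(c(15, 12, 3), length.out = n),
    died_24h = rep(c(FALSE, FALSE, TRUE), length.out = n),
    discharged_early = FALSE,
    stringsAsFactors = FALSE)
}

# Independent term-by-term evaluation of the restricted cubic spline
# formula (kept deliberately separate from rcs_basis): basis j+1 combines
# truncated cubes with boundary corrections, scaled by the squared span.
oracle_rcs_term <- function(x, k, j) {
  n <- length(k)
  cube <- function(u) ifelse(u > 0, u^3, 0)
  (cube(x - k[j]) -
     cube(x - k[n - 1]) * (k[n] - k[j]) / (k[n] - k[n - 1]) +
     cube(x - k[n]) * (k[n - 1] - k[j]) / (k[n] - k[n - 1])) / (k[n] - k[1])^2
}

# A small cohort with MAR missingness for imputation tests.
small_missing_cohort <- function(n = 600, seed = 7) {
  spec <- cohort_spec(n = n, seed = seed)
  impose_missingness(generate_cohort(spec), spec)
}
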