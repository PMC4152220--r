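# The deployable final model: frozen knots, (shrunk) coefficients, and a
# re-estimated intercept; plus the published model as a ready-made fixture.

#' Construct a deployable triage model
#'
#' A `triage_model` freezes one knot set per spline variable together with
#' the coefficient vector (named by design column, e.g. `sbp_basis1`),
#' an intercept, the shrinkage factor that was applied, and a provenance
#' tag. `intercept = NA` is legal (the published after-shrinkage constant
#' was never printed); such a model can rank patients via linear
#' predictors but refuses to emit absolute probabilities.
#'
#' @param spec A [model_spec()] giving each variable's functional form.
#' @param knots Named list of `knot_set`s for the spline variables.
#' @param coefficients Named coefficient vector (no intercept).
#' @param intercept Scalar intercept, or `NA`.
#' @param shrinkage Shrinkage factor applied to the coefficients.
#' @param provenance `"fitted"`, `"published"` or `"synthetic"`.
#' @return An object of class `triage_model`.
#' @export
triage_model <- function(spec, knots, coefficients, intercept = NA_real_,
                         shrinkage = 1, provenance = "fitted") {
  expected <- 0L
  for (v in names(spec$terms)) {
    expected <- expected + if (spec$terms[[v]] == "linear") 1L else
      .spec_knot_count(spec$terms[[v]]) - 1L
  }
  if (length(spec$extras) == 0 && length(coefficients) != expected) {
    stop("coefficient count (", length(coefficients),
         ") does not match the spec (expected ", expected, ")", call. = FALSE)
  }
  structure(list(spec = spec, knots = knots,
                 coefficients = coefficients, intercept = intercept,
                 shrinkage = shrinkage, provenance = provenance),
            class = "triage_model")
}

#' The published final model
#'
#' The derivation study's final model: four-knot restricted cubic splines
#' for systolic blood pressure and heart rate, a linear Glasgow coma scale
#' term. Knots default to the published median-across-imputations
#' locations (SBP 80/110/121/147, HR 70/86/92/118); the complete-case
#' alternative (SBP 80/110/122/149, HR 70/85/92/119) is available via
#' `knots = "complete_case"`.
#'
#' Two modes: `shrunk = FALSE` returns the before-shrinkage coefficients
#' with the published constant 2.21, usable for absolute probabilities;
#' `shrunk = TRUE` returns the after-shrinkage coefficients whose constant
#' was published as NA — such a model scores linear predictors (rankings)
#' only, unless a re-estimated `intercept` is supplied by the user.
#'
#' @param shrunk Use the after-shrinkage coefficient column.
#' @param knots `"median"` or `"complete_case"`.
#' @param intercept Optional user-supplied intercept for the shrunk mode.
#' @return A `triage_model` with provenance `"published"`.
#' @export
published_model <- function(shrunk = TRUE, knots = c("median", "complete_case"),
                            intercept = NULL) {
  knots <- match.arg(knots)
  kn <- if (knots == "median") {
    list(sbp = knot_set(c(80, 110, 121, 147), "sbp", c(5, 35, 65, 95)),
         hr = knot_set(c(70, 86, 92, 118), "hr", c(5, 35, 65, 95)))
  } else {
    list(sbp = knot_set(c(80, 110, 122, 149), "sbp", c(5, 35, 65, 95)),
         hr = knot_set(c(70, 85, 92, 119), "hr", c(5, 35, 65, 95)))
  }
  before <- c(sbp_basis1 = -0.02, sbp_basis2 = -0.04, sbp_basis3 = 0.38,
              hr_basis1 = 0.00, hr_basis2 = -0.02, hr_basis3 = 0.22,
              gcs = -0.23)
  after <- c(sbp_basis1 = -0.02, sbp_basis2 = -0.04, sbp_basis3 = 0.34,
             hr_basis1 = 0.00, hr_basis2 = -0.02, hr_basis3 = 0.20,
             gcs = -0.20)
  b0 <- if (shrunk) {
    if (is.null(intercept)) NA_real_ else intercept
  } else 2.21
  triage_model(model_spec(sbp = "rcs4", hr = "rcs4", gcs = "linear"),
               knots = kn,
               coefficients = if (shrunk) after else before,
               intercept = b0,
               shrinkage = if (shrunk) 0.90 else 1,
               provenance = "published")
}

#' Linear predictor of a triage model
#'
#' Intercept plus the coefficient-weighted spline/linear design evaluated
#' at the model's frozen knots. The scorer does not impute: missing inputs
#' are an error. Values outside clinical plausibility ranges (SBP 40-250
#' mmHg, HR 20-220 bpm) are scored — splines are linear beyond the
#' boundary knots — but flagged with a warning.
#'
#' @param model A `triage_model`.
#' @param sbp,hr,gcs Vital-sign vectors (recycled to a common length).
#' @return Numeric linear predictor (log-odds). If the intercept is `NA`,
#'   the intercept-free linear predictor is returned with a warning
#'   attribute-free; use it for ranking only.
#' @export
linear_predictor <- function(model, sbp, hr, gcs) {
  n <- max(length(sbp), length(hr), length(gcs))
  df <- data.frame(sbp = rep_len(sbp, n), hr = rep_len(hr, n),
                   gcs = rep_len(gcs, n))
  .score(model, df)
}

.score <- function(model, newdata) {
  need <- c(names(model$spec$terms), model$spec$extras)
  for (v in intersect(need, c("sbp", "hr", "gcs", "age"))) {
    if (!v %in% names(newdata)) stop("newdata lacks '", v, "'", call. = FALSE)
    if (anyNA(newdata[[v]])) {
      stop("missing values in '", v, "': the scorer does not impute",
           call. = FALSE)
    }
  }
  if ("gcs" %in% need && any(newdata$gcs < 3 | newdata$gcs > 15)) {
    stop("gcs must lie in [3, 15]", call. = FALSE)
  }
  ranges <- list(sbp = c(40, 250), hr = c(20, 220))
  for (v in intersect(need, names(ranges))) {
    out <- newdata[[v]] < ranges[[v]][1] | newdata[[v]] > ranges[[v]][2]
    if (any(out)) {
      warning(sum(out), " value(s) of ", v,
              " outside the plausible range ", ranges[[v]][1], "-",
              ranges[[v]][2], "; scored by linear extrapolation",
              call. = FALSE)
    }
  }
  d <- .build_design(newdata, model$spec, knots = model$knots)
  cf <- model$coefficients
  miss <- setdiff(names(cf), colnames(d$X))
  if (length(miss) > 0) {
    stop("design lacks coefficient column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lp <- drop(d$X[, names(cf), drop = FALSE] %*% cf)
  if (!is.na(model$intercept)) lp <- lp + model$intercept
  lp
}

#' Predicted probability of early mortality
#'
#' Inverse logit of [linear_predictor()]. Requires a model with a known
#' intercept; the published shrunk model has none and errors here.
#'
#' @inheritParams linear_predictor
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(model, sbp, hr, gcs) {
  if (is.na(model$intercept)) {
    stop("model has no intercept (the published shrunk constant was not ",
         "printed); supply one via published_model(intercept=) or use ",
         "linear predictors for ranking", call. = FALSE)
  }
  stats::plogis(linear_predictor(model, sbp, hr, gcs))
}

#' @export
predict.triage_model <- function(object, newdata,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  lp <- .score(object, newdata)
  if (type == "link") return(lp)
  if (is.na(object$intercept)) {
    stop("model has no intercept; use type = \"link\"", call. = FALSE)
  }
  stats::plogis(lp)
}

#' @export
coef.triage_model <- function(object, ...) {
  c("(Intercept)" = unname(object$intercept), object$coefficients)
}

#' @export
print.triage_model <- function(x, ...) {
  cat("Triage model (", x$provenance, "), shrinkage factor ",
      format(x$shrinkage), "\n", sep = "")
  for (v in names(x$knots)) {
    cat("  knots ", v, ": ", paste(signif(x$knots[[v]]$locations, 6),
                                   collapse = ", "), "\n", sep = "")
  }
  cat("  intercept:", if (is.na(x$intercept)) "NA (ranking only)" else
    format(round(x$intercept, 4)), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Risk heatmap over a systolic blood pressure by GCS grid
#'
#' Evaluates predicted mortality probability on a grid of SBP and GCS at a
#' fixed heart rate (ignored by models without an HR term, such as the
#' reduced model the heatmap was designed for).
#'
#' @param model A `triage_model` with a known intercept.
#' @param sbp_grid,gcs_grid Grid values.
#' @param hr_fixed Heart rate at which to evaluate (if the model uses HR).
#' @return Matrix of probabilities, rows = `sbp_grid`, cols = `gcs_grid`,
#'   class `risk_heatmap`.
#' @export
risk_heatmap <- function(model, sbp_grid = seq(60, 200, by = 5),
                         gcs_grid = 3:15, hr_fixed = 88) {
  grid <- expand.grid(sbp = sbp_grid, gcs = gcs_grid)
  grid$hr <- hr_fixed
  p <- suppressWarnings(predict(model, grid, type = "response"))
  out <- matrix(p, nrow = length(sbp_grid),
                dimnames = list(sbp = sbp_grid, gcs = gcs_grid))
  class(out) <- c("risk_heatmap", class(out))
  out
}

#' @export
plot.risk_heatmap <- function(x, ...) {
  sbp <- as.numeric(rownames(x)); gcs <- as.numeric(colnames(x))
  graphics::image(sbp, gcs, unclass(x),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "Systolic blood pressure (mmHg)",
                  ylab = "Glasgow coma scale",
                  main = "Predicted probability of 24-h mortality", ...)
  invisible(x)
}

#' Save / load a triage model as JSON
#'
#' Round-trips knots, coefficients, intercept, shrinkage and provenance.
#'
#' @param model A `triage_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored model.
#' @export
write_model <- function(model, path) {
  obj <- list(
    terms = as.list(model$spec$terms), extras = model$spec$extras,
    knots = lapply(model$knots, function(k)
      list(variable = k$variable, locations = k$locations,
           percentiles = k$percentiles)),
    coefficients = as.list(model$coefficients),
    intercept = model$intercept, shrinkage = model$shrinkage,
    provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(model_spec, c(as.list(unlist(obj$terms)),
                                list(extras = obj$extras %||% character(0))))
  kn <- lapply(obj$knots, function(k)
    knot_set(k$locations, k$variable, k$percentiles))
  triage_model(spec, kn, unlist(obj$coefficients),
               intercept = if (is.null(obj$intercept)) NA_real_ else
                 obj$intercept,
               shrinkage = obj$shrinkage, provenance = obj$provenance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
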