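#' Percentile schedule for restricted cubic spline knots
#'
#' Knots are placed at equally spaced percentiles between the 5th and the
#' 95th, the convention of Harrell and of Stata's \code{mkspline, cubic}.
#' Four knots therefore sit at the 5th, 35th, 65th and 95th percentiles.
#'
#' @param n_knots Number of knots; one of 3, 4 or 5.
#' @return Numeric vector of percentiles (0-100 scale), length `n_knots`.
#' @examples
#' knot_percentiles(4)  # 5 35 65 95
#' @export
knot_percentiles <- function(n_knots) {
  if (!is.numeric(n_knots) || length(n_knots) != 1L || !n_knots %in% c(3, 4, 5)) {
    stop("`n_knots` must be 3, 4 or 5", call. = FALSE)
  }
  seq(5, 95, length.out = n_knots)
}

#' Place spline knots at empirical percentiles
#'
#' Computes knot locations as linear-interpolation empirical percentiles
#' (quantile type 7) of the observed values at the schedule returned by
#' [knot_percentiles()]. Note that percentile dialects differ between
#' software packages; this is the interpolation rule used by R's default
#' `quantile()`.
#'
#' @param values Numeric vector (missing values dropped).
#' @param n_knots Number of knots (3, 4 or 5).
#' @param variable Optional variable name carried along for messages.
#' @return An object of class `knot_set`: list with `variable`, `locations`
#'   (strictly increasing numeric) and `percentiles`.
#' @export
place_knots <- function(values, n_knots = 4, variable = "x") {
  values <- values[!is.na(values)]
  pct <- knot_percentiles(n_knots)
  if (length(unique(values)) < n_knots) {
    stop("fewer than ", n_knots, " distinct values for '", variable, "'",
         call. = FALSE)
  }
  loc <- unname(stats::quantile(values, pct / 100, type = 7))
  if (any(diff(loc) <= 0)) {
    stop("degenerate knots for '", variable,
         "': ties collapse the percentile schedule", call. = FALSE)
  }
  knot_set(loc, variable = variable, percentiles = pct)
}

#' Construct a knot set from explicit locations
#'
#' @param locations Strictly increasing numeric vector, length >= 3.
#' @param variable Variable name.
#' @param percentiles Optional percentile schedule the locations came from.
#' @return A `knot_set` object.
#' @export
knot_set <- function(locations, variable = "x", percentiles = NULL) {
  locations <- as.numeric(locations)
  if (length(locations) < 3 || any(diff(locations) <= 0)) {
    stop("knot locations must be strictly increasing with length >= 3",
         call. = FALSE)
  }
  structure(list(variable = variable, locations = locations,
                 percentiles = percentiles),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat("Knots for", x$variable, ":", paste(signif(x$locations, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Restricted cubic spline basis matrix
#'
#' Builds the truncated-power restricted cubic spline basis in the
#' parameterisation of Stata's \code{mkspline, cubic}: with knots
#' \eqn{k_1 < \dots < k_n}, the first basis function is the variable itself
#' and, for \eqn{j = 1, \dots, n-2},
#' \deqn{B_{j+1}(x) = \frac{(x-k_j)_+^3 -
#'   (x-k_{n-1})_+^3 \frac{k_n-k_j}{k_n-k_{n-1}} +
#'   (x-k_n)_+^3 \frac{k_{n-1}-k_j}{k_n-k_{n-1}}}{(k_n-k_1)^2}.}
#' The resulting spline is linear below the first and above the last knot
#' and has continuous value, first and second derivatives everywhere.
#'
#' @param values Numeric vector; missing values propagate as `NA` rows.
#' @param knots A `knot_set` or a strictly increasing numeric vector.
#' @return Numeric matrix with `length(knots) - 1` columns named
#'   `basis1, basis2, ...`; attribute `knots` holds the `knot_set`.
#' @export
rcs_basis <- function(values, knots) {
  if (!inherits(knots, "knot_set")) knots <- knot_set(knots)
  k <- knots$locations
  n <- length(k)
  x <- as.numeric(values)
  out <- matrix(NA_real_, length(x), n - 1L,
                dimnames = list(NULL, paste0("basis", seq_len(n - 1L))))
  out[, 1L] <- x
  pos3 <- function(u) pmax(u, 0)^3
  denom <- (k[n] - k[1])^2
  for (j in seq_len(n - 2L)) {
    out[, j + 1L] <- (pos3(x - k[j]) -
                        pos3(x - k[n - 1L]) * (k[n] - k[j]) / (k[n] - k[n - 1L]) +
                        pos3(x - k[n]) * (k[n - 1L] - k[j]) / (k[n] - k[n - 1L])) /
      denom
  }
  attr(out, "knots") <- knots
  out
}
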