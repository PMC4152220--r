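#' @keywords internal
"_PACKAGE"

# Canonical cohort schema. One row per admitted trauma patient.
.cohort_columns <- c("hospital_id", "age", "sex", "tti_hours", "transferred",
                     "mechanism", "sbp", "hr", "gcs", "died_24h",
                     "discharged_early")

.mechanism_levels <- c("fall", "railway", "road_traffic", "assault", "burn",
                       "other", "unknown")

#' Validate and normalise a cohort data frame
#'
#' Enforces the patient-record invariants: age >= 15, GCS an integer in
#' [3, 15] when observed, strictly positive vital signs, non-negative time
#' to arrival, and that death within 24 hours and early live discharge are
#' never both recorded for the same patient.
#'
#' @param data A data frame with the canonical columns (see [read_cohort()]).
#' @param provenance Free-text provenance tag, e.g. `"synthetic"` or `"file"`.
#' @return The validated data frame, with class `trauma_cohort` prepended,
#'   `sex`/`mechanism` as lowercase factors and logical flag columns.
#' @export
as_cohort <- function(data, provenance = "file") {
  missing_cols <- setdiff(.cohort_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(data) == 0) stop("cohort has zero rows", call. = FALSE)
  data <- as.data.frame(data)[, .cohort_columns]
  data$hospital_id <- factor(data$hospital_id)
  data$sex <- factor(tolower(as.character(data$sex)), levels = c("male", "female"))
  data$mechanism <- factor(tolower(as.character(data$mechanism)),
                           levels = .mechanism_levels)
  for (col in c("transferred", "died_24h", "discharged_early")) {
    data[[col]] <- .as_flag(data[[col]], col)
  }
  for (col in c("age", "tti_hours", "sbp", "hr", "gcs")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  .check_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      stop("invalid ", what, " in row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
    }
  }
  .check_rows(data$age < 15, "age (must be >= 15)")
  .check_rows(!is.na(data$gcs) & (data$gcs < 3 | data$gcs > 15 |
                                    data$gcs != round(data$gcs)),
              "gcs (integer in [3, 15])")
  .check_rows(data$sbp <= 0, "sbp (must be positive)")
  .check_rows(data$hr <= 0, "hr (must be positive)")
  .check_rows(data$tti_hours < 0, "tti_hours (must be non-negative)")
  .check_rows(data$died_24h & data$discharged_early,
              "outcome (died_24h and discharged_early both true)")
  .check_rows(is.na(data$died_24h), "died_24h (must be known)")
  attr(data, "provenance") <- provenance
  class(data) <- c("trauma_cohort", "data.frame")
  data
}

.as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (any(is.na(out) & !is.na(x) & nzchar(x))) {
    stop("column '", name, "' contains values not interpretable as logical",
         call. = FALSE)
  }
  out
}

#' Read a patient-level cohort CSV
#'
#' Reads an RFC 4180 CSV with a header row, one row per patient, maps
#' foreign column names onto the canonical schema and validates the result.
#' Unparseable numeric cells become missing with a warning reporting the
#' count.
#'
#' @param path Path to the CSV file.
#' @param schema_map Named character vector mapping canonical names to the
#'   file's column names, e.g. `c(sbp = "SBP_mmHg")`. Unmapped canonical
#'   names are assumed to appear verbatim in the file.
#' @param na_strings Strings treated as missing (besides empty cells).
#' @return A `trauma_cohort` data frame (see [as_cohort()]).
#' @export
read_cohort <- function(path, schema_map = NULL,
                        na_strings = c("", "NA", ".", "na")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = na_strings, check.names = FALSE)
  if (nrow(raw) == 0) stop("empty input: ", path, call. = FALSE)
  if (!is.null(schema_map)) {
    for (canon in names(schema_map)) {
      src <- schema_map[[canon]]
      if (!src %in% names(raw)) {
        stop("schema_map column '", src, "' not present in file", call. = FALSE)
      }
      raw[[canon]] <- raw[[src]]
    }
  }
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n_bad <- 0L
  for (col in c("age", "tti_hours", "sbp", "hr", "gcs")) {
    was_na <- is.na(raw[[col]])
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    n_bad <- n_bad + sum(is.na(parsed) & !was_na)
    raw[[col]] <- parsed
  }
  if (n_bad > 0) {
    warning(n_bad, " unparseable numeric cell(s) set to missing", call. = FALSE)
  }
  as_cohort(raw, provenance = "file")
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] up to floating-point formatting: missing
#' values are written as empty cells.
#'
#' @param cohort A `trauma_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Outcome recodings
#'
#' `primary_outcome()` implements the primary-analysis rule: a patient
#' discharged alive before 24 hours is considered alive at 24 hours, so the
#' outcome is simply the recorded death flag. `worst_case_outcome()`
#' implements the worst-case sensitivity recoding in which every patient
#' discharged alive before 24 hours is counted as dead at 24 hours.
#'
#' @param cohort A `trauma_cohort` (or any data frame with `died_24h` and
#'   `discharged_early` logical columns).
#' @return Logical vector, one element per patient.
#' @export
primary_outcome <- function(cohort) {
  as.logical(cohort$died_24h)
}

#' @rdname primary_outcome
#' @export
worst_case_outcome <- function(cohort) {
  as.logical(cohort$died_24h) | as.logical(cohort$discharged_early)
}

#' Events-per-parameter sample-size rule
#'
#' Minimum number of outcome events required for a model with the given
#' number of free parameters, at ten events per free parameter. Three vital
#' signs each represented by three variables (a four-knot restricted cubic
#' spline) give nine parameters and hence 90 required events.
#'
#' @param n_free_parameters Positive integer count of free parameters.
#' @return `10 * n_free_parameters`.
#' @examples
#' required_events(9)  # 90
#' @export
required_events <- function(n_free_parameters) {
  if (!is.numeric(n_free_parameters) || length(n_free_parameters) != 1L ||
      is.na(n_free_parameters) || n_free_parameters < 1 ||
      n_free_parameters != round(n_free_parameters)) {
    stop("`n_free_parameters` must be a positive integer", call. = FALSE)
  }
  as.integer(10L * n_free_parameters)
}

#' @export
print.trauma_cohort <- function(x, ...) {
  y <- primary_outcome(x)
  cat("Trauma cohort:", nrow(x), "patients,",
      sum(y), sprintf("deaths within 24 h (%.1f%%),", 100 * mean(y)),
      nlevels(x$hospital_id), "hospital(s)\n")
  miss <- vapply(x[c("sbp", "hr", "gcs", "tti_hours")],
                 function(v) mean(is.na(v)), numeric(1))
  if (any(miss > 0)) {
    cat("Missing:", paste(sprintf("%s %.0f%%", names(miss), 100 * miss),
                          collapse = ", "), "\n")
  }
  invisible(x)
}
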