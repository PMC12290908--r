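#' Age-indexed annual rate table
#'
#' The basic container for age-specific annual event probabilities
#' (breast-cancer incidence, all-cause mortality, population utility norms).
#' A rate table is an ordinary tibble with columns `age` (integer years,
#' contiguous ascending) and `value` (a per-person annual probability, or a
#' utility in the norms case), so it pipes straight into dplyr verbs.
#'
#' @param age Integer vector of ages (years), contiguous ascending.
#' @param value Numeric vector of annual probabilities (or utilities), one per
#'   age, each in \[0, 1\].
#' @return A tibble with columns `age` and `value`, validated.
#' @examples
#' age_rate_table(20:79, rep(0.001, 60))
#' @export
age_rate_table <- function(age, value) {
  out <- tibble::tibble(age = as.integer(age), value = as.numeric(value))
  validate_age_rate_table(out)
}

#' Validate an age rate table
#'
#' Checks the rate-table invariants: an `age` column of contiguous ascending
#' integer years, a `value` column with every entry in \[0, 1\], no missing
#' values. Errors (class `rrmcea_validation_error`) on violation.
#'
#' @param tbl A data frame with columns `age` and `value`.
#' @param what Label used in error messages.
#' @return `tbl`, invisibly usable, as a tibble.
#' @export
validate_age_rate_table <- function(tbl, what = "age rate table") {
  if (!all(c("age", "value") %in% names(tbl))) {
    abort_rrmcea(sprintf("%s must have columns 'age' and 'value'", what),
                 "rrmcea_validation_error")
  }
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0 || anyNA(tbl$age) || anyNA(tbl$value)) {
    abort_rrmcea(sprintf("%s must be non-empty with no missing values", what),
                 "rrmcea_validation_error")
  }
  if (any(diff(tbl$age) != 1L)) {
    abort_rrmcea(sprintf("%s ages must be contiguous ascending (step 1)", what),
                 "rrmcea_validation_error")
  }
  if (any(tbl$value < 0 | tbl$value > 1 | !is.finite(tbl$value))) {
    abort_rrmcea(sprintf("%s values must all lie in [0, 1]", what),
                 "rrmcea_validation_error")
  }
  tbl
}

# extract values for [start_age, end_age); error if not covered
rate_window <- function(tbl, start_age, end_age, what = "rate table") {
  ages <- seq.int(start_age, end_age - 1L)
  if (min(tbl$age) > start_age || max(tbl$age) < end_age - 1L) {
    abort_rrmcea(
      sprintf("%s covers [%d, %d] but [%d, %d) is required",
              what, min(tbl$age), max(tbl$age), start_age, end_age),
      "rrmcea_coverage_error"
    )
  }
  tbl$value[match(ages, tbl$age)]
}

#' Read / write an age rate table as CSV
#'
#' Two-column CSV (`age,value`) with header; validated on read.
#'
#' @param path File path.
#' @return `read_age_rate_table()` returns a validated rate-table tibble;
#'   `write_age_rate_table()` returns `tbl` invisibly.
#' @export
read_age_rate_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    age = readr::col_integer(), value = readr::col_double()
  ))
  tbl <- tibble::tibble(age = tbl$age, value = tbl$value)
  validate_age_rate_table(tbl, what = basename(path))
}

#' @rdname read_age_rate_table
#' @param tbl A validated rate table.
#' @export
write_age_rate_table <- function(tbl, path) {
  validate_age_rate_table(tbl)
  readr::write_csv(tbl, path)
  invisible(tbl)
}
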