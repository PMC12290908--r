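#' Round half away from zero
#'
#' Commercial rounding used for all reported integer counts and currency:
#' 0.5 always rounds away from zero (base [round()] rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half-away-from-zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# shared stage vocabulary, in diagnosis-severity order
bc_stages <- function() c("dcis", "stage1", "stage2", "stage3", "stage4")

abort_rrmcea <- function(msg, class) {
  rlang::abort(msg, class = c(class, "rrmcea_error"))
}

check_probability <- function(x, what, allow_zero = TRUE, allow_one = TRUE) {
  bad <- !is.finite(x) | x < 0 | x > 1 |
    (!allow_zero & x == 0) | (!allow_one & x == 1)
  if (any(bad)) {
    abort_rrmcea(
      sprintf("%s must be in %s0, 1%s; offending value: %s",
              what,
              if (allow_zero) "[" else "(",
              if (allow_one) "]" else ")",
              paste(utils::head(x[bad], 3), collapse = ", ")),
      "rrmcea_domain_error"
    )
  }
  invisible(x)
}
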