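#' Round half away from zero
#'
#' The staffing framework's rounding convention. Base [round()] rounds half to
#' even ("banker's rounding"), which disagrees with the framework's published
#' tables: 1750 referrals / 209 patients per FTE = 8.3732... must print as 8.37
#' and 8.37 FTE x 269 unique patients = 2251.53 must print as 2252. Half-way
#' cases round away from zero (for the non-negative quantities of this package,
#' up).
#'
#' A small guard (round to 6 decimals before taking the floor) absorbs binary
#' floating-point representation error in decimal products; e.g. `7.10 * 1175`
#' is stored as 8342.499999...96 but is exactly 8342.5 in decimal and must
#' round to 8343.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(8.3732, 2) # 8.37
#' round_half_up(2251.53) # 2252
#' round_half_up(7.10 * 1175) # 8343, not 8342
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  z <- round(x * p, 6)
  sign(z) * floor(abs(z) + 0.5) / p
}

# floor with a representation guard: values within 5e-10 of an integer are
# treated as that integer (0.2 * 280 or 60 * (0.70/0.75) land just off 56)
guarded_floor <- function(x) {
  floor(round(x, 9))
}

# shared validation helpers -------------------------------------------------

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", field),
      class = "psocap_validation_error"
    )
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %s violates bound %s%s, %s%s.",
      field, format(x),
      if (closed_lower) "[" else "(", format(lower),
      format(upper), if (closed_upper) "]" else ")"
    ), class = "psocap_validation_error")
  }
  invisible(x)
}

check_string <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single string.", field),
      class = "psocap_validation_error"
    )
  }
  invisible(x)
}
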