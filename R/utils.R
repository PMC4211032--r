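payer_levels <- c("health_system", "patient", "external")
kind_levels <- c("fixed", "variable")

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "ambucea_validation_error")
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE,
                                max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number.", name)
  }
  if (strict_min && x <= min) {
    stop_validation("`%s` must be > %s (got %s).", name, min, x)
  }
  if (!strict_min && x < min) {
    stop_validation("`%s` must be >= %s (got %s).", name, min, x)
  }
  if (x > max) {
    stop_validation("`%s` must be <= %s (got %s).", name, max, x)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_scalar_number(x, name, min = 0, max = 1)
}

#' Round half away from zero
#'
#' Presentation-layer rounding for dollar tables. Base R's `round()` rounds
#' half to even; report tables here round halves away from zero so that,
#' e.g., $34.50 prints as $35.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0, whole dollars).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
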