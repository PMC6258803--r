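# Internal helpers shared across the package.

#' @keywords internal
validation_error <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(errorCondition(msg, class = c("bmissde_validation_error", "validationError")))
}

# Positivity check that names the offending argument in the error message.
check_positive <- function(x, name) {
  if (length(x) == 0L || !is.numeric(x)) {
    validation_error("'%s' must be a non-empty numeric vector", name)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    validation_error("'%s' contains missing or non-finite values", name)
  }
  if (any(x <= 0)) {
    validation_error("'%s' must be strictly positive (got %s)", name,
                     paste(format(x[x <= 0][1]), collapse = ", "))
  }
  invisible(x)
}

check_numeric <- function(x, name) {
  if (length(x) == 0L || !is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    validation_error("'%s' must be a finite numeric vector", name)
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Presentation rounding used when printing tables: ties go away from zero
#' (so 34.45 -> 34.5 at one decimal), unlike [base::round()]'s round-half-even.
#' Computation never rounds internally; this is applied at I/O boundaries only.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @export
#' @examples
#' round_half_up(34.45, 1)  # 34.5
#' round_half_up(-0.125, 2) # -0.13
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a few ulp so values that are exact halves in decimal but stored
  # just below (e.g. 0.285) still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
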