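# The anthropometric regression predicting effective diameter (cm) from BMI
# (kg/m^2). The shipped default line, D_E = 0.76 * BMI + 9.4, was fitted on
# an adult abdominal CT cohort whose BMI spanned 17.4-38.8 kg/m^2; outside
# that range predictions are extrapolations and are flagged as such.

#' BMI-to-effective-diameter regression line
#'
#' Constructs the affine map used to estimate a patient's effective diameter
#' from BMI. The default coefficients (slope 0.76 cm per kg/m^2, intercept
#' 9.4 cm) are those of the published abdominal regression; the validity
#' range records the BMI span of the cohort the line was fitted on.
#'
#' @param slope cm of effective diameter per unit BMI (> 0 for the default).
#' @param intercept cm.
#' @param valid_bmi_range length-2 numeric, the closed BMI interval over
#'   which the line was fitted; predictions outside it are flagged.
#' @return object of class `regression_line`.
#' @seealso [de_from_bmi()]
#' @export
regression_line <- function(slope = 0.76, intercept = 9.4,
                            valid_bmi_range = c(17.4, 38.8)) {
  check_numeric(slope, "slope")
  check_numeric(intercept, "intercept")
  if (length(valid_bmi_range) != 2L || diff(valid_bmi_range) <= 0) {
    validation_error("'valid_bmi_range' must be an increasing length-2 interval")
  }
  structure(list(slope = slope, intercept = intercept,
                 valid_bmi_range = as.numeric(valid_bmi_range)),
            class = "regression_line")
}

#' Effective diameter estimated from BMI
#'
#' Evaluates `slope * bmi + intercept`. Values are returned for any positive
#' BMI — the conversion table deliberately spans BMI 15-50, beyond the fitted
#' cohort — but BMIs outside the line's validity range raise a warning and
#' are marked in the `"extrapolated"` attribute of the result.
#'
#' @param bmi body mass index, kg/m^2 (> 0); vectorised.
#' @param line a [regression_line()].
#' @return estimated effective diameter in cm, with a logical attribute
#'   `extrapolated` of the same length.
#' @export
#' @examples
#' de_from_bmi(24.6)            # 28.096 cm
#' suppressWarnings(de_from_bmi(50))  # flagged as extrapolation
de_from_bmi <- function(bmi, line = regression_line()) {
  check_positive(bmi, "bmi")
  stopifnot(inherits(line, "regression_line"))
  d_e <- line$slope * bmi + line$intercept
  extrap <- bmi < line$valid_bmi_range[1] | bmi > line$valid_bmi_range[2]
  if (any(extrap)) {
    warning(sprintf(
      "%d BMI value(s) outside the regression's validity range [%.1f, %.1f]; extrapolating",
      sum(extrap), line$valid_bmi_range[1], line$valid_bmi_range[2]),
      call. = FALSE)
  }
  attr(d_e, "extrapolated") <- extrap
  d_e
}

#' @export
predict.regression_line <- function(object, bmi, ...) {
  de_from_bmi(bmi, object)
}

#' @export
coef.regression_line <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
print.regression_line <- function(x, ...) {
  cat(sprintf("D_E [cm] = %.4g * BMI + %.4g   (fitted for BMI in [%.1f, %.1f] kg/m^2)\n",
              x$slope, x$intercept, x$valid_bmi_range[1], x$valid_bmi_range[2]))
  invisible(x)
}
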