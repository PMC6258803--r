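# Body-size metrics: BMI, BMI categories, effective diameters and the
# outer/inner diameter ratio. All diameters are in centimetres, height in
# metres, weight in kilograms, BMI in kg/m^2. Functions are vectorised and
# reject non-positive input with a validation error naming the offending
# argument.

#' Body mass index from weight and height
#'
#' @param weight body weight in kilograms (> 0).
#' @param height standing height in metres (> 0).
#' @return BMI in kg/m^2, `weight / height^2`.
#' @export
#' @examples
#' compute_bmi(70, 1.75)
compute_bmi <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  weight / height^2
}

#' BMI category
#'
#' Classifies BMI into the four WHO adult categories with half-open,
#' lower-inclusive bins: underweight `[0, 18.5)`, normal `[18.5, 25)`,
#' overweight `[25, 30)`, obese `[30, Inf)`.
#'
#' @param bmi body mass index in kg/m^2 (> 0).
#' @return factor with levels `underweight`, `normal`, `overweight`, `obese`.
#' @export
#' @examples
#' bmi_category(c(18.4, 18.5, 25, 30))
bmi_category <- function(bmi) {
  check_positive(bmi, "bmi")
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese"))
}

#' Effective diameter
#'
#' The effective diameter is the diameter of the circle with the same
#' cross-sectional area as the patient at a given z-level, computed as the
#' geometric mean of the anteroposterior and lateral skin-to-skin diameters
#' measured on the CT localiser images:
#' \deqn{D_E = \sqrt{D_{AP} \times D_{LAT}}}
#'
#' @param d_ap anteroposterior skin-to-skin diameter, cm (> 0).
#' @param d_lat lateral skin-to-skin diameter, cm (> 0).
#' @return effective diameter in cm. Symmetric in its two arguments and
#'   always between `min(d_ap, d_lat)` and `max(d_ap, d_lat)`.
#' @seealso [inner_effective_diameter()], [diameter_ratio()]
#' @export
#' @examples
#' effective_diameter(24.8, 31.5)
effective_diameter <- function(d_ap, d_lat) {
  check_positive(d_ap, "d_ap")
  check_positive(d_lat, "d_lat")
  sqrt(d_ap * d_lat)
}

#' Inner effective diameter
#'
#' Geometric mean of the anteroposterior and lateral diameters measured on
#' the axial midslice image excluding the subcutaneous adipose tissue.
#' Same contract as [effective_diameter()].
#'
#' @param d_ap_in inner anteroposterior diameter, cm (> 0).
#' @param d_lat_in inner lateral diameter, cm (> 0).
#' @return inner effective diameter in cm.
#' @export
inner_effective_diameter <- function(d_ap_in, d_lat_in) {
  check_positive(d_ap_in, "d_ap_in")
  check_positive(d_lat_in, "d_lat_in")
  sqrt(d_ap_in * d_lat_in)
}

#' Outer-to-inner effective diameter ratio
#'
#' A body-fat-distribution metric: the ratio of the conventional (outer)
#' effective diameter to the inner effective diameter. The outer envelope
#' contains the inner one, so the ratio is always >= 1.
#'
#' @param d_out outer effective diameter, cm (> 0).
#' @param d_in inner effective diameter, cm (> 0, must not exceed `d_out`).
#' @return dimensionless ratio `d_out / d_in` (>= 1).
#' @export
#' @examples
#' diameter_ratio(27.79, 22.59)
diameter_ratio <- function(d_out, d_in) {
  check_positive(d_out, "d_out")
  check_positive(d_in, "d_in")
  if (any(d_in > d_out)) {
    validation_error("'d_in' must not exceed 'd_out': inner envelope cannot be larger than the outer one")
  }
  d_out / d_in
}

#' Anthropometrics for one patient
#'
#' Bundles the size measurements available for a single patient: BMI (given
#' directly or derived from height and weight) and, optionally, the measured
#' outer and inner skin-to-skin diameters. Invariants are checked on
#' construction: a supplied BMI must agree with `weight/height^2` when height
#' and weight are also present, and inner diameters may not exceed their
#' outer counterparts.
#'
#' @param bmi body mass index, kg/m^2 (optional if `height` and `weight` given).
#' @param height height in metres (optional).
#' @param weight weight in kilograms (optional).
#' @param d_ap,d_lat outer anteroposterior / lateral diameters, cm (optional).
#' @param d_ap_in,d_lat_in inner diameters, cm (optional).
#' @return an object of class `patient_size`.
#' @export
#' @examples
#' patient_size(height = 1.75, weight = 70, d_ap = 24, d_lat = 31)
patient_size <- function(bmi = NULL, height = NULL, weight = NULL,
                         d_ap = NULL, d_lat = NULL,
                         d_ap_in = NULL, d_lat_in = NULL) {
  if (!is.null(height)) check_positive(height, "height")
  if (!is.null(weight)) check_positive(weight, "weight")
  if (!is.null(height) && !is.null(weight)) {
    derived <- compute_bmi(weight, height)
    if (!is.null(bmi) && abs(bmi - derived) > 1e-9) {
      validation_error("supplied bmi (%.6f) disagrees with weight/height^2 (%.6f)",
                       bmi, derived)
    }
    bmi <- derived
  }
  if (is.null(bmi) && is.null(d_ap) && is.null(d_lat)) {
    validation_error("patient_size needs bmi, height+weight, or measured diameters")
  }
  if (!is.null(bmi)) check_positive(bmi, "bmi")
  for (nm in c("d_ap", "d_lat", "d_ap_in", "d_lat_in")) {
    v <- get(nm)
    if (!is.null(v)) check_positive(v, nm)
  }
  if (!is.null(d_ap_in) && !is.null(d_ap) && d_ap_in > d_ap) {
    validation_error("'d_ap_in' exceeds 'd_ap'")
  }
  if (!is.null(d_lat_in) && !is.null(d_lat) && d_lat_in > d_lat) {
    validation_error("'d_lat_in' exceeds 'd_lat'")
  }
  structure(list(bmi = bmi, height = height, weight = weight,
                 d_ap = d_ap, d_lat = d_lat,
                 d_ap_in = d_ap_in, d_lat_in = d_lat_in),
            class = "patient_size")
}

#' Derived diameters for one patient
#'
#' Computes whichever of the effective diameter, inner effective diameter and
#' diameter ratio the available measurements permit.
#'
#' @param ps a [patient_size()] object.
#' @return list with elements `d_e`, `d_in`, `d_ratio` (`NULL` when the
#'   underlying measurements are absent).
#' @export
derive_diameters <- function(ps) {
  stopifnot(inherits(ps, "patient_size"))
  d_e <- if (!is.null(ps$d_ap) && !is.null(ps$d_lat)) {
    effective_diameter(ps$d_ap, ps$d_lat)
  }
  d_in <- if (!is.null(ps$d_ap_in) && !is.null(ps$d_lat_in)) {
    inner_effective_diameter(ps$d_ap_in, ps$d_lat_in)
  }
  d_ratio <- if (!is.null(d_e) && !is.null(d_in)) diameter_ratio(d_e, d_in)
  list(d_e = d_e, d_in = d_in, d_ratio = d_ratio)
}

#' @export
print.patient_size <- function(x, ...) {
  cat("Patient size\n")
  if (!is.null(x$bmi)) cat(sprintf("  BMI: %.1f kg/m^2 (%s)\n", x$bmi,
                                   as.character(bmi_category(x$bmi))))
  if (!is.null(x$d_ap)) cat(sprintf("  D_AP: %.1f cm, D_LAT: %.1f cm\n", x$d_ap, x$d_lat))
  if (!is.null(x$d_ap_in)) cat(sprintf("  inner D_AP: %.1f cm, inner D_LAT: %.1f cm\n",
                                       x$d_ap_in, x$d_lat_in))
  invisible(x)
}
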