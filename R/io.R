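# Cohort CSV input/output. The schema is fixed: comma-separated, UTF-8,
# header row, '.' decimal separator, units frozen in the column names, and
# missing optional values written as empty fields.

#' Cohort CSV column schema
#'
#' @return character vector of the ordered column names every cohort CSV
#'   must carry.
#' @export
cohort_schema <- function() {
  c("id", "bmi", "bmi_category", "d_ap_cm", "d_lat_cm", "d_e_cm", "d_in_cm",
    "d_ratio", "ctdi_vol_mgy", "scan_length_cm", "dlp_mgycm",
    "conversion_factor", "ssde_mgy", "phantom_cm")
}

cohort_numeric_cols <- function() setdiff(cohort_schema(), "bmi_category")

#' Write a cohort to CSV
#'
#' Values are written at full precision (15 significant digits) so that a
#' write/read round trip is stable to at least 10 significant digits.
#'
#' @param cohort data.frame carrying the [cohort_schema()] columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!is.data.frame(cohort)) validation_error("'cohort' must be a data.frame")
  missing_cols <- setdiff(cohort_schema(), names(cohort))
  if (length(missing_cols)) {
    validation_error("cohort is missing schema column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  out <- cohort[cohort_schema()]
  for (v in cohort_numeric_cols()) {
    out[[v]] <- ifelse(is.na(out[[v]]), "", format(out[[v]], digits = 15,
                                                   trim = TRUE, scientific = FALSE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' Validates the header against [cohort_schema()]: missing mandatory columns
#' are a schema error listing every absent name; unknown extra columns are
#' kept but trigger a warning. Numeric fields that fail to parse raise an
#' error naming the first offending row; empty fields become `NA`.
#'
#' @param path CSV file path.
#' @return data.frame with the schema columns (plus any extras, warned about).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) validation_error("cohort file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_schema(), names(raw))
  if (length(missing_cols)) {
    validation_error("cohort file %s is missing mandatory column(s): %s",
                     path, paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), cohort_schema())
  if (length(extra)) {
    warning(sprintf("ignoring unknown column(s) in %s: %s", path,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  for (v in cohort_numeric_cols()) {
    txt <- raw[[v]]
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(!is.na(txt) & nzchar(txt) & is.na(val))
    if (length(bad)) {
      validation_error("column '%s' has unparseable value '%s' at data row %d of %s",
                       v, txt[bad[1]], bad[1], path)
    }
    raw[[v]] <- val
  }
  raw
}
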