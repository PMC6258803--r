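# Validation statistics: Pearson correlation with a two-tailed t-based
# p-value, ordinary least squares, Welch's two-sample comparison, and the
# cohort validation report that assembles them.

check_paired <- function(x, y) {
  check_numeric(x, "x")
  check_numeric(y, "y")
  if (length(x) != length(y)) {
    validation_error("'x' and 'y' must have equal length (%d vs %d)",
                     length(x), length(y))
  }
  if (length(x) < 3L) validation_error("need at least 3 paired observations, got %d", length(x))
}

#' Pearson correlation with two-tailed significance
#'
#' Product-moment correlation; the p-value comes from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), neither constant.
#' @return list of class `correlation_result` with `r`, `n`, `p_two_tailed`.
#' @export
#' @examples
#' pearson(1:10, (1:10) + rnorm(10))
pearson <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0) validation_error("'x' is constant; correlation undefined")
  if (stats::sd(y) == 0) validation_error("'y' is constant; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(x),
                 p_two_tailed = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, two-tailed p = %.3g)\n",
              x$r, x$n, x$p_two_tailed))
  invisible(x)
}

#' Ordinary least squares for one predictor
#'
#' @param x predictor (non-constant), `y` response; equal length, n >= 3.
#' @param y response.
#' @return list of class `ols_result` with `slope`, `intercept`, `r_squared`,
#'   `n` and `residuals`. The fitted line passes through the sample means and
#'   the residuals sum to zero.
#' @export
ols <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0) validation_error("'x' is constant; slope undefined")
  fit <- stats::lm(y ~ x)
  res <- unname(stats::residuals(fit))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 n = length(x),
                 residuals = res),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g * x + %.4g   (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Welch's unequal-variance two-sample comparison
#'
#' Chosen over the pooled-variance form because dose metrics in BMI-stratified
#' groups can have standard deviations differing several-fold.
#'
#' @param a,b numeric vectors, each with at least 2 observations.
#' @return list with `t`, `df` (Welch-Satterthwaite), `p_two_tailed`,
#'   `mean_a`, `mean_b`.
#' @export
welch_two_sample <- function(a, b) {
  check_numeric(a, "a")
  check_numeric(b, "b")
  if (length(a) < 2L || length(b) < 2L) {
    validation_error("each group needs at least 2 observations (got %d and %d)",
                     length(a), length(b))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_tailed = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

# variables summarised / correlated in the validation report
report_vars <- c("bmi", "d_ap_cm", "d_lat_cm", "d_e_cm", "d_ratio",
                 "ctdi_vol_mgy", "dlp_mgycm", "ssde_mgy")

#' Cohort validation report
#'
#' Re-runs the study-style analysis on a cohort (simulated or read from CSV):
#' per-variable mean and SD overall and stratified by BMI category, the full
#' pairwise Pearson correlation matrix with two-tailed p-values, an OLS refit
#' of effective diameter on BMI, and Welch comparisons of the dose metrics
#' between the BMI < 25 and BMI >= 25 groups. P-values are stored at full
#' precision; any truncation (e.g. printing "0.000") is presentation only.
#'
#' @param cohort data.frame with at least the columns `bmi`, `d_ap_cm`,
#'   `d_lat_cm`, `d_e_cm`, `d_ratio`, `ctdi_vol_mgy`, `dlp_mgycm`,
#'   `ssde_mgy`, e.g. from [generate_cohort()] or [read_cohort()].
#' @return object of class `validation_report`; serialise with
#'   [write_validation_report()].
#' @export
build_validation_report <- function(cohort) {
  if (!is.data.frame(cohort)) validation_error("'cohort' must be a data.frame")
  missing_cols <- setdiff(report_vars, names(cohort))
  if (length(missing_cols)) {
    validation_error("cohort is missing required column(s): %s",
                     paste(missing_cols, collapse = ", "))
  }
  cohort <- cohort[stats::complete.cases(cohort[report_vars]), , drop = FALSE]
  n <- nrow(cohort)
  if (n < 3L) validation_error("need at least 3 complete cohort rows, got %d", n)

  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  overall <- vapply(cohort[report_vars], msd, numeric(2))

  cat_f <- bmi_category(cohort$bmi)
  by_category <- lapply(split(cohort[report_vars], cat_f), function(d) {
    if (nrow(d) == 0L) return(NULL)
    list(n = nrow(d), summary = vapply(d, msd, numeric(2)))
  })

  m <- as.matrix(cohort[report_vars])
  k <- length(report_vars)
  r_mat <- diag(1, k); p_mat <- matrix(NA_real_, k, k); diag(p_mat) <- 0
  dimnames(r_mat) <- dimnames(p_mat) <- list(report_vars, report_vars)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      pr <- pearson(m[, i], m[, j])
      r_mat[i, j] <- r_mat[j, i] <- pr$r
      p_mat[i, j] <- p_mat[j, i] <- pr$p_two_tailed
    }
  }

  de_bmi_fit <- ols(cohort$bmi, cohort$d_e_cm)

  lo <- cohort$bmi < 25; hi <- !lo
  group_comparisons <- NULL
  if (sum(lo) >= 2L && sum(hi) >= 2L) {
    group_comparisons <- lapply(
      stats::setNames(nm = c("ctdi_vol_mgy", "dlp_mgycm", "ssde_mgy")),
      function(v) welch_two_sample(cohort[[v]][lo], cohort[[v]][hi]))
  }

  structure(list(n = n,
                 overall = overall,
                 by_category = by_category,
                 category_n = as.integer(table(cat_f)),
                 correlation = r_mat,
                 correlation_p = p_mat,
                 de_bmi_fit = de_bmi_fit,
                 group_comparisons = group_comparisons),
            class = "validation_report")
}

#' Serialise a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path file to write; the JSON is also returned invisibly as a string.
#' @return the JSON string, invisibly.
#' @export
write_validation_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "validation_report"))
  x <- unclass(report)
  x$de_bmi_fit <- x$de_bmi_fit[c("slope", "intercept", "r_squared", "n")]
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) writeLines(json, path)
  invisible(as.character(json))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Cohort validation report (n = %d)\n", x$n))
  cat("  mean +- SD:\n")
  for (v in colnames(x$overall)) {
    cat(sprintf("    %-13s %8.2f +- %.2f\n", v, x$overall["mean", v], x$overall["sd", v]))
  }
  cat(sprintf("  D_E ~ BMI refit: slope %.3f, intercept %.2f (R^2 = %.3f)\n",
              x$de_bmi_fit$slope, x$de_bmi_fit$intercept, x$de_bmi_fit$r_squared))
  cat(sprintf("  r(BMI, D_E) = %.3f\n", x$correlation["bmi", "d_e_cm"]))
  if (!is.null(x$group_comparisons)) {
    g <- x$group_comparisons$ctdi_vol_mgy
    cat(sprintf("  CTDIvol, BMI<25 vs >=25: %.2f vs %.2f mGy (Welch p = %.3g)\n",
                g$mean_a, g$mean_b, g$p_two_tailed))
  }
  invisible(x)
}
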