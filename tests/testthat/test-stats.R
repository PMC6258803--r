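test_that("pearson handles collinear, tabulated and degenerate input", {
  p <- pearson(1:10, 3 * (1:10))
  expect_equal(p$r, 1)
  expect_lt(p$p_two_tailed, 1e-12)
  tab <- ref_table()
  expect_gt(pearson(tab$bmi, tab$d_e_cm)$r, 0.9999)
  expect_error(pearson(rep(2, 5), 1:5), "constant", class = "bmissde_validation_error")
  expect_error(pearson(1:4, 1:5), "length", class = "bmissde_validation_error")
  expect_error(pearson(1:2, 2:3), class = "bmissde_validation_error")
})

test_that("pearson and ols agree with brute-force summation oracles", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 10, 3)
    y <- 1.5 * x + rnorm(n, 0, 2)
    p <- pearson(x, y); bp <- bf_pearson(x, y)
    expect_equal(p$r, bp$r, tolerance = 1e-12)
    expect_equal(p$p_two_tailed, bp$p, tolerance = 1e-9)
    o <- ols(x, y); bo <- bf_ols(x, y)
    expect_equal(o$slope, bo$slope, tolerance = 1e-12)
    expect_equal(o$intercept, bo$intercept, tolerance = 1e-12)
    expect_equal(o$r_squared, bo$r_squared, tolerance = 1e-12)
    # structural invariants of the least-squares fit
    expect_lt(abs(sum(o$residuals)) / max(abs(y)), 1e-9)
    expect_equal(o$slope * mean(x) + o$intercept, mean(y), tolerance = 1e-9)
  }
})

test_that("ols recovers exact lines and the published regression", {
  o <- ols(c(1, 2, 5, 9), 2 * c(1, 2, 5, 9) + 1)
  expect_equal(o$slope, 2)
  expect_equal(o$intercept, 1)
  expect_equal(o$r_squared, 1)
  tab <- ref_table()
  fit <- ols(tab$bmi, tab$d_e_cm)
  expect_equal(fit$slope, 0.76, tolerance = 0.005 / 0.76)
  expect_equal(fit$intercept, 9.4, tolerance = 0.05 / 9.4)
  expect_error(ols(1:2, 2:3), class = "bmissde_validation_error")
})

test_that("welch_two_sample matches the closed-form Welch statistic", {
  same <- c(1, 2, 3, 4)
  w0 <- welch_two_sample(same, same)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_two_tailed, 1)
  set.seed(32)
  a <- rnorm(30, 0, 1); b <- rnorm(30, 5, 1)
  w <- welch_two_sample(a, b)
  bw <- bf_welch(a, b)
  expect_equal(w$t, bw$t, tolerance = 1e-12)
  expect_equal(w$df, bw$df, tolerance = 1e-12)
  expect_equal(w$p_two_tailed, bw$p, tolerance = 1e-9)
  expect_lt(w$p_two_tailed, 1e-6)
  expect_error(welch_two_sample(1, c(1, 2)), class = "bmissde_validation_error")
})

test_that("validation report reproduces hand-computed summaries on tiny cohorts", {
  rows <- data.frame(bmi = c(20, 24, 30),
                     d_ap_cm = c(22, 25, 31), d_lat_cm = c(29, 31, 37),
                     d_e_cm = c(25.3, 27.8, 33.9), d_ratio = c(1.1, 1.2, 1.4),
                     ctdi_vol_mgy = c(4, 5, 11), dlp_mgycm = c(190, 238, 520),
                     ssde_mgy = c(5.8, 6.6, 12.1))
  rep <- build_validation_report(rows)
  expect_equal(rep$n, 3L)
  expect_equal(rep$overall["mean", "bmi"], mean(c(20, 24, 30)))
  expect_equal(rep$overall["sd", "ctdi_vol_mgy"], sd(c(4, 5, 11)))
  expect_equal(sum(rep$category_n), rep$n)
  expect_equal(rep$by_category$normal$n, 2L)
  expect_equal(rep$by_category$obese$summary["mean", "ssde_mgy"], 12.1)
  # correlation matrix: symmetric, unit diagonal
  expect_identical(rep$correlation, t(rep$correlation))
  expect_equal(unname(diag(rep$correlation)), rep(1, 8))
  # too few rows in one BMI group: no group comparison, no error
  expect_null(rep$group_comparisons)
})

test_that("validation report errors name missing columns and reject tiny cohorts", {
  co <- generate_cohort(cohort_params(n = 60, seed = 3))
  rep <- build_validation_report(co)
  expect_false(is.null(rep$group_comparisons))
  expect_lt(rep$group_comparisons$ctdi_vol_mgy$p_two_tailed, 0.05)
  co$ctdi_vol_mgy <- NULL
  expect_error(build_validation_report(co), "ctdi_vol_mgy",
               class = "bmissde_validation_error")
  expect_error(build_validation_report(data.frame()), class = "bmissde_validation_error")
})

test_that("validation report serialises to JSON with full-precision p-values", {
  co <- generate_cohort(cohort_params(n = 80, seed = 4))
  rep <- build_validation_report(co)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$n, rep$n)
  expect_equal(parsed$de_bmi_fit$slope, rep$de_bmi_fit$slope, tolerance = 1e-12)
  expect_true(is.numeric(parsed$correlation))
})
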