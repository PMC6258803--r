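test_that("de_from_bmi evaluates the regression and flags extrapolation", {
  d15_33 <- suppressWarnings(as.numeric(de_from_bmi(c(15, 33))))
  expect_equal(round_half_up(d15_33, 1), c(20.8, 34.5))
  d <- de_from_bmi(24.6)
  expect_equal(as.numeric(d), 0.76 * 24.6 + 9.4)
  expect_false(attr(d, "extrapolated"))
  expect_warning(de_from_bmi(50), "extrapolat")
  expect_true(attr(suppressWarnings(de_from_bmi(15)), "extrapolated"))
  expect_error(de_from_bmi(0), class = "bmissde_validation_error")
  expect_error(de_from_bmi(-3), class = "bmissde_validation_error")
  # affine: differences scale exactly with the slope
  line <- regression_line()
  b1 <- runif(20, 16, 45); b2 <- runif(20, 16, 45)
  d1 <- suppressWarnings(as.numeric(de_from_bmi(b1, line)))
  d2 <- suppressWarnings(as.numeric(de_from_bmi(b2, line)))
  expect_equal(d1 - d2, line$slope * (b1 - b2))
})

test_that("fit_conversion_model exactly recovers a known exponential", {
  d <- c(10, 20, 30)
  m <- fit_conversion_model(d, 2 * exp(-0.1 * d))
  expect_equal(m$a, 2, tolerance = 1e-9)
  expect_equal(m$b, 0.1, tolerance = 1e-9)
  expect_lt(m$calibration_residual_max, 1e-12)
})

test_that("fit_conversion_model validates its calibration rows", {
  expect_error(fit_conversion_model(c(10, 20), c(1, 0.5)), "3",
               class = "bmissde_validation_error")
  expect_error(fit_conversion_model(c(10, 10, 20), c(1, 1, 0.5)), "distinct",
               class = "bmissde_validation_error")
  expect_error(fit_conversion_model(c(10, 20, 30), c(1, -0.5, 0.2)),
               class = "bmissde_validation_error")
  expect_error(fit_conversion_model(c(10, 20, 30), c(1, 0.7, 0.5), phantom = 20),
               class = "bmissde_validation_error")
})

test_that("calibration to the packaged table matches the summation oracle", {
  tab <- ref_table()
  m <- fit_conversion_model(tab$d_e_cm, tab$conversion_factor)
  oracle <- bf_exp_fit(tab$d_e_cm, tab$conversion_factor)
  expect_equal(m$a, oracle$a, tolerance = 1e-10)
  expect_equal(m$b, oracle$b, tolerance = 1e-10)
  # frozen coefficients of the 32-cm calibration
  expect_equal(m$a, 3.6944, tolerance = 1e-4)
  expect_equal(m$b, 0.036626, tolerance = 1e-4)
  expect_lte(m$calibration_residual_max, 0.01)
})

test_that("conversion_factor reproduces printed factors and decreases monotonically", {
  # the refitted curve reproduces the printed factors within the 0.01
  # calibration tolerance (the BMI-15 row lands at 1.72 vs the printed 1.73)
  expect_lte(abs(conversion_factor(20.8) - 1.73), 0.01)
  expect_equal(round_half_up(conversion_factor(32.2), 2), 1.14)
  d <- seq(15, 55, by = 0.25)
  f <- conversion_factor(d)
  expect_true(all(diff(f) < 0))
  expect_error(conversion_factor(0), class = "bmissde_validation_error")
  # SSDE exceeds CTDIvol exactly for patients below the unit-factor diameter
  m <- default_conversion_model()
  d_unit <- log(m$a) / m$b
  expect_true(all((conversion_factor(d) > 1) == (d < d_unit)))
})

test_that("there is no fabricated 16-cm phantom calibration", {
  expect_error(default_conversion_model(16), "16-cm",
               class = "bmissde_validation_error")
  # but fitting one from user rows is allowed
  d <- c(10, 15, 20)
  m16 <- fit_conversion_model(d, 2.5 * exp(-0.05 * d), phantom = 16)
  expect_equal(m16$phantom_diameter, 16)
})

test_that("ssde and dlp are validated products", {
  expect_equal(ssde_from_ctdi(6.26, 1.0), 6.26)
  expect_equal(ssde_from_ctdi(4.33, 1.31), 4.33 * 1.31)
  expect_error(ssde_from_ctdi(-1, 1.2), class = "bmissde_validation_error")
  expect_equal(dlp_from_ctdi(1, 47), 47)
  expect_equal(dlp_from_ctdi(4.33, 46.7), 4.33 * 46.7)
  expect_error(dlp_from_ctdi(6.26, 0), class = "bmissde_validation_error")
})

test_that("generate_conversion_table reproduces the packaged table row-for-row", {
  tab <- generate_conversion_table()
  ref <- ref_table()
  expect_equal(nrow(tab), 36L)
  expect_equal(tab$bmi, ref$bmi)
  expect_true(all(abs(tab$d_e_cm - ref$d_e_cm) <= 0.05))
  expect_true(all(abs(tab$conversion_factor - ref$conversion_factor) <= 0.01 + 1e-9))
  # monotone invariants of the table rows
  expect_true(all(diff(tab$d_e_cm) > 0))
  expect_true(all(diff(tab$conversion_factor) <= 0))
})

test_that("generate_conversion_table handles single rows and bad ranges", {
  one <- suppressWarnings(generate_conversion_table(50, 50, 1))
  expect_equal(one$d_e_cm, 47.4)
  expect_equal(one$conversion_factor, 0.65)
  expect_error(generate_conversion_table(20, 15, 1), class = "bmissde_validation_error")
  expect_error(generate_conversion_table(15, 50, 0), class = "bmissde_validation_error")
})

test_that("conversion model methods are coherent", {
  m <- default_conversion_model()
  expect_named(coef(m), c("a", "b"))
  expect_equal(predict(m, 28.4), conversion_factor(28.4, m))
  expect_equal(max(abs(residuals(m))), m$calibration_residual_max)
  expect_output(print(m), "32-cm")
})
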