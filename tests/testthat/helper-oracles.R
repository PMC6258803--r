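# Brute-force statistical oracles, written from the direct summation
# formulas so they are independent of the implementation they check.

bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

bf_ols <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  ss_res <- sum((y - slope * x - intercept)^2)
  ss_tot <- sum((y - yb)^2)
  list(slope = slope, intercept = intercept, r_squared = 1 - ss_res / ss_tot)
}

bf_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df = df))
}

# log-linear exponential fit by direct summation (oracle for the
# conversion-model calibration)
bf_exp_fit <- function(d_e, f) {
  o <- bf_ols(d_e, log(f))
  list(a = exp(o$intercept), b = -o$slope)
}

ref_table <- function() reference_conversion_table()
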