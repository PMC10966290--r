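# Shared fixtures and independent oracles for the test suite.

# Random curve-model parameter sets whose phases are well separated: the
# pre-onset tail is below ~2e-4 AU (so the estimated baseline matches the
# true one) and the curve returns to baseline well before the 2-h trace
# ends. Used for the extraction-vs-oracle property tests.
random_curve_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      tf <- stats::runif(1, 30, 90)
      tl <- stats::runif(1, 150, 400)
      amp <- stats::runif(1, 0.05, 0.55)
      onset <- 36 + tf * (log(amp / 2e-4) + stats::runif(1, 0, 3))
      mid <- onset + 4 * tf + stats::runif(1, 600, 2000)
      curve_gen_params(
        baseline_abs = stats::runif(1, 0.02, 0.10), amplitude = amp,
        onset_time = onset, formation_timescale = tf,
        lysis_midpoint_time = mid, lysis_timescale = tl
      )
    })
  })
}

# Independent rmcorr oracle: explicit dummy-coded ANCOVA design matrix,
# sequential sums of squares computed by comparing the subject-only model
# with the subject + covariate model via QR least squares.
rmcorr_oracle <- function(x, y, subject) {
  subject <- factor(subject)
  D <- stats::model.matrix(~ subject)
  X_full <- cbind(D, x = x)
  fit_red <- stats::lsfit(D, y, intercept = FALSE)
  fit_full <- stats::lsfit(X_full, y, intercept = FALSE)
  sse_red <- sum(fit_red$residuals^2)
  sse_full <- sum(fit_full$residuals^2)
  ss_x <- sse_red - sse_full
  slope <- fit_full$coefficients[["x"]]
  r <- sign(slope) * sqrt(ss_x / (ss_x + sse_full))
  df <- length(y) - nlevels(subject) - 1
  list(r = r, df = df, slope = slope)
}

# Small paired data set with a known within-subject association.
toy_paired_data <- function(n = 32, rho = 0.5, seed = 1) {
  withr::with_seed(seed, {
    xw <- matrix(stats::rnorm(n * 2), n)
    yw <- rho * xw + sqrt(1 - rho^2) * matrix(stats::rnorm(n * 2), n)
    tibble::tibble(
      subject = rep(seq_len(n), 2),
      x = as.vector(xw) + rep(stats::rnorm(n, 0, 2), 2),
      y = as.vector(yw) + rep(stats::rnorm(n, 0, 2), 2)
    )
  })
}
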