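test_that("perfect within-subject linearity gives r = 1 regardless of subject offsets", {
  d <- tibble::tibble(
    subject = c("a", "a", "b", "b"),
    x = c(0, 1, 0, 1),
    y = c(0, 1, 10, 11)
  )
  fit <- rmcorr(d, x, y, subject)
  expect_equal(fit$r, 1)
  expect_equal(fit$error_df, 1)
  expect_equal(fit$slope, 1)
})

test_that("rmcorr equals the explicit ANCOVA decomposition", {
  for (seed in 1:10) {
    d <- toy_paired_data(n = 32, rho = 0.4, seed = seed)
    fit <- rmcorr(d, x, y, subject)
    oracle <- rmcorr_oracle(d$x, d$y, d$subject)
    expect_equal(fit$r, oracle$r, tolerance = 1e-10)
    expect_equal(fit$error_df, oracle$df)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    # and the textbook lm route as a second independent reference
    lmfit <- stats::lm(y ~ factor(subject) + x, data = d)
    an <- stats::anova(lmfit)
    r_lm <- sign(stats::coef(lmfit)[["x"]]) *
      sqrt(an["x", "Sum Sq"] / (an["x", "Sum Sq"] + an["Residuals", "Sum Sq"]))
    expect_equal(fit$r, r_lm, tolerance = 1e-10)
  }
})

test_that("rmcorr is invariant to per-subject shifts and equals the centered Pearson correlation", {
  d <- toy_paired_data(n = 20, rho = 0.5, seed = 3)
  fit <- rmcorr(d, x, y, subject)
  withr::with_seed(4, {
    shift_x <- stats::rnorm(20, 0, 50)[d$subject]
    shift_y <- stats::rnorm(20, 0, 50)[d$subject]
  })
  d2 <- dplyr::mutate(d, x = x + shift_x, y = y + shift_y)
  fit2 <- rmcorr(d2, x, y, subject)
  expect_equal(fit$r, fit2$r, tolerance = 1e-10)

  xc <- d$x - stats::ave(d$x, d$subject)
  yc <- d$y - stats::ave(d$y, d$subject)
  expect_equal(abs(fit$r), abs(stats::cor(xc, yc)), tolerance = 1e-10)
})

test_that("rmcorr is centered at zero under within-subject permutation", {
  d <- toy_paired_data(n = 32, rho = 0.6, seed = 12)
  withr::with_seed(13, {
    rs <- replicate(1000, {
      perm <- d |>
        dplyr::group_by(subject) |>
        dplyr::mutate(y = sample(y)) |>
        dplyr::ungroup()
      rmcorr(perm, x, y, subject)$r
    })
  })
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("rmcorr validates its input structure", {
  d <- toy_paired_data(n = 5, seed = 2)
  expect_warning(
    fit <- rmcorr(dplyr::bind_rows(
      d, tibble::tibble(subject = 99L, x = 1, y = 1)), x, y, subject),
    "< 2 observations")
  expect_equal(fit$n_subjects, 5)
  solo <- tibble::tibble(subject = c(1, 2), x = c(1, 2), y = c(1, 2))
  expect_error(suppressWarnings(rmcorr(solo, x, y, subject)), ">= 2 subjects")
  const <- tibble::tibble(subject = rep(1:3, each = 2), x = 5,
                          y = stats::rnorm(6))
  expect_error(rmcorr(const, x, y, subject), "within-subject variance")
})

test_that("LMM reduces to OLS when the random intercept is estimated at zero", {
  withr::with_seed(1, {
    n <- 32
    x <- stats::rnorm(2 * n)
    y <- 0.5 + 0.3 * x + stats::rnorm(2 * n)  # independent errors
    d <- tibble::tibble(y = y, x = x, s = rep(1:n, 2))
  })
  fit <- fit_random_intercept_lmm(d, y, x, s)
  expect_lt(fit$var_u, 1e-10)
  ols <- unname(stats::coef(stats::lm(y ~ x, data = d))[2])
  expect_equal(fit$coefs$estimate[2], ols, tolerance = 1e-6)
})

test_that("duplicating every observation tightens the CI with nearly unchanged slope", {
  withr::with_seed(5, {
    n <- 32
    x <- stats::rnorm(2 * n, 40, 8)
    y <- 0.1 + 0.006 * x + rep(stats::rnorm(n, 0, 0.1), 2) +
      stats::rnorm(2 * n, 0, 0.05)
    d <- tibble::tibble(y = y, x = x, s = rep(1:n, 2))
  })
  f1 <- fit_random_intercept_lmm(d, y, x, s)
  f2 <- fit_random_intercept_lmm(dplyr::bind_rows(d, d), y, x, s)
  # REML re-estimates the variance ratio on the duplicated data, so the
  # GLS slope shifts slightly; it must stay within a few percent while the
  # Wald interval clearly narrows
  expect_equal(f2$coefs$estimate[2], f1$coefs$estimate[2], tolerance = 0.05)
  w1 <- f1$coefs$conf_high[2] - f1$coefs$conf_low[2]
  w2 <- f2$coefs$conf_high[2] - f2$coefs$conf_low[2]
  expect_lt(w2, w1)
})

test_that("REML optimum beats random variance-ratio probes", {
  d <- generate_cohort(cohort_config(n_subjects = 32, seed = 31),
                       curves = FALSE)$records
  dd <- lme4::lmer(max_abs ~ bmi + (1 | subject_id), data = d,
                   devFunOnly = TRUE)
  fit <- lme4::lmer(max_abs ~ bmi + (1 | subject_id), data = d, REML = TRUE)
  crit_opt <- dd(lme4::getME(fit, "theta"))
  withr::with_seed(32, {
    probes <- vapply(stats::runif(50, 0, 5), function(th) dd(th), numeric(1))
  })
  expect_true(all(crit_opt <= probes + 1e-8))
})

test_that("adjusted period effect vanishes when the outcome is driven by the adjustor", {
  withr::with_seed(41, {
    keep <- replicate(300, {
      co <- generate_cohort(cohort_config(n_subjects = 32), curves = FALSE)
      rec <- co$records
      rec$outcome <- 2 + 1300 * rec$max_abs + stats::rnorm(64, 0, 30)
      fit <- adjusted_period_effect(rec, outcome, max_abs, period, subject_id)
      fit$coefs$p_value[fit$coefs$term == "period"] > 0.05
    })
  })
  expect_gte(mean(keep), 0.90)
})

test_that("adjusted period effect recovers an injected pre/post shift", {
  withr::with_seed(43, {
    est <- replicate(300, {
      n <- 32
      adjustor <- stats::rnorm(2 * n, 0.4, 0.1)
      shift <- rep(c(0, -150), each = n)
      outcome <- 600 + shift + rep(stats::rnorm(n, 0, 80), 2) +
        stats::rnorm(2 * n, 0, 40)
      d <- tibble::tibble(outcome = outcome, adjustor = adjustor,
                          period = rep(c("pre", "post"), each = n),
                          s = rep(1:n, 2))
      fit <- adjusted_period_effect(d, outcome, adjustor, period, s)
      fit$coefs$estimate[fit$coefs$term == "period"]
    })
  })
  # period factor is alphabetical (post < pre), so the pre coefficient is +150
  expect_lt(abs(mean(est) - 150) / 150, 0.05)
})

test_that("a constant adjustor reduces to the unadjusted period model", {
  d <- generate_cohort(cohort_config(n_subjects = 16, seed = 6),
                       curves = FALSE)$records
  d$const <- 1
  expect_warning(
    fit <- adjusted_period_effect(d, lysis_area, const, period, subject_id),
    "constant")
  ref <- lme4::lmer(lysis_area ~ period + (1 | subject_id), data = d,
                    REML = TRUE)
  expect_equal(fit$coefs$estimate[2], unname(lme4::fixef(ref)[2]),
               tolerance = 1e-8)
})

test_that("association table covers requested covariates and flags degenerate ones", {
  cohort <- generate_cohort(cohort_config(n_subjects = 32, seed = 15),
                            curves = FALSE)
  rec <- cohort$records
  rec$frozen <- rep(3.2, nrow(rec))  # same value pre and post
  tab <- association_table(rec, covariates = c("bmi", "hba1c_pct", "frozen"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$covariate, c("bmi", "hba1c_pct", "frozen"))
  expect_true(is.na(tab$r[tab$covariate == "frozen"]))
  expect_match(tab$flag[tab$covariate == "frozen"], "within-subject variance")
  expect_true(all(!is.na(tab$r[tab$covariate != "frozen"])))
  expect_error(association_table(rec, covariates = "nope"), "not in records")
})

test_that("association r is centered at zero for an unrelated covariate", {
  withr::with_seed(50, {
    rs <- replicate(200, {
      co <- generate_cohort(cohort_config(n_subjects = 32), curves = FALSE)
      rec <- co$records
      rec$unrelated <- stats::rnorm(nrow(rec), 50, 5)
      rmcorr(rec, unrelated, max_abs, subject_id)$r
    })
  })
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("default cohort calibration reproduces the target BMI association", {
  withr::with_seed(60, {
    rs <- vapply(1:200, function(i) {
      co <- generate_cohort(cohort_config(n_subjects = 32), curves = FALSE)
      rmcorr(co$records, bmi, max_abs, subject_id)$r
    }, numeric(1))
  })
  target <- implied_rmcorr(cohort_config(), "bmi")
  expect_equal(target, 0.693, tolerance = 1e-6)
  expect_lt(abs(mean(rs) - target), 0.05)
})

test_that("tidiers return the documented schemas", {
  d <- toy_paired_data(n = 16, seed = 9)
  rf <- rmcorr(d, x, y, subject)
  td <- tidy(rf)
  expect_named(td, c("estimate", "conf_low", "conf_high", "p_value",
                     "error_df"))
  expect_true(td$conf_low <= td$estimate && td$estimate <= td$conf_high)
  gl <- glance(rf)
  expect_equal(gl$n_obs, 32)

  lf <- fit_random_intercept_lmm(d, y, x, subject)
  tl <- tidy(lf)
  expect_equal(tl$term, c("(Intercept)", "x"))
  gll <- glance(lf)
  expect_true(gll$random_intercept_variance >= 0)
  expect_true(gll$residual_variance >= 0)
  expect_true(is.logical(gll$converged))
})
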