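#' Default variable table for the synthetic paired cohort
#'
#' One row per clinical or clot variable with pre/post-surgery target means
#' and SDs, measurement unit, display label, reporting group and the
#' latent-factor structure: `loading` is the variable's loading on the
#' shared adiposity factor (in \[-1, 1\]); where `target_rmcorr` is given
#' instead, the loading is solved at configuration time so the implied
#' within-subject (difference) correlation with maximum absorbance matches
#' that target. Skewed non-negative variables (`log_scale = TRUE`) are
#' sampled on the log scale with moment-matched lognormal parameters so the
#' natural-scale mean and SD hit their targets without negative draws.
#' Dichotomous variables are thresholded from the latent score of a source
#' variable at the quantile matching the target proportion.
#'
#' @return A tibble of variable definitions; edit and pass to
#'   [cohort_config()] to change the generated population.
#' @export
cohort_variable_defaults <- function() {
  cont <- tibble::tribble(
    ~variable,              ~label,                              ~unit,    ~group,   ~pre_mean, ~pre_sd, ~post_mean, ~post_sd, ~log_scale, ~loading, ~target_rmcorr, ~period_invariant,
    "age_y",                "Age at recruitment",                "y",      "demographic", 47.91,  10.3,   47.91,  10.3,  FALSE, 0,    NA,    TRUE,
    "weight_kg",            "Weight",                            "kg",     "table1", 148.3,  24.9,  105.0,  18.9,  FALSE, NA,   0.617, FALSE,
    "bmi",                  "BMI",                               "kg/m2",  "table1",  52.1,   7.3,   37.5,   4.9,  FALSE, NA,   0.693, FALSE,
    "waist_cm",             "Waist circumference",               "cm",     "table1", 143.0,  10.4,  116.7,  11.0,  FALSE, NA,   0.717, FALSE,
    "hip_cm",               "Hip circumference",                 "cm",     "table1", 136.9,  11.5,  117.9,  10.5,  FALSE, NA,   0.622, FALSE,
    "waist_hip_ratio",      "Waist-to-hip ratio",                "",       "table1",   1.1,   0.1,    1.0,   0.1,  FALSE, NA,   0.592, FALSE,
    "neck_cm",              "Neck circumference",                "cm",     "table1",  46.3,   5.1,   40.0,   4.6,  FALSE, NA,   0.662, FALSE,
    "excess_weight_kg",     "Excess weight",                     "kg",     "table1",  87.3,  22.0,   44.2,  15.1,  FALSE, NA,   0.584, FALSE,
    "visceral_fat_rating",  "Visceral fat rating",               "",       "table1",  23,     7,     14,     4,    FALSE, NA,   0.750, FALSE,
    "hba1c_pct",            "Glycated hemoglobin",               "%",      "table1",   6.9,   1.7,    5.6,   0.7,  FALSE, NA,   0.443, FALSE,
    "glucose_mmol_l",       "Glucose",                           "mmol/L", "table1",   5.5,   2.5,    4.6,   0.7,  TRUE,  0.40, NA,    FALSE,
    "total_cholesterol_mm", "Total cholesterol",                 "mM",     "table1",   5.0,   1.1,    4.5,   0.9,  FALSE, 0.20, NA,    FALSE,
    "triglyceride_mm",      "Triglyceride",                      "mM",     "table1",   1.9,   1.2,    1.6,   1.0,  TRUE,  0.25, NA,    FALSE,
    "hdl_mm",               "High-density lipoprotein",          "mM",     "table1",   1.1,   0.2,    1.2,   0.2,  FALSE, -0.20, NA,   FALSE,
    "ldl_mm",               "Low-density lipoprotein",           "mM",     "table1",   3.1,   1.0,    2.8,   0.7,  FALSE, 0.20, NA,    FALSE,
    "chol_hdl_ratio",       "Cholesterol:HDL ratio",             "",       "table1",   4.7,   1.1,    4.0,   0.9,  FALSE, 0.35, NA,    FALSE,
    "fibrinogen_g_l",       "Fibrinogen",                        "g/L",    "fig2b",    3.4,   0.8,    3.4,   0.8,  FALSE, 0.20, NA,    FALSE,
    "pai1_pg_ml",           "PAI-1",                             "pg/mL",  "fig2b", 10560, 6681,  15290, 6559,   TRUE,  0.25, NA,    FALSE,
    "hs_crp_mg_l",          "hs-CRP",                            "mg/L",   "fig2b",  11.73,  6.95,   2.88,  4.04, TRUE,  NA,   0.575, FALSE,
    "max_abs",              "Maximum absorbance",                "AU",     "fig2b",    0.43,  0.11,   0.29,  0.10, FALSE, 0.92, NA,    FALSE,
    "lysis_area",           "Clot lysis area",                   "AU*s",   "fig2b",  587,   171,    413,   201,   FALSE, 0.80, NA,    FALSE,
    "lag_time_s",           "Lag time",                          "s",      "fig2b",  360,    90,    370,    90,   FALSE, -0.10, NA,   FALSE,
    "t50_lysis_s",          "50% lysis time",                    "s",      "fig2b", 1200,   300,   1260,   310,   FALSE, 0.15, NA,    FALSE,
    "t100_lysis_s",         "100% lysis time",                   "s",      "fig2b", 2400,   500,   2480,   520,   FALSE, 0.15, NA,    FALSE
  )
  attr(cont, "dichotomous") <- tibble::tribble(
    ~variable,     ~label,                  ~group,        ~source_variable, ~pre_prop, ~post_prop, ~period_invariant,
    "male",        "Males",                 "demographic", NA,               0.3125,    0.3125,     TRUE,
    "smoker",      "Smokers",               "demographic", NA,               0.50,      0.50,       TRUE,
    "dysglycemia", "With dysglycemia",      "table1",      "hba1c_pct",      0.625,     0.15625,    FALSE,
    "metformin",   "Prescribed metformin",  "table1",      "hba1c_pct",      0.3125,    0.125,      FALSE,
    "statin",      "Prescribed statin",     "table1",      "chol_hdl_ratio", 0.3125,    0.1875,     FALSE
  )
  cont
}

lognormal_params <- function(mean, sd) {
  if (mean <= 0) stop("log-scale variables need a positive mean", call. = FALSE)
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Implied within-subject (paired-difference) correlation between two
#' variables of the generator
#'
#' With two periods per subject, within-subject centering leaves each
#' subject contributing half its pre/post difference with opposite signs,
#' so the repeated-measures correlation of the generated data equals (in
#' population) the *uncentered* correlation of the paired differences —
#' the common period mean shift counts as within-subject covariation,
#' exactly as in a real pre/post cohort where most variables move together
#' after the intervention:
#' \deqn{r_{uv} = \frac{\Delta_u \Delta_v + C_{uv}}
#'   {\sqrt{(\Delta_u^2 + V_u)(\Delta_v^2 + V_v)}}}
#' with \eqn{\Delta} the post-minus-pre mean shift, \eqn{C_{uv}} the
#' covariance and \eqn{V} the variances of the paired differences. For two
#' Gaussian variables \eqn{C_{uv} = \lambda_u\lambda_v(s_{1u}s_{1v} +
#' s_{2u}s_{2v} - \rho(s_{1u}s_{2v} + s_{2u}s_{1v}))}, where \eqn{s_1, s_2}
#' are the per-period SDs, \eqn{\rho} the pre/post correlation of the
#' shared factor and \eqn{\phi} the subject-level share of each variable's
#' unique variation. Log-scale variables are handled exactly on the natural
#' scale via the closed-form Gaussian-lognormal and lognormal-lognormal
#' covariances, so solved loadings are free of attenuation bias.
#'
#' @param config A [cohort_config()].
#' @param var_u,var_v Variable names from the config's variable table.
#' @return The implied correlation.
#' @export
implied_rmcorr <- function(config, var_u, var_v = "max_abs") {
  stopifnot(inherits(config, "cohort_config"))
  vars <- config$variables
  ru <- vars[vars$variable == var_u, ]
  rv <- vars[vars$variable == var_v, ]
  if (nrow(ru) != 1L || nrow(rv) != 1L) stop("unknown variable", call. = FALSE)
  implied_diff_cor(ru, rv, config$rho, config$phi)
}

# Correlation of the latent z-scores of (variable u, period i) and
# (variable v, period j) under the factor model.
latent_z_cor <- function(lu, lv, same_var, same_period, rho, phi) {
  if (same_var) {
    if (same_period) 1 else rho * lu^2 + phi * (1 - lu^2)
  } else {
    if (same_period) lu * lv else lu * lv * rho
  }
}

# Natural-scale description of one variable in one period.
nat_moments <- function(row, period) {
  m <- if (period == 1) row$pre_mean else row$post_mean
  s <- if (period == 1) row$pre_sd else row$post_sd
  if (row$log_scale) {
    lp <- lognormal_params(m, s)
    list(mean = m, sd = s, log = TRUE, sdlog = lp$sdlog)
  } else {
    list(mean = m, sd = s, log = FALSE, sdlog = NA_real_)
  }
}

# Natural-scale covariance of the two (possibly lognormal) observations
# given the correlation of their latent z-scores.
nat_cov <- function(a, b, zcor) {
  if (!a$log && !b$log) {
    a$sd * b$sd * zcor
  } else if (a$log && !b$log) {
    a$mean * a$sdlog * b$sd * zcor
  } else if (!a$log && b$log) {
    a$sd * b$mean * b$sdlog * zcor
  } else {
    a$mean * b$mean * (exp(a$sdlog * b$sdlog * zcor) - 1)
  }
}

# Implied uncentered correlation of paired differences on the natural
# scale, for any combination of Gaussian and lognormal variables.
implied_diff_cor <- function(ru, rv, rho, phi) {
  mu <- lapply(1:2, function(i) nat_moments(ru, i))
  mv <- lapply(1:2, function(i) nat_moments(rv, i))
  lu <- ru$loading; lv <- rv$loading
  cz <- function(same_var, i, j, la, lb)
    latent_z_cor(la, lb, same_var, i == j, rho, phi)
  var_d <- function(m, l) {
    m[[1]]$sd^2 + m[[2]]$sd^2 -
      2 * nat_cov(m[[1]], m[[2]], cz(TRUE, 1, 2, l, l))
  }
  cov_d <- nat_cov(mu[[2]], mv[[2]], cz(FALSE, 2, 2, lu, lv)) +
    nat_cov(mu[[1]], mv[[1]], cz(FALSE, 1, 1, lu, lv)) -
    nat_cov(mu[[1]], mv[[2]], cz(FALSE, 1, 2, lu, lv)) -
    nat_cov(mu[[2]], mv[[1]], cz(FALSE, 2, 1, lu, lv))
  du <- mu[[2]]$mean - mu[[1]]$mean
  dv <- mv[[2]]$mean - mv[[1]]$mean
  den2 <- (du^2 + var_d(mu, lu)) * (dv^2 + var_d(mv, lv))
  if (den2 <= 0) return(NA_real_)
  (du * dv + cov_d) / sqrt(den2)
}

# Solve a loading so the implied difference-correlation with the reference
# variable hits `target`. Falls back to 0 for degenerate (zero-variance)
# configurations; when the target is outside the attainable range the
# loading is capped at the boundary that comes closest.
solve_loading <- function(target, row, ref, rho, phi) {
  f <- function(l) {
    row$loading <- l
    implied_diff_cor(row, ref, rho, phi) - target
  }
  if (!all(is.finite(c(f(-1), f(1))))) return(0)
  if (sign(f(-1)) == sign(f(1)))
    return(if (abs(f(1)) <= abs(f(-1))) 1 else -1)
  stats::uniroot(f, c(-1, 1), tol = 1e-10)$root
}

#' Configuration for the synthetic paired cohort
#'
#' Defines the generating population: per-variable pre/post means and SDs
#' (see [cohort_variable_defaults()]), the latent-factor correlation
#' structure, replicate wells per sample and curve noise. All values
#' default to the studied bariatric-surgery cohort so that
#' `generate_cohort(cohort_config())` emulates the study conditions:
#' 32 subjects measured before and 9 months after surgery, duplicate wells,
#' 12-s reads over 2 h.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param variables Variable table; see [cohort_variable_defaults()].
#' @param rho Pre/post correlation of the shared latent factor, in \[0, 1\].
#' @param phi Subject-level share of each variable's unique variation, in
#'   \[0, 1\]; keeps pre/post within-subject correlation positive even for
#'   variables with small factor loadings. With `rho = phi` every variable
#'   has pre/post latent correlation exactly `phi`; the default 0.35 keeps
#'   paired structure while leaving enough paired-difference variance for
#'   the configured within-subject correlation targets to be reachable.
#' @param replicates Wells per sample (>= 1; assay default 2, duplicate).
#' @param noise_sd Curve reading-noise SD (AU).
#' @param grid [time_grid()] used for generated curves.
#' @param baseline_abs Baseline absorbance of generated curves (AU).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `cohort_config` object with loadings resolved.
#' @export
cohort_config <- function(n_subjects = 32, variables = cohort_variable_defaults(),
                          rho = 0.35, phi = 0.35, replicates = 2L,
                          noise_sd = 0.003, grid = time_grid(),
                          baseline_abs = 0.05, seed = NULL) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  if (rho < 0 || rho > 1 || phi < 0 || phi > 1)
    stop("`rho` and `phi` must be in [0, 1]", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  need <- c("variable", "pre_mean", "pre_sd", "post_mean", "post_sd",
            "log_scale", "loading", "target_rmcorr", "period_invariant")
  if (!all(need %in% names(variables)))
    stop("`variables` is missing columns: ",
         paste(setdiff(need, names(variables)), collapse = ", "), call. = FALSE)
  if (any(variables$pre_sd < 0 | variables$post_sd < 0))
    stop("SDs must be >= 0", call. = FALSE)
  if (!"max_abs" %in% variables$variable)
    stop("`variables` must include `max_abs`", call. = FALSE)
  bad <- !is.na(variables$loading) & abs(variables$loading) > 1
  if (any(bad)) stop("loadings must be in [-1, 1]", call. = FALSE)

  ref <- variables[variables$variable == "max_abs", ]
  variables$loading <- purrr::pmap_dbl(
    variables, function(...) {
      row <- tibble::tibble(...)
      if (!is.na(row$loading)) return(row$loading)
      if (is.na(row$target_rmcorr))
        stop("variable ", row$variable,
             " needs either `loading` or `target_rmcorr`", call. = FALSE)
      solve_loading(row$target_rmcorr, row, ref, rho, phi)
    }
  )
  structure(
    list(n_subjects = as.integer(n_subjects), variables = variables,
         dichotomous = attr(variables, "dichotomous") %||%
           attr(cohort_variable_defaults(), "dichotomous"),
         rho = rho, phi = phi, replicates = as.integer(replicates),
         noise_sd = noise_sd, grid = grid, baseline_abs = baseline_abs,
         seed = seed),
    class = "cohort_config"
  )
}

#' Generate a synthetic paired pre/post cohort
#'
#' Samples a paired cohort from a single-latent-factor Gaussian model: a
#' shared "adiposity" factor (subject-level component plus period
#' innovation) drives the cross-variable correlations, each variable adds
#' its own subject-level intercept and period noise, and skewed non-negative
#' variables are drawn on the log scale with moment-matched lognormal
#' parameters. Dichotomous states are thresholded from the latent score of
#' their source variable at the quantile matching the configured
#' proportion. Optionally, replicate turbidity curves are generated per
#' subject-period sample, calibrated so each curve's true (dense-grid
#' oracle) maximum absorbance equals the subject's sampled value and its
#' true lag time equals the sampled lag time.
#'
#' @param config A [cohort_config()].
#' @param curves Generate replicate turbidity curves? Set `FALSE` for fast
#'   large-n calibration studies of the tabular variables only.
#' @return A `clot_cohort` list: `records` (tibble, one row per
#'   subject-period), `curves` (long tibble or `NULL`), `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 4, seed = 1),
#'                           curves = FALSE)
#' dplyr::count(cohort$records, period)
#' @export
generate_cohort <- function(config, curves = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config, curves))
}

generate_cohort_impl <- function(config, curves) {
  n <- config$n_subjects
  vars <- config$variables
  subjects <- sprintf("S%03d", seq_len(n))
  rho <- config$rho; phi <- config$phi

  f <- stats::rnorm(n)
  a <- list(
    pre = sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n),
    post = sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
  )

  zscores <- list(pre = list(), post = list())
  values <- list(pre = list(), post = list())
  for (k in seq_len(nrow(vars))) {
    row <- vars[k, ]
    lam <- row$loading
    b <- stats::rnorm(n)
    for (period in c("pre", "post")) {
      if (row$period_invariant) {
        z <- b
      } else {
        eta <- sqrt(phi) * b + sqrt(1 - phi) * stats::rnorm(n)
        z <- lam * a[[period]] + sqrt(1 - lam^2) * eta
      }
      m <- if (period == "pre") row$pre_mean else row$post_mean
      s <- if (period == "pre") row$pre_sd else row$post_sd
      val <- if (row$log_scale) {
        lp <- lognormal_params(m, s)
        exp(lp$meanlog + lp$sdlog * z)
      } else {
        m + s * z
      }
      zscores[[period]][[row$variable]] <- z
      values[[period]][[row$variable]] <- val
    }
  }

  dich <- config$dichotomous
  dvalues <- list(pre = list(), post = list())
  for (k in seq_len(nrow(dich))) {
    row <- dich[k, ]
    if (row$period_invariant) {
      state <- stats::runif(n) < row$pre_prop
      dvalues$pre[[row$variable]] <- state
      dvalues$post[[row$variable]] <- state
    } else {
      for (period in c("pre", "post")) {
        p <- if (period == "pre") row$pre_prop else row$post_prop
        z <- zscores[[period]][[row$source_variable]]
        if (is.null(z))
          stop("dichotomous source variable not generated: ",
               row$source_variable, call. = FALSE)
        dvalues[[period]][[row$variable]] <- z > stats::qnorm(1 - p)
      }
    }
  }

  records <- dplyr::bind_rows(lapply(c("pre", "post"), function(period) {
    tibble::as_tibble(c(
      list(subject_id = subjects,
           period = factor(period, levels = c("pre", "post"))),
      values[[period]], dvalues[[period]]
    ))
  })) |>
    dplyr::arrange(.data$subject_id, .data$period)

  curve_tbl <- NULL
  if (curves) {
    curve_tbl <- generate_cohort_curves(records, config)
  }
  structure(list(records = records, curves = curve_tbl, config = config),
            class = "clot_cohort")
}

# Replicate curves for every subject-period sample, calibrated to the
# sampled maximum absorbance and lag time. Values outside the range the
# curve model supports are clipped (documented in the methods vignette).
generate_cohort_curves <- function(records, config) {
  b <- config$baseline_abs
  purrr::pmap(
    list(records$subject_id, as.character(records$period),
         records$max_abs, records$lag_time_s, records$t50_lysis_s),
    function(subject, period, max_abs, lag, t50) {
      params <- calibrate_curve_params(
        target_max = max(max_abs, b + 0.02),
        target_lag = max(lag, 60),
        baseline_abs = b,
        lysis_half_time = max(t50, 300)
      )
      sample_id <- paste(subject, period, sep = "_")
      dplyr::bind_rows(lapply(seq_len(config$replicates), function(r) {
        generate_curve(params, config$grid, noise_sd = config$noise_sd,
                       sample_id = sample_id,
                       well_id = paste0(sample_id, "_w", r), replicate = r)
      }))
    }
  ) |>
    dplyr::bind_rows()
}

#' @export
print.clot_cohort <- function(x, ...) {
  cat("<clot_cohort> ", x$config$n_subjects, " subjects, ",
      nrow(x$records), " records",
      if (!is.null(x$curves))
        paste0(", ", length(unique(x$curves$well_id)), " curves"),
      "\n", sep = "")
  print(x$records, n = 4)
  invisible(x)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n_subjects=", x$n_subjects,
      " rho=", x$rho, " phi=", x$phi,
      " replicates=", x$replicates, " noise_sd=", x$noise_sd, "\n", sep = "")
  invisible(x)
}
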