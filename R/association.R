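#' Repeated-measures correlation
#'
#' Common within-subject association between two repeatedly measured
#' variables, from the analysis-of-covariance model with subject-specific
#' intercepts and a common slope: both variables are centered within
#' subject, the common slope \eqn{b} estimated by least squares, and
#' \deqn{r = \mathrm{sign}(b)\sqrt{SS_x / (SS_x + SS_e)}}
#' with \eqn{SS_x} the covariate sum of squares and \eqn{SS_e} the residual
#' sum of squares; this equals the Pearson correlation of the
#' within-subject-centered variables in magnitude. Error degrees of freedom
#' are \eqn{N - k - 1} for \eqn{N} observations on \eqn{k} subjects; the p
#' value comes from \eqn{t = r\sqrt{df/(1 - r^2)}} and the 95% CI from the
#' Fisher z-transform with standard error \eqn{1/\sqrt{df - 1}}.
#'
#' Subjects with fewer than two complete observations carry no
#' within-subject information and are dropped with a warning.
#'
#' @param data A data frame.
#' @param x,y Column names (strings or bare names) of the two measures.
#' @param subject Column name identifying the individual.
#' @return An `rmcorr_fit` object; see [tidy()] and [glance()].
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42), curves = FALSE)
#' rmcorr(cohort$records, bmi, max_abs, subject_id)
#' @export
rmcorr <- function(data, x, y, subject) {
  stopifnot(is.data.frame(data))
  xv <- col_pull(data, rlang::enquo(x))
  yv <- col_pull(data, rlang::enquo(y))
  sv <- col_pull(data, rlang::enquo(subject))
  rmcorr_impl(xv, yv, sv)
}

# Resolve a column given as a bare name or a string.
col_pull <- function(data, quo) {
  v <- rlang::eval_tidy(quo, data)
  if (is.character(v) && length(v) == 1L && v %in% names(data))
    v <- data[[v]]
  v
}

rmcorr_impl <- function(x, y, subject) {
  if (length(x) != length(y) || length(x) != length(subject))
    stop("`x`, `y` and `subject` must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y) & !is.na(subject)
  x <- x[ok]; y <- y[ok]; subject <- as.character(subject[ok])

  per_subject <- table(subject)
  few <- names(per_subject)[per_subject < 2]
  if (length(few) > 0) {
    warning("dropping subject(s) with < 2 observations: ",
            paste(few, collapse = ", "), call. = FALSE)
    keep <- !(subject %in% few)
    x <- x[keep]; y <- y[keep]; subject <- subject[keep]
  }
  n_subj <- length(unique(subject))
  n_obs <- length(x)
  if (n_subj < 2)
    stop("repeated-measures correlation needs >= 2 subjects with repeated observations",
         call. = FALSE)

  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  ssxx <- sum(xc^2)
  if (ssxx <= .Machine$double.eps * n_obs)
    stop("`x` has no within-subject variance; rmcorr undefined", call. = FALSE)
  slope <- sum(xc * yc) / ssxx
  ss_x <- slope^2 * ssxx
  ss_e <- sum((yc - slope * xc)^2)
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  df <- n_obs - n_subj - 1

  t_stat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  z <- atanh(r)
  se_z <- 1 / sqrt(df - 1)
  ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se_z)

  structure(
    list(r = r, error_df = df, p_value = p,
         conf_low = ci[1], conf_high = ci[2], slope = slope,
         n_obs = n_obs, n_subjects = n_subj),
    class = "rmcorr_fit"
  )
}

#' @export
print.rmcorr_fit <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures correlation\n  r = %.3f  (95%% CI %.3f to %.3f)\n  error df = %d, p = %.4g  (%d obs, %d subjects)\n",
    x$r, x$conf_low, x$conf_high, x$error_df, x$p_value, x$n_obs,
    x$n_subjects))
  invisible(x)
}

# Shared machinery for random-intercept mixed models: fit
# y ~ <fixed terms> + (1 | subject) by REML (lme4), extract Wald-normal
# inference for the fixed effects and the two variance components.
lmm_engine <- function(formula, data, reml = TRUE) {
  fit <- suppressMessages(lme4::lmer(
    formula, data = data, REML = reml,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zcrit <- stats::qnorm(0.975)
  coefs <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std_error = unname(se),
    statistic = unname(beta / se),
    p_value = 2 * stats::pnorm(-abs(unname(beta / se))),
    conf_low = unname(beta - zcrit * se),
    conf_high = unname(beta + zcrit * se)
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_u <- vc$vcov[vc$grp != "Residual"][1]
  var_e <- vc$vcov[vc$grp == "Residual"][1]
  msgs <- fit@optinfo$conv$lme4$messages
  list(model = fit, coefs = coefs, var_u = var_u, var_e = var_e,
       n_obs = stats::nobs(fit), n_subjects = lme4::ngrps(fit)[[1]],
       converged = is.null(msgs) || length(msgs) == 0, reml = reml)
}

new_ri_lmm <- function(engine, focus_term) {
  structure(c(engine, list(focus_term = focus_term)), class = "ri_lmm")
}

#' Random-intercept linear mixed-model regression
#'
#' Fits \eqn{y_{ij} = \beta_0 + \beta_1 x_{ij} + u_i + \epsilon_{ij}} with
#' \eqn{u_i \sim N(0, \sigma_u^2)} a per-subject random intercept and
#' \eqn{\epsilon_{ij} \sim N(0, \sigma_e^2)}, the standard model for
#' regression on repeated measurements. Variance components are estimated
#' by REML (restricted maximum likelihood; set `reml = FALSE` for ML) and
#' slope inference uses the Wald normal approximation without a
#' small-sample df correction — an approximation, stated as such. A
#' boundary fit with \eqn{\hat\sigma_u^2 = 0} is valid and reduces the
#' slope to ordinary least squares.
#'
#' @param data A data frame.
#' @param y,x Outcome and covariate column names.
#' @param subject Column identifying the individual.
#' @param reml Use REML (default) rather than ML.
#' @return An `ri_lmm` object; see [tidy()] and [glance()].
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42), curves = FALSE)
#' fit_random_intercept_lmm(cohort$records, max_abs, bmi, subject_id)
#' @export
fit_random_intercept_lmm <- function(data, y, x, subject, reml = TRUE) {
  stopifnot(is.data.frame(data))
  d <- tibble::tibble(
    .y = col_pull(data, rlang::enquo(y)),
    .x = col_pull(data, rlang::enquo(x)),
    .subject = as.character(col_pull(data, rlang::enquo(subject)))
  )
  d <- d[stats::complete.cases(d), ]
  assert_finite(d$.y, "y")
  eng <- lmm_engine(.y ~ .x + (1 | .subject), d, reml = reml)
  eng$coefs$term <- c("(Intercept)", "x")
  new_ri_lmm(eng, "x")
}

#' Period effect adjusted for a covariate, with random intercepts
#'
#' Fits `outcome ~ period + adjustor + (1 | subject)` and reports the
#' period coefficient: the pre/post difference remaining after adjustment.
#' Used, e.g., to ask whether a change in clot lysis area persists after
#' adjusting for maximum absorbance. A constant adjustor is dropped
#' (reducing to the unadjusted period model) with a warning.
#'
#' @param data A data frame.
#' @param outcome,adjustor Outcome and adjustment covariate columns.
#' @param period Factor-like column with the two periods.
#' @param subject Column identifying the individual.
#' @param reml Use REML (default).
#' @return An `ri_lmm` object whose focus term is the period contrast.
#' @export
adjusted_period_effect <- function(data, outcome, adjustor, period, subject,
                                   reml = TRUE) {
  stopifnot(is.data.frame(data))
  d <- tibble::tibble(
    .y = col_pull(data, rlang::enquo(outcome)),
    .adj = col_pull(data, rlang::enquo(adjustor)),
    .period = factor(col_pull(data, rlang::enquo(period))),
    .subject = as.character(col_pull(data, rlang::enquo(subject)))
  )
  d <- d[stats::complete.cases(d), ]
  if (nlevels(droplevels(d$.period)) != 2)
    stop("`period` must have exactly two levels", call. = FALSE)
  d$.period <- droplevels(d$.period)
  if (stats::sd(d$.adj) == 0) {
    warning("adjustor is constant; fitting the unadjusted period model",
            call. = FALSE)
    eng <- lmm_engine(.y ~ .period + (1 | .subject), d, reml = reml)
    eng$coefs$term <- c("(Intercept)", "period")
  } else {
    eng <- lmm_engine(.y ~ .period + .adj + (1 | .subject), d, reml = reml)
    eng$coefs$term <- c("(Intercept)", "period", "adjustor")
  }
  new_ri_lmm(eng, "period")
}

#' @export
print.ri_lmm <- function(x, ...) {
  foc <- x$coefs[x$coefs$term == x$focus_term, ]
  cat(sprintf(
    "Random-intercept LMM (%s)\n  %s: beta = %.4g (95%% CI %.4g to %.4g), p = %.4g\n  var(subject) = %.4g, var(residual) = %.4g; %d obs, %d subjects%s\n",
    if (x$reml) "REML" else "ML", x$focus_term, foc$estimate, foc$conf_low,
    foc$conf_high, foc$p_value, x$var_u, x$var_e, x$n_obs, x$n_subjects,
    if (x$converged) "" else " [convergence warning]"))
  invisible(x)
}

#' Association table: each covariate against an outcome
#'
#' For every requested covariate, computes the repeated-measures
#' correlation with the outcome and the univariate random-intercept LMM
#' slope of the outcome on the covariate, using all subject-period
#' observations. Covariates enter in their natural units (no
#' standardisation), so slopes for an outcome of small magnitude are
#' themselves small. Covariates with zero within-subject variance have no
#' repeated-measures correlation and are flagged.
#'
#' @param records Long cohort tibble (one row per subject-period).
#' @param outcome Outcome variable name (string); default `"max_abs"`.
#' @param covariates Character vector of covariate names.
#' @param variables Variable metadata for labels.
#' @param reml Use REML for the LMM fits.
#' @return A tibble with one row per covariate: `r`, `r_conf_low`,
#'   `r_conf_high`, `r_p`, `beta`, `beta_conf_low`, `beta_conf_high`,
#'   `beta_p`, `n_obs`, `n_subjects`, `flag`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42), curves = FALSE)
#' association_table(cohort$records, covariates = c("bmi", "hba1c_pct"))
#' @export
association_table <- function(records, outcome = "max_abs",
                              covariates = c("bmi", "weight_kg", "waist_cm",
                                             "hip_cm", "waist_hip_ratio",
                                             "neck_cm", "excess_weight_kg",
                                             "visceral_fat_rating",
                                             "hba1c_pct", "hs_crp_mg_l"),
                              variables = cohort_variable_defaults(),
                              reml = TRUE) {
  stopifnot(is.data.frame(records), outcome %in% names(records),
            "subject_id" %in% names(records))
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov) > 0)
    stop("covariate(s) not in records: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  labels <- stats::setNames(variables$label, variables$variable)

  purrr::map(covariates, function(cov) {
    base <- tibble::tibble(
      covariate = cov,
      label = if (cov %in% names(labels)) unname(labels[cov]) else cov
    )
    rm_fit <- tryCatch(
      rmcorr_impl(records[[cov]], records[[outcome]], records$subject_id),
      error = function(e) conditionMessage(e))
    lmm_fit <- tryCatch(
      fit_random_intercept_lmm(records, outcome, cov, "subject_id",
                               reml = reml),
      error = function(e) conditionMessage(e))
    if (is.character(rm_fit)) {
      base <- dplyr::mutate(base, r = NA_real_, r_conf_low = NA_real_,
                            r_conf_high = NA_real_, r_p = NA_real_,
                            flag = rm_fit)
    } else {
      base <- dplyr::mutate(base, r = rm_fit$r, r_conf_low = rm_fit$conf_low,
                            r_conf_high = rm_fit$conf_high,
                            r_p = rm_fit$p_value, flag = NA_character_)
    }
    if (is.character(lmm_fit)) {
      base <- dplyr::mutate(base, beta = NA_real_, beta_conf_low = NA_real_,
                            beta_conf_high = NA_real_, beta_p = NA_real_,
                            n_obs = NA_integer_, n_subjects = NA_integer_)
    } else {
      sl <- lmm_fit$coefs[lmm_fit$coefs$term == "x", ]
      base <- dplyr::mutate(base, beta = sl$estimate,
                            beta_conf_low = sl$conf_low,
                            beta_conf_high = sl$conf_high,
                            beta_p = sl$p_value,
                            n_obs = lmm_fit$n_obs,
                            n_subjects = lmm_fit$n_subjects)
    }
    base
  }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("flag", .after = dplyr::last_col())
}
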