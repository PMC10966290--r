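#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeated-measures correlation fit
#'
#' @param x An `rmcorr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `estimate` (r), `conf_low`, `conf_high`,
#'   `p_value`, `error_df`.
#' @export
tidy.rmcorr_fit <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, conf_low = x$conf_low, conf_high = x$conf_high,
    p_value = x$p_value, error_df = x$error_df
  )
}

#' @rdname tidy.rmcorr_fit
#' @export
glance.rmcorr_fit <- function(x, ...) {
  tibble::tibble(
    r = x$r, error_df = x$error_df, p_value = x$p_value,
    n_obs = x$n_obs, n_subjects = x$n_subjects, slope = x$slope
  )
}

#' Tidy a random-intercept mixed-model fit
#'
#' @param x An `ri_lmm`.
#' @param ... Unused.
#' @return `tidy()`: one row per fixed-effect term with Wald-normal
#'   inference. `glance()`: one row of model-level quantities including the
#'   variance components.
#' @export
tidy.ri_lmm <- function(x, ...) {
  x$coefs
}

#' @rdname tidy.ri_lmm
#' @export
glance.ri_lmm <- function(x, ...) {
  tibble::tibble(
    random_intercept_variance = x$var_u, residual_variance = x$var_e,
    n_obs = x$n_obs, n_subjects = x$n_subjects,
    converged = x$converged, reml = x$reml
  )
}
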