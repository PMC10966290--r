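#' Parameters of the synthetic turbidity-curve model
#'
#' The generator is phenomenological: absorbance starts at a baseline, rises
#' sigmoidally once fibrin polymerisation begins, plateaus at a maximum, and
#' falls back to baseline as tPA-driven fibrinolysis dissolves the clot. The
#' noiseless model is
#' \deqn{A(t) = b + a \, S\!\left(\frac{t - t_0}{\tau_f}\right)
#'         \left[1 - S\!\left(\frac{t - t_m}{\tau_l}\right)\right]}
#' with \eqn{S} the standard logistic, \eqn{b} the baseline absorbance,
#' \eqn{a} the amplitude, \eqn{t_0} the formation onset, \eqn{\tau_f} the
#' formation timescale, \eqn{t_m} the lysis midpoint and \eqn{\tau_l} the
#' lysis timescale. When onset and lysis midpoint are well separated the peak
#' of the product term approaches 1, so the curve maximum approaches
#' \eqn{b + a}.
#'
#' @param baseline_abs Baseline absorbance (AU at 340 nm).
#' @param amplitude Target rise above baseline (AU); must be >= 0.
#' @param onset_time Clot-formation onset (s).
#' @param formation_timescale Formation logistic timescale (s), > 0.
#' @param lysis_midpoint_time Time of half-maximal lysis (s); must exceed
#'   `onset_time`.
#' @param lysis_timescale Lysis logistic timescale (s), > 0.
#' @return A `curve_gen_params` list.
#' @examples
#' p <- curve_gen_params(amplitude = 0.4)
#' curve_model(p)(c(0, 600, 3600, 7200))
#' @export
curve_gen_params <- function(baseline_abs = 0.05,
                             amplitude = 0.40,
                             onset_time = 600,
                             formation_timescale = 60,
                             lysis_midpoint_time = 3600,
                             lysis_timescale = 300) {
  vals <- c(baseline_abs, amplitude, onset_time, formation_timescale,
            lysis_midpoint_time, lysis_timescale)
  if (!all(is.finite(vals))) stop("curve parameters must be finite", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (formation_timescale <= 0 || lysis_timescale <= 0)
    stop("timescales must be > 0", call. = FALSE)
  if (onset_time >= lysis_midpoint_time)
    stop("`onset_time` must be < `lysis_midpoint_time`", call. = FALSE)
  structure(
    list(
      baseline_abs = baseline_abs, amplitude = amplitude,
      onset_time = onset_time, formation_timescale = formation_timescale,
      lysis_midpoint_time = lysis_midpoint_time,
      lysis_timescale = lysis_timescale
    ),
    class = "curve_gen_params"
  )
}

#' Plate-reader time grid
#'
#' Default matches the assay protocol: one reading every 12 s for at least
#' two hours.
#'
#' @param start First read time (s).
#' @param step Sampling interval (s), > 0.
#' @param duration Total monitored time (s), >= `step`.
#' @return A `time_grid` list with a `times` vector.
#' @export
time_grid <- function(start = 0, step = 12, duration = 7200) {
  if (!all(is.finite(c(start, step, duration))))
    stop("grid values must be finite", call. = FALSE)
  if (step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (duration < step) stop("`duration` must be >= `step`", call. = FALSE)
  structure(
    list(start = start, step = step, duration = duration,
         times = seq(start, start + duration, by = step)),
    class = "time_grid"
  )
}

#' Noiseless curve model as a function of time
#'
#' @param params A [curve_gen_params()] object.
#' @return A vectorised function of time (s) returning absorbance (AU).
#' @export
curve_model <- function(params) {
  stopifnot(inherits(params, "curve_gen_params"))
  force(params)
  function(t) {
    rise <- stats::plogis((t - params$onset_time) / params$formation_timescale)
    fall <- 1 - stats::plogis((t - params$lysis_midpoint_time) / params$lysis_timescale)
    params$baseline_abs + params$amplitude * rise * fall
  }
}

#' Generate a synthetic turbidity curve
#'
#' Evaluates the noiseless clot formation/lysis model on a plate-reader time
#' grid and adds i.i.d. Gaussian reading noise. Deterministic for a fixed
#' seed.
#'
#' @param params A [curve_gen_params()] object.
#' @param grid A [time_grid()] object.
#' @param noise_sd Additive reading-noise SD (AU); default 0.003, small
#'   relative to the 0.01 AU lag threshold.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @param sample_id,well_id,replicate Identifiers carried into the output.
#' @return A tibble with columns `sample_id`, `well_id`, `replicate`,
#'   `time_s`, `abs_340`.
#' @examples
#' curve <- generate_curve(curve_gen_params(), time_grid(), noise_sd = 0)
#' head(curve)
#' @export
generate_curve <- function(params, grid, noise_sd = 0.003, seed = NULL,
                           sample_id = "S1", well_id = "A1", replicate = 1L) {
  stopifnot(inherits(params, "curve_gen_params"), inherits(grid, "time_grid"))
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("`noise_sd` must be finite and >= 0", call. = FALSE)
  times <- grid$times
  clean <- curve_model(params)(times)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  } else {
    numeric(length(times))
  }
  tibble::tibble(
    sample_id = sample_id,
    well_id = well_id,
    replicate = as.integer(replicate),
    time_s = times,
    abs_340 = clean + noise
  )
}

#' Ground-truth clot parameters by dense-grid evaluation
#'
#' Brute-force oracle for the extraction stage: evaluates the noiseless
#' generator on a fine grid (step <= 0.1 s) and reads off the assay
#' parameters by direct scan — lag time (first rise of 0.01 AU above
#' baseline), maximum absorbance and its time, 50% and 100% lysis times
#' (elapsed from the maximum) and clot lysis area (area above baseline from
#' the maximum to baseline return). A curve that never rises 0.01 AU above
#' baseline is flagged `no_clot`.
#'
#' @param params A [curve_gen_params()] object.
#' @param dense_step Oracle grid step (s), <= 0.1.
#' @param duration Evaluation horizon (s); default long enough for the curve
#'   to return to baseline.
#' @param lag_threshold Rise above baseline defining the lag time (AU).
#' @param return_tolerance Band above baseline within which the clot is
#'   considered fully lysed (AU).
#' @return A one-row tibble in the same schema as [extract_parameters()].
#' @export
ground_truth_parameters <- function(params, dense_step = 0.1, duration = NULL,
                                    lag_threshold = 0.01,
                                    return_tolerance = 0.01) {
  stopifnot(inherits(params, "curve_gen_params"))
  if (dense_step > 0.1) stop("`dense_step` must be <= 0.1 s", call. = FALSE)
  if (is.null(duration)) {
    # horizon where the lysis logistic has decayed to ~amplitude/1e4
    duration <- params$lysis_midpoint_time + 12 * params$lysis_timescale
  }
  tt <- seq(0, duration, by = dense_step)
  aa <- curve_model(params)(tt)
  b <- params$baseline_abs

  if (params$amplitude < lag_threshold) {
    return(clot_parameter_row(
      sample_id = "truth", well_id = NA_character_, replicate = NA_integer_,
      baseline = b, flags = "no_clot"
    ))
  }

  i_lag <- which(aa >= b + lag_threshold)[1L]
  lag <- tt[i_lag]
  i_max <- which.max(aa)
  max_abs <- aa[i_max]
  t_max <- tt[i_max]

  post_t <- tt[tt >= t_max]
  post_a <- aa[tt >= t_max]
  i50 <- which(post_a <= max_abs - 0.5 * (max_abs - b))[1L]
  i100 <- which(post_a <= b + return_tolerance)[1L]
  flags <- character()
  t50 <- if (is.na(i50)) NA_real_ else post_t[i50] - t_max
  t100 <- if (is.na(i100)) NA_real_ else post_t[i100] - t_max
  if (is.na(i100)) flags <- c(flags, "no_return_to_baseline", "truncated")
  t_end <- if (is.na(i100)) max(tt) else post_t[i100]
  keep <- tt >= t_max & tt <= t_end
  excess <- pmax(aa[keep] - b, 0)
  area <- sum(diff(tt[keep]) * (utils::head(excess, -1) + utils::tail(excess, -1)) / 2)

  clot_parameter_row(
    sample_id = "truth", well_id = NA_character_, replicate = NA_integer_,
    baseline = b, lag_time_s = lag, max_abs = max_abs, time_of_max_s = t_max,
    formation_time_s = t_max - lag, t50_lysis_s = t50, t100_lysis_s = t100,
    lysis_area = area, amplitude = max_abs - b,
    flags = paste(flags, collapse = ";")
  )
}

# Shared one-row constructor so the oracle and the extractor emit the same
# schema.
clot_parameter_row <- function(sample_id, well_id, replicate, baseline,
                               lag_time_s = NA_real_, max_abs = NA_real_,
                               time_of_max_s = NA_real_,
                               formation_time_s = NA_real_,
                               t50_lysis_s = NA_real_, t100_lysis_s = NA_real_,
                               lysis_area = NA_real_, amplitude = NA_real_,
                               flags = "") {
  tibble::tibble(
    sample_id = sample_id, well_id = well_id, replicate = replicate,
    baseline = baseline, lag_time_s = lag_time_s, max_abs = max_abs,
    time_of_max_s = time_of_max_s, formation_time_s = formation_time_s,
    t50_lysis_s = t50_lysis_s, t100_lysis_s = t100_lysis_s,
    lysis_area = lysis_area, amplitude = amplitude, flags = flags
  )
}

#' Calibrate curve parameters to a target maximum and lag time
#'
#' Because the formation and lysis logistics overlap, the peak of the product
#' term is slightly below 1; the cohort generator needs curves whose true
#' (oracle) maximum equals a sampled maximum-absorbance value and whose true
#' lag equals a sampled lag time. The amplitude is rescaled by the peak of
#' the product term and the onset solved from the closed-form lag relation,
#' iterating a few times since the onset shifts the peak only marginally.
#'
#' @param target_max Desired curve maximum (AU), must exceed
#'   `baseline_abs + 0.01`.
#' @param target_lag Desired lag time (s).
#' @param baseline_abs,formation_timescale,lysis_timescale Fixed shape
#'   parameters.
#' @param lysis_half_time Elapsed time from (approximate) maximum to the
#'   lysis midpoint (s); controls the 50% lysis time.
#' @return A [curve_gen_params()] object whose dense-grid oracle maximum
#'   matches `target_max` to ~1e-6 AU.
#' @export
calibrate_curve_params <- function(target_max, target_lag,
                                   baseline_abs = 0.05,
                                   formation_timescale = 60,
                                   lysis_timescale = 300,
                                   lysis_half_time = 1200) {
  if (target_max <= baseline_abs + 0.01)
    stop("`target_max` must exceed `baseline_abs` + 0.01 AU", call. = FALSE)
  amp <- target_max - baseline_abs
  onset <- target_lag
  mid <- target_lag + lysis_half_time + 4 * formation_timescale
  for (k in 1:4) {
    onset <- target_lag + formation_timescale * log(amp / 0.01 - 1)
    mid <- max(onset + 4 * formation_timescale + lysis_half_time,
               onset + lysis_timescale)
    p <- curve_gen_params(baseline_abs, amp, onset, formation_timescale,
                          mid, lysis_timescale)
    tt <- seq(0, mid + 8 * lysis_timescale, by = 1)
    cur_max <- max(curve_model(p)(tt))
    amp <- amp * (target_max - baseline_abs) / (cur_max - baseline_abs)
  }
  curve_gen_params(baseline_abs, amp, onset, formation_timescale, mid,
                   lysis_timescale)
}
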