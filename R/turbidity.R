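#' Estimate the pre-clot baseline absorbance
#'
#' Thrombin is added immediately before reading starts, so the earliest
#' readings best represent pre-clot turbidity: the baseline is the mean of
#' the first `n_points` readings (default 3).
#'
#' @param absorbance Absorbance readings (AU), in time order.
#' @param n_points Number of initial readings to average, >= 1.
#' @return Baseline absorbance (AU).
#' @export
estimate_baseline <- function(absorbance, n_points = 3) {
  n_points <- as.integer(n_points)
  if (n_points < 1L || n_points > length(absorbance))
    stop("`n_points` must be between 1 and the curve length", call. = FALSE)
  mean(absorbance[seq_len(n_points)])
}

#' Lag time: first rise of `threshold` AU above baseline
#'
#' Linearly interpolated between the bracketing samples. Returns `NA` when
#' the curve never crosses (no clot formed).
#'
#' @param time Times (s), strictly increasing.
#' @param absorbance Absorbance readings (AU).
#' @param baseline Baseline absorbance (AU).
#' @param threshold Rise defining clot onset (AU), default 0.01.
#' @return Lag time (s) or `NA`.
#' @export
find_lag_time <- function(time, absorbance, baseline, threshold = 0.01) {
  cross_up(time, absorbance, baseline + threshold)
}

#' Maximum absorbance and its time
#'
#' The highest absorbance value recorded on the curve; ties broken by the
#' earliest time.
#'
#' @inheritParams find_lag_time
#' @return A list with `max_abs` (AU) and `time_of_max` (s).
#' @export
find_max <- function(time, absorbance) {
  i <- which.max(absorbance)
  list(max_abs = absorbance[i], time_of_max = time[i])
}

#' Lysis time: elapsed time from the maximum to fractional resolution
#'
#' For `fraction = 0.5`, the time from the maximum until absorbance first
#' falls half-way from the maximum back to baseline (the 50% reduction is
#' taken relative to `max - baseline`, the standard convention for this
#' assay family). For `fraction = 1`, full return to baseline is detected at
#' `baseline + return_tolerance`, symmetric with the lag threshold, since an
#' exact return is unattainable in the presence of noise. Crossings are
#' linearly interpolated. Returns `NA` when the trace ends first.
#'
#' @inheritParams find_lag_time
#' @param fraction Fraction of `max - baseline` that must resolve, in (0, 1].
#' @param return_tolerance Band above baseline counting as full lysis (AU).
#' @return Elapsed time from the maximum (s) or `NA`.
#' @export
find_lysis_time <- function(time, absorbance, baseline, fraction = 0.5,
                            return_tolerance = 0.01) {
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  pk <- find_max(time, absorbance)
  target <- if (fraction >= 1) {
    baseline + return_tolerance
  } else {
    pk$max_abs - fraction * (pk$max_abs - baseline)
  }
  post <- time >= pk$time_of_max
  t_cross <- cross_down(time[post], absorbance[post], target)
  if (is.na(t_cross)) NA_real_ else t_cross - pk$time_of_max
}

#' Clot lysis area
#'
#' Trapezoidal integral of absorbance above baseline from the time of the
#' maximum to the 100% lysis time (or the end of the trace when lysis is
#' censored). Negative excursions below baseline are clipped at zero.
#'
#' @inheritParams find_lysis_time
#' @return A list with `area` (AU*s) and logical `truncated`.
#' @export
#' @param t_end Optional integration end time (s); defaults to the 100%
#'   lysis crossing detected on the raw trace.
lysis_area <- function(time, absorbance, baseline, return_tolerance = 0.01,
                       t_end = NULL) {
  pk <- find_max(time, absorbance)
  truncated <- FALSE
  if (is.null(t_end)) {
    t100 <- find_lysis_time(time, absorbance, baseline, fraction = 1,
                            return_tolerance = return_tolerance)
    truncated <- is.na(t100)
    t_end <- if (truncated) max(time) else pk$time_of_max + t100
  }
  area <- trapz_between(time, pmax(absorbance - baseline, 0),
                        pk$time_of_max, t_end)
  list(area = max(area, 0), truncated = truncated)
}

# Centered moving average used to denoise threshold-crossing detection;
# edges keep the raw readings. window = 1 disables smoothing.
smooth_readings <- function(absorbance, window) {
  window <- as.integer(window)
  if (window <= 1L) return(absorbance)
  if (window %% 2L == 0L) stop("`smooth_window` must be odd", call. = FALSE)
  sm <- as.numeric(stats::filter(absorbance, rep(1 / window, window),
                                 sides = 2))
  edge <- is.na(sm)
  sm[edge] <- absorbance[edge]
  sm
}

# Extraction for one well; vector in, one-row tibble out. Threshold
# crossings (lag, 50%, 100% lysis) are detected on a lightly smoothed trace
# so single noisy readings do not trigger them early; the maximum and the
# area use the raw recorded values.
extract_one <- function(time, absorbance, sample_id, well_id, replicate,
                        baseline_points = 3, lag_threshold = 0.01,
                        return_tolerance = 0.01, smooth_window = 3) {
  if (length(time) < 10L)
    stop("turbidity curve must have at least 10 points", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("curve times must be strictly increasing", call. = FALSE)
  assert_finite(absorbance, "absorbance")

  b <- estimate_baseline(absorbance, baseline_points)
  pk <- find_max(time, absorbance)
  smoothed <- smooth_readings(absorbance, smooth_window)
  lag <- find_lag_time(time, smoothed, b, lag_threshold)

  if (is.na(lag)) {
    return(clot_parameter_row(sample_id, well_id, replicate, baseline = b,
                              max_abs = pk$max_abs, flags = "no_clot"))
  }

  t50 <- find_lysis_time(time, smoothed, b, 0.5, return_tolerance)
  t100 <- find_lysis_time(time, smoothed, b, 1, return_tolerance)
  la <- lysis_area(time, absorbance, b, return_tolerance,
                   t_end = if (is.na(t100)) NULL else pk$time_of_max + t100)
  flags <- character()
  if (is.na(t100)) flags <- c(flags, "no_return_to_baseline")
  if (la$truncated) flags <- c(flags, "truncated")

  clot_parameter_row(
    sample_id, well_id, replicate, baseline = b, lag_time_s = lag,
    max_abs = pk$max_abs, time_of_max_s = pk$time_of_max,
    formation_time_s = pk$time_of_max - lag, t50_lysis_s = t50,
    t100_lysis_s = t100, lysis_area = la$area,
    amplitude = pk$max_abs - b, flags = paste(flags, collapse = ";")
  )
}

#' Extract clot formation and lysis parameters from turbidity curves
#'
#' Composes baseline estimation, lag detection, maximum location, 50%/100%
#' lysis times and the clot lysis area for every curve in a long-format
#' table. Five assay readouts are reported per well: lag time, maximum
#' absorbance, time to 50% lysis, 100% lysis time and clot lysis area; the
#' clot formation time (time of maximum minus lag time) and the
#' baseline-subtracted amplitude are carried along for convenience. Curves
#' that never clot are flagged `no_clot`; traces that end before returning
#' to baseline are flagged `no_return_to_baseline` and their area (to the
#' trace end) flagged `truncated`. Times are in seconds; use
#' [parameters_in_minutes()] for reporting.
#'
#' @param curves Long tibble with columns `time_s`, `abs_340` and any of
#'   `sample_id`, `well_id`, `replicate` identifying individual wells.
#' @param baseline_points Readings averaged for the baseline (default 3).
#' @param lag_threshold Rise above baseline defining the lag time (AU).
#' @param return_tolerance Band above baseline counting as full lysis (AU).
#' @param smooth_window Odd width of the centered moving average applied to
#'   the trace before threshold-crossing detection (default 3; 1 disables).
#'   The maximum and the lysis area always use the raw readings.
#' @return A tibble with one row per well.
#' @examples
#' curve <- generate_curve(curve_gen_params(), time_grid(), noise_sd = 0)
#' extract_parameters(curve)
#' @export
extract_parameters <- function(curves, baseline_points = 3,
                               lag_threshold = 0.01,
                               return_tolerance = 0.01, smooth_window = 3) {
  stopifnot(is.data.frame(curves),
            all(c("time_s", "abs_340") %in% names(curves)))
  keys <- intersect(c("sample_id", "well_id", "replicate"), names(curves))
  if (length(keys) == 0L) {
    curves$well_id <- "well"
    keys <- "well_id"
  }
  curves |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_map(function(d, g) {
      extract_one(
        d$time_s, d$abs_340,
        sample_id = if ("sample_id" %in% names(g)) g$sample_id else NA_character_,
        well_id = if ("well_id" %in% names(g)) g$well_id else NA_character_,
        replicate = if ("replicate" %in% names(g)) as.integer(g$replicate) else NA_integer_,
        baseline_points = baseline_points, lag_threshold = lag_threshold,
        return_tolerance = return_tolerance, smooth_window = smooth_window
      )
    }) |>
    dplyr::bind_rows()
}

#' Average duplicate wells into per-sample clot parameters
#'
#' Samples are assayed in duplicate; numeric parameters are averaged over
#' the unflagged replicates of each sample. Flags raised by any replicate
#' are reported in a `warnings` column rather than propagated as flags. A
#' sample whose replicates are all flagged is a sample-level failure: its
#' numeric outputs are `NA` and the flags are kept.
#'
#' @param params Output of [extract_parameters()].
#' @return A tibble with one row per `sample_id`, plus `n_replicates` and
#'   `n_used`.
#' @export
average_replicates <- function(params) {
  stopifnot(is.data.frame(params), "sample_id" %in% names(params))
  num_cols <- c("baseline", "lag_time_s", "max_abs", "time_of_max_s",
                "formation_time_s", "t50_lysis_s", "t100_lysis_s",
                "lysis_area", "amplitude")
  params |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_map(function(d, g) {
      clean <- d[d$flags == "", , drop = FALSE]
      all_flags <- paste(unique(unlist(strsplit(d$flags[d$flags != ""], ";"))),
                         collapse = ";")
      if (nrow(clean) == 0L) {
        warning("sample ", g$sample_id, ": all replicates flagged (",
                all_flags, ")", call. = FALSE)
        out <- clot_parameter_row(g$sample_id, NA_character_, NA_integer_,
                                  baseline = mean(d$baseline),
                                  flags = all_flags)
      } else {
        if (all_flags != "")
          warning("sample ", g$sample_id, ": flagged replicate(s) dropped (",
                  all_flags, ")", call. = FALSE)
        out <- dplyr::summarise(
          clean,
          sample_id = g$sample_id, well_id = NA_character_,
          replicate = NA_integer_,
          dplyr::across(dplyr::all_of(num_cols), mean),
          flags = ""
        )[, c("sample_id", "well_id", "replicate", num_cols, "flags")]
        out <- tibble::as_tibble(out)
      }
      out$warnings <- all_flags
      out$n_replicates <- nrow(d)
      out$n_used <- nrow(clean)
      out
    }) |>
    dplyr::bind_rows()
}

#' Convert time parameters from seconds to minutes for reporting
#'
#' Lysis times are conventionally reported in minutes although the
#' acquisition grid is in seconds.
#'
#' @param params A clot-parameter tibble (from [extract_parameters()] or
#'   [average_replicates()]).
#' @return The same tibble with `*_s` time columns replaced by `*_min`
#'   columns and lysis area rescaled to AU*min.
#' @export
parameters_in_minutes <- function(params) {
  out <- params
  for (col in c("lag_time_s", "time_of_max_s", "formation_time_s",
                "t50_lysis_s", "t100_lysis_s")) {
    if (col %in% names(out)) {
      new <- sub("_s$", "_min", col)
      out[[new]] <- out[[col]] / 60
      out[[col]] <- NULL
    }
  }
  if ("lysis_area" %in% names(out)) out$lysis_area <- out$lysis_area / 60
  out
}
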