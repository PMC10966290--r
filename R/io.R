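#' Read a wide plate-reader export into long turbidity curves
#'
#' Expects delimited text (comma or tab, autodetected) with one time column
#' (first column) and one column per well, plus a layout file mapping wells
#' to samples: columns `well`, `sample_id`, `replicate`. Well columns absent
#' from the layout are skipped with a warning. Times are converted to
#' seconds; minutes are autodetected from the sampling interval (sub-second
#' spacing with a short total span implies a minutes axis) and can be
#' forced.
#'
#' @param path Plate file path.
#' @param layout_path Layout file path (same delimiter rules).
#' @param time_units `"auto"` (default), `"s"` or `"min"`.
#' @return A long tibble of curves: `sample_id`, `well_id`, `replicate`,
#'   `time_s`, `abs_340`.
#' @export
read_plate_file <- function(path, layout_path,
                            time_units = c("auto", "s", "min")) {
  time_units <- match.arg(time_units)
  plate <- read_delim_auto(path)
  layout <- read_delim_auto(layout_path)
  need <- c("well", "sample_id", "replicate")
  if (!all(need %in% names(layout)))
    stop("layout must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)

  time_col <- names(plate)[1L]
  times <- plate[[time_col]]
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("time column must be finite and strictly increasing", call. = FALSE)
  if (time_units == "auto") {
    # 12-s sampling read in minutes gives 0.2-unit steps over a small span
    time_units <- if (stats::median(diff(times)) < 1 && max(times) < 600)
      "min" else "s"
  }
  if (time_units == "min") times <- times * 60

  wells <- setdiff(names(plate), time_col)
  unmapped <- setdiff(wells, layout$well)
  if (length(unmapped) > 0)
    warning("skipping unmapped well(s): ", paste(unmapped, collapse = ", "),
            call. = FALSE)
  mapped <- intersect(wells, layout$well)
  if (length(mapped) == 0L) stop("no mapped wells in plate file", call. = FALSE)

  purrr::map(mapped, function(w) {
    lay <- layout[layout$well == w, ][1L, ]
    tibble::tibble(
      sample_id = as.character(lay$sample_id), well_id = w,
      replicate = as.integer(lay$replicate),
      time_s = times, abs_340 = plate[[w]]
    )
  }) |>
    dplyr::bind_rows()
}

#' Write turbidity curves as a wide plate file plus layout map
#'
#' Inverse of [read_plate_file()]; all curves must share one time grid.
#'
#' @param curves Long curve tibble (`sample_id`, `well_id`, `replicate`,
#'   `time_s`, `abs_340`).
#' @param path,layout_path Output paths (written as CSV).
#' @return `path`, invisibly.
#' @export
write_plate_file <- function(curves, path, layout_path) {
  stopifnot(is.data.frame(curves),
            all(c("sample_id", "well_id", "replicate", "time_s", "abs_340")
                %in% names(curves)))
  wide <- curves |>
    dplyr::select("well_id", "time_s", "abs_340") |>
    tidyr::pivot_wider(names_from = "well_id", values_from = "abs_340")
  layout <- curves |>
    dplyr::distinct(well = .data$well_id, .data$sample_id, .data$replicate)
  readr::write_csv(wide, path)
  readr::write_csv(layout, layout_path)
  invisible(path)
}

# Comma/tab autodetection on the first line.
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read / write a long-format cohort table
#'
#' One row per subject-period; `period` is restored as a pre/post factor
#' and logical columns are restored from text.
#'
#' @param path Delimited file path (comma or tab).
#' @return A tibble.
#' @export
read_cohort_table <- function(path) {
  d <- read_delim_auto(path)
  if (!all(c("subject_id", "period") %in% names(d)))
    stop("cohort table needs `subject_id` and `period` columns", call. = FALSE)
  d$period <- factor(d$period, levels = c("pre", "post"))
  for (v in intersect(c("male", "smoker", "dysglycemia", "metformin",
                        "statin"), names(d)))
    d[[v]] <- as.logical(d[[v]])
  d
}

#' @rdname read_cohort_table
#' @param records Cohort tibble to write.
#' @export
write_cohort_table <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' YAML key-value file with exactly one of:
#' \describe{
#'   \item{`inputs`}{`plate_file`, `layout_file`, `cohort_file` — paths to
#'     measured data.}
#'   \item{`synthesis`}{`n_subjects`, and optionally `rho`, `phi`,
#'     `replicates`, `noise_sd` — parameters for [cohort_config()].}
#' }
#' plus optional blocks `extraction` (`baseline_points`, `lag_threshold`,
#' `return_tolerance`), `stats` (`alpha`, `continuity_correction`, `reml`),
#' and top-level `seed` and `attrition` (`approached`, `consented`,
#' `post_excluded`, `followup_failures`).
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config A named list with the same structure as the YAML file.
#' @export
as_run_config <- function(config) {
  has_inputs <- !is.null(config$inputs)
  has_synth <- !is.null(config$synthesis)
  if (has_inputs == has_synth)
    stop("run config must have exactly one of `inputs` or `synthesis`",
         call. = FALSE)
  if (has_synth && (is.null(config$synthesis$n_subjects) ||
                    config$synthesis$n_subjects < 2))
    stop("synthesis block needs `n_subjects` >= 2", call. = FALSE)
  config$extraction <- utils::modifyList(
    list(baseline_points = 3, lag_threshold = 0.01, return_tolerance = 0.01),
    config$extraction %||% list())
  config$stats <- utils::modifyList(
    list(alpha = 0.05, continuity_correction = TRUE, reml = TRUE),
    config$stats %||% list())
  config$seed <- config$seed %||% 1L
  structure(config, class = "run_config")
}
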