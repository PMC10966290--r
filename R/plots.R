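#' Plot turbidity curves
#'
#' Absorbance against time, one line per well, optionally facetted by
#' sample. The classic morphology — lag, sigmoidal rise, plateau, lysis —
#' should be visible for any healthy assay run.
#'
#' @param curves Long curve tibble (`time_s`, `abs_340`, identifiers).
#' @param facet Facet by `sample_id` (default when present)?
#' @return A ggplot object.
#' @export
plot_curves <- function(curves, facet = "sample_id" %in% names(curves)) {
  stopifnot(all(c("time_s", "abs_340") %in% names(curves)))
  grp <- if ("well_id" %in% names(curves)) "well_id" else NULL
  p <- ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time_s / 60, y = .data$abs_340,
    group = if (is.null(grp)) 1 else .data$well_id
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Time (min)", y = "Absorbance at 340 nm (AU)") +
    ggplot2::theme_minimal()
  if (facet && "sample_id" %in% names(curves))
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sample_id))
  p
}

#' Paired pre/post dot plot for selected cohort variables
#'
#' One panel per variable: per-subject pre and post values joined by a
#' line, with the period means overlaid — the standard display for a paired
#' biomarker panel.
#'
#' @param records Long cohort tibble.
#' @param variables Character vector of variable names to plot.
#' @return A ggplot object.
#' @export
plot_paired <- function(records, variables = c("max_abs", "lysis_area")) {
  stopifnot(all(variables %in% names(records)))
  long <- records |>
    dplyr::select("subject_id", "period", dplyr::all_of(variables)) |>
    tidyr::pivot_longer(dplyr::all_of(variables), names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                       alpha = 0.3, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
                          colour = "red") +
    ggplot2::facet_wrap(ggplot2::vars(.data$variable), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of an association table
#'
#' Repeated-measures correlation coefficients (with 95% CI) for each
#' covariate against the outcome.
#'
#' @param association Output of [association_table()].
#' @return A ggplot object.
#' @export
plot_association <- function(association) {
  stopifnot(all(c("covariate", "r", "r_conf_low", "r_conf_high")
                %in% names(association)))
  d <- dplyr::filter(association, !is.na(.data$r))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$r, y = stats::reorder(.data$label, .data$r)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$r_conf_low, xmax = .data$r_conf_high),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Repeated-measures correlation (r)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a synthetic cohort
#'
#' Curves for the first few subjects when curves were generated, otherwise
#' the paired clot-parameter panel.
#'
#' @param object A `clot_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clot_cohort <- function(object, ...) {
  if (!is.null(object$curves)) {
    ids <- utils::head(unique(object$curves$sample_id), 4)
    plot_curves(dplyr::filter(object$curves, .data$sample_id %in% ids))
  } else {
    plot_paired(object$records)
  }
}
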