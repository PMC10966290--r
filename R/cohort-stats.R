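#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] (Royston's algorithm) with
#' explicit guards for the sample-size range and degenerate input.
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return A one-row tibble with `statistic` (W) and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::sd(values) < .Machine$double.eps^0.5 * max(1, abs(mean(values))))
    stop("Shapiro-Wilk undefined for (near-)constant input", call. = FALSE)
  ht <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Normality-routed paired comparison
#'
#' The pre/post comparison used throughout the cohort workflow: the paired
#' differences are tested for normality with the Shapiro-Wilk test; a paired
#' Student's t-test is used when normality is not rejected
#' (p > `alpha_normality`), a Wilcoxon matched-pairs signed-rank test
#' otherwise. Normality is assessed on the differences (not each arm
#' separately) because that is the quantity whose distribution the paired
#' t-test assumes. Wilcoxon follows the signed-rank convention: zero
#' differences are dropped, the exact distribution is used for n <= 25
#' without ties, and the tie-corrected normal approximation otherwise. All
#' tests are two-sided.
#'
#' @param pre,post Matched measurement vectors (same subjects, same order),
#'   n >= 3.
#' @param alpha_normality Shapiro-Wilk significance level routing to the
#'   rank test (default 0.05).
#' @param force Optional override of the routing: `"paired_t"` or
#'   `"wilcoxon_signed_rank"`.
#' @return A one-row tibble: `test_used`, `statistic`, `p_value`,
#'   `normality_p`, `pre_mean`, `pre_sd`, `post_mean`, `post_sd`, `n`.
#' @examples
#' set.seed(1)
#' pre <- rnorm(32, 0.43, 0.11)
#' paired_compare(pre, pre - 0.14 + rnorm(32, 0, 0.05))
#' @export
paired_compare <- function(pre, post, alpha_normality = 0.05, force = NULL) {
  if (length(pre) != length(post))
    stop("`pre` and `post` must have equal length", call. = FALSE)
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 3) stop("paired comparison needs n >= 3", call. = FALSE)
  d <- post - pre
  if (all(d == 0))
    stop("all paired differences are zero: no effect to test", call. = FALSE)

  norm_p <- NA_real_
  if (is.null(force)) {
    norm_p <- shapiro_wilk(d)$p_value
    test <- if (norm_p > alpha_normality) "paired_t" else "wilcoxon_signed_rank"
  } else {
    test <- match.arg(force, c("paired_t", "wilcoxon_signed_rank"))
  }

  if (test == "paired_t") {
    ht <- stats::t.test(post, pre, paired = TRUE)
  } else {
    dz <- d[d != 0]
    exact <- length(dz) <= 25 && !any(duplicated(abs(dz)))
    ht <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = exact,
                         correct = TRUE)
    )
  }
  tibble::tibble(
    test_used = test, statistic = unname(ht$statistic),
    p_value = ht$p.value, normality_p = norm_p,
    pre_mean = mean(pre), pre_sd = stats::sd(pre),
    post_mean = mean(post), post_sd = stats::sd(post), n = n
  )
}

#' Chi-squared test for a 2x2 contingency table
#'
#' Pearson chi-squared with Yates continuity correction by default (the
#' correction is required to reproduce conventional small-sample paired
#' cohort reporting), p from the chi-squared distribution with 1 df.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` first group,
#'   `(c, d)` second group.
#' @param continuity_correction Apply the Yates correction (default TRUE)?
#' @return A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi_squared_2x2(20, 12, 5, 27) # strongly dependent
#' @export
chi_squared_2x2 <- function(a, b, c, d, continuity_correction = TRUE) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("both margins of the 2x2 table must be positive", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(m, correct = continuity_correction))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' Pre/post cohort summary with routed paired tests
#'
#' Produces the study-style summary of a paired cohort: for every continuous
#' variable, mean +/- SD per period and the normality-routed paired test
#' ([paired_compare()]); for every dichotomous variable, % (n/N) per period
#' and a Yates-corrected chi-squared test on the 2x2 period-by-state counts;
#' demographic (period-invariant) variables are summarised once without a
#' test. Subjects missing either period are excluded with a warning. Row
#' order follows the variable-table groups (demographics, then the clinical
#' table, then the clot/biomarker panel).
#'
#' @param records Long cohort tibble: `subject_id`, `period` (pre/post) and
#'   measurement columns, one row per subject-period.
#' @param variables Variable metadata as in [cohort_variable_defaults()];
#'   used for labels, units and ordering. Variables absent from `records`
#'   are skipped.
#' @param continuity_correction Passed to [chi_squared_2x2()].
#' @return A tibble with one row per summarised variable.
#' @export
summarize_cohort <- function(records, variables = cohort_variable_defaults(),
                             continuity_correction = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "period") %in% names(records)))
  counts <- table(records$subject_id)
  complete <- names(counts)[counts == 2L]
  dropped <- setdiff(unique(records$subject_id), complete)
  if (length(dropped) > 0)
    warning("excluding subject(s) without both periods: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  records <- records[records$subject_id %in% complete, , drop = FALSE]
  records <- dplyr::arrange(records, .data$subject_id, .data$period)
  pre <- records[records$period == "pre", , drop = FALSE]
  post <- records[records$period == "post", , drop = FALSE]
  n_subj <- nrow(pre)

  dich <- attr(variables, "dichotomous") %||%
    attr(cohort_variable_defaults(), "dichotomous")

  cont_rows <- variables |>
    dplyr::filter(.data$variable %in% names(records)) |>
    purrr::pmap(function(...) {
      row <- tibble::tibble(...)
      x_pre <- pre[[row$variable]]
      x_post <- post[[row$variable]]
      base <- tibble::tibble(
        variable = row$variable, label = row$label, unit = row$unit,
        group = row$group,
        type = if (row$period_invariant) "demographic" else "continuous",
        pre_mean = mean(x_pre), pre_sd = stats::sd(x_pre),
        post_mean = mean(x_post), post_sd = stats::sd(x_post),
        n = n_subj
      )
      if (row$period_invariant) {
        dplyr::mutate(base, test_used = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      note = NA_character_)
      } else {
        res <- tryCatch(paired_compare(x_pre, x_post),
                        error = function(e) conditionMessage(e))
        if (is.character(res)) {
          dplyr::mutate(base, test_used = "error", statistic = NA_real_,
                        p_value = NA_real_, note = res)
        } else {
          dplyr::mutate(base, test_used = res$test_used,
                        statistic = res$statistic, p_value = res$p_value,
                        note = NA_character_)
        }
      }
    }) |>
    dplyr::bind_rows()

  dich_rows <- dich |>
    dplyr::filter(.data$variable %in% names(records)) |>
    purrr::pmap(function(...) {
      row <- tibble::tibble(...)
      x_pre <- as.logical(pre[[row$variable]])
      x_post <- as.logical(post[[row$variable]])
      base <- tibble::tibble(
        variable = row$variable, label = row$label, unit = "% (n/N)",
        group = row$group,
        type = if (row$period_invariant) "demographic" else "dichotomous",
        pre_pct = 100 * mean(x_pre), pre_n = sum(x_pre),
        post_pct = 100 * mean(x_post), post_n = sum(x_post),
        n = n_subj
      )
      if (row$period_invariant) {
        dplyr::mutate(base, test_used = NA_character_,
                      statistic = NA_real_, p_value = NA_real_,
                      note = NA_character_)
      } else {
        res <- tryCatch(
          chi_squared_2x2(sum(x_pre), n_subj - sum(x_pre),
                          sum(x_post), n_subj - sum(x_post),
                          continuity_correction = continuity_correction),
          error = function(e) conditionMessage(e))
        if (is.character(res)) {
          dplyr::mutate(base, test_used = "error", statistic = NA_real_,
                        p_value = NA_real_, note = res)
        } else {
          dplyr::mutate(base, test_used = "chi_squared",
                        statistic = res$statistic, p_value = res$p_value,
                        note = NA_character_)
        }
      }
    }) |>
    dplyr::bind_rows()

  dplyr::bind_rows(cont_rows, dich_rows) |>
    dplyr::arrange(factor(.data$group,
                          levels = c("demographic", "table1", "fig2b")))
}

#' Recruitment and attrition accounting
#'
#' Stage-wise rates for a recruitment funnel: recruitment % =
#' consented/approached; each attrition % = losses among that stage's
#' entrants; final analysed N after all losses.
#'
#' @param approached Patients approached.
#' @param consented Patients recruited and consented.
#' @param post_excluded Post-operative exclusions among the consented.
#' @param followup_failures Failures to provide a valid follow-up sample
#'   among those remaining.
#' @return A tibble with one row per stage: `stage`, `n_entered`, `n_lost`,
#'   `rate_pct` (recruitment or attrition rate of that stage), plus a final
#'   `analyzed` row.
#' @examples
#' attrition_report(119, 63, 16, 15)
#' @export
attrition_report <- function(approached, consented, post_excluded,
                             followup_failures) {
  counts <- c(approached, consented, post_excluded, followup_failures)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and >= 0", call. = FALSE)
  if (consented > approached)
    stop("`consented` cannot exceed `approached`", call. = FALSE)
  remaining <- consented - post_excluded
  analyzed <- remaining - followup_failures
  if (post_excluded > consented || followup_failures > remaining ||
      analyzed < 0)
    stop("losses exceed stage entrants", call. = FALSE)
  tibble::tibble(
    stage = c("recruitment", "postoperative_exclusion", "followup_attrition",
              "analyzed"),
    n_entered = c(approached, consented, remaining, analyzed),
    n_lost = c(approached - consented, post_excluded, followup_failures, 0),
    rate_pct = c(100 * consented / approached,
                 100 * post_excluded / consented,
                 100 * followup_failures / remaining,
                 NA_real_)
  )
}
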