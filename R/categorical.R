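# Categorical (outlier) analyses of ECG parameters: absolute QTc
# thresholds, change-from-baseline thresholds, and compound PR/QRS rules.

#' Threshold flags for corrected ECG observations
#'
#' Applies the standard thorough-QT categorical rules with strict
#' inequalities:
#' * absolute QTc > 450, > 480, > 500 ms (per correction method);
#' * change from time-matched baseline in QTc > 30, > 60 ms;
#' * PR > 200 ms AND > 25% above baseline;
#' * QRS > 110 ms AND > 25% above baseline.
#'
#' Relative (25%) rules use the time-matched Day -1 value; when that time
#' is missing from the baseline day the subject's Day -1 mean is used
#' instead.  Missing baselines leave the relative flags `NA` while the
#' absolute flags are still computed.
#'
#' @param points replicate-averaged points for drug days with QTc columns
#'   (e.g. `QTcI`, `QTcF`) plus `pr_ms`, `qrs_ms`.
#' @param deltas change-from-baseline table from [time_matched_delta()]
#'   for the QTc metrics.
#' @param baseline_points replicate-averaged Day -1 points (for the
#'   relative PR/QRS rules).
#' @param methods QTc correction columns to flag.
#' @param thresholds named list overriding the default cut-offs
#'   (`qtc_abs`, `dqtc`, `pr_ms`, `qrs_ms`, `rel_increase`).
#' @return tidy flags tibble, one row per subject/day/time/method.
#' @export
flag_observations <- function(points, deltas, baseline_points,
                              methods = c("QTcI", "QTcF"),
                              thresholds = list()) {
  th <- utils::modifyList(
    list(qtc_abs = c(450, 480, 500), dqtc = c(30, 60),
         pr_ms = 200, qrs_ms = 110, rel_increase = 0.25),
    thresholds)
  methods <- intersect(methods, names(points))
  drug <- points[points$day != -1, , drop = FALSE]

  base_tm <- baseline_points |>
    dplyr::select("subject_id", "time_h", pr_base = "pr_ms",
                  qrs_base = "qrs_ms")
  base_mean <- baseline_points |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(pr_base_mean = mean(.data$pr_ms, na.rm = TRUE),
                     qrs_base_mean = mean(.data$qrs_ms, na.rm = TRUE),
                     .groups = "drop")
  drug <- drug |>
    dplyr::left_join(base_tm, by = c("subject_id", "time_h")) |>
    dplyr::left_join(base_mean, by = "subject_id") |>
    dplyr::mutate(pr_base = dplyr::coalesce(.data$pr_base, .data$pr_base_mean),
                  qrs_base = dplyr::coalesce(.data$qrs_base, .data$qrs_base_mean))

  delta_wide <- deltas |>
    dplyr::filter(.data$metric %in% methods) |>
    dplyr::select("subject_id", "day", "time_h", "metric", "delta") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "delta",
                       names_prefix = "d_")

  rows <- lapply(methods, function(m) {
    qtc <- drug[[m]]
    d_col <- paste0("d_", m)
    dd <- dplyr::left_join(
      drug[, c("subject_id", "day", "time_h", "pr_ms", "qrs_ms",
               "pr_base", "qrs_base")],
      delta_wide[, c("subject_id", "day", "time_h",
                     intersect(d_col, names(delta_wide)))],
      by = c("subject_id", "day", "time_h"))
    dqtc <- if (d_col %in% names(dd)) dd[[d_col]] else NA_real_
    tibble::tibble(
      subject_id = dd$subject_id, day = dd$day, time_h = dd$time_h,
      method = m,
      qtc_gt_450 = qtc > th$qtc_abs[1],
      qtc_gt_480 = qtc > th$qtc_abs[2],
      qtc_gt_500 = qtc > th$qtc_abs[3],
      dqtc_gt_30 = dqtc > th$dqtc[1],
      dqtc_gt_60 = dqtc > th$dqtc[2],
      pr_flag = dd$pr_ms > th$pr_ms &
        dd$pr_ms > (1 + th$rel_increase) * dd$pr_base,
      qrs_flag = dd$qrs_ms > th$qrs_ms &
        dd$qrs_ms > (1 + th$rel_increase) * dd$qrs_base)
  })
  dplyr::bind_rows(rows) |>
    dplyr::distinct(.data$subject_id, .data$day, .data$time_h, .data$method,
                    .keep_all = TRUE)
}

#' Heart-rate eligibility screening flags
#'
#' Resting heart rate outside the protocol's eligibility bounds
#' (below 50 or above 100 bpm).  These are screening flags, not outlier
#' categories, and do not enter the incidence tables.
#'
#' @param points replicate-averaged points with `hr_bpm`.
#' @param low,high eligibility bounds (bpm).
#' @return `points` with logical columns `hr_below_low`, `hr_above_high`.
#' @export
screening_flags <- function(points, low = 50, high = 100) {
  points$hr_below_low <- points$hr_bpm < low
  points$hr_above_high <- points$hr_bpm > high
  points
}

#' Incidence table of categorical flags
#'
#' Counts, per day and correction method, the number and percentage of
#' subjects with at least one flagged observation in each category.  The
#' default denominator is the number of subjects with any observation on
#' that day.
#'
#' @param flags output of [flag_observations()].
#' @param denominators optional tibble (`day`, `n_total`) overriding the
#'   per-day denominator.
#' @return tidy tibble `method`, `day`, `category`, `n_flagged`,
#'   `n_total`, `pct`.
#' @export
tabulate_flags <- function(flags, denominators = NULL) {
  cats <- c("qtc_gt_450", "qtc_gt_480", "qtc_gt_500",
            "dqtc_gt_30", "dqtc_gt_60", "pr_flag", "qrs_flag")
  flags <- dplyr::distinct(flags, .data$subject_id, .data$day, .data$time_h,
                           .data$method, .keep_all = TRUE)
  denom <- denominators %||% (flags |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(n_total = dplyr::n_distinct(.data$subject_id),
                     .groups = "drop"))
  flags |>
    tidyr::pivot_longer(dplyr::all_of(cats), names_to = "category",
                        values_to = "flag") |>
    dplyr::group_by(.data$method, .data$day, .data$category) |>
    dplyr::summarise(
      n_flagged = dplyr::n_distinct(.data$subject_id[.data$flag %in% TRUE]),
      .groups = "drop") |>
    dplyr::left_join(denom, by = "day") |>
    dplyr::mutate(pct = 100 * .data$n_flagged / .data$n_total)
}
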