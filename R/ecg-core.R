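# Replicate averaging, QT correction and time-matched baseline changes.
#
# Conventions: RR in seconds, QT/QTc/PR/QRS in ms, HR in bpm (derived as
# 60/RR when absent).  Corrections are always applied to the
# replicate-averaged point; the individual exponent is estimated from
# replicate-level pairs.

#' Fridericia-corrected QT
#'
#' `QTcF = QT / RR^(1/3)` with RR in seconds.
#'
#' @param qt_ms QT interval (ms).
#' @param rr_s RR interval (s); must be positive.
#' @return QTcF (ms).
#' @export
#' @examples
#' qtc_fridericia(400, 1)     # 400
#' qtc_fridericia(360, 0.729) # 400: 0.729^(1/3) = 0.9
qtc_fridericia <- function(qt_ms, rr_s) {
  if (any(rr_s <= 0, na.rm = TRUE)) {
    stop("RR must be positive (seconds)", call. = FALSE)
  }
  qt_ms / rr_s^(1 / 3)
}

#' Bazett-corrected QT
#'
#' `QTcB = QT / RR^(1/2)`, offered as an optional third correction method.
#'
#' @inheritParams qtc_fridericia
#' @return QTcB (ms).
#' @export
qtc_bazett <- function(qt_ms, rr_s) {
  if (any(rr_s <= 0, na.rm = TRUE)) {
    stop("RR must be positive (seconds)", call. = FALSE)
  }
  qt_ms / sqrt(rr_s)
}

#' Individually corrected QT
#'
#' `QTcI = QT / RR^b` with a subject-specific exponent `b` (see
#' [estimate_individual_exponent()]).
#'
#' @inheritParams qtc_fridericia
#' @param b subject exponent.
#' @return QTcI (ms).
#' @export
qtc_individual <- function(qt_ms, rr_s, b) {
  if (any(rr_s <= 0, na.rm = TRUE)) {
    stop("RR must be positive (seconds)", call. = FALSE)
  }
  qt_ms / rr_s^b
}

#' Average same-time ECG replicates into one observation
#'
#' Each numeric field is the arithmetic mean of the non-missing replicate
#' values; the number of replicates averaged is recorded.
#'
#' @param replicates data frame of replicate rows sharing one
#'   subject/day/time, with columns `subject_id`, `day`, `time_h` and any
#'   of `qt_ms`, `rr_s`, `hr_bpm`, `pr_ms`, `qrs_ms`.
#' @return one-row tibble with the averaged fields plus `n_replicates`.
#' @export
average_replicates <- function(replicates) {
  if (is.null(replicates) || nrow(replicates) == 0L) {
    stop("no replicates supplied", call. = FALSE)
  }
  key <- unique(replicates[, c("subject_id", "day", "time_h")])
  if (nrow(key) != 1L) {
    stop("replicates span more than one subject/day/time", call. = FALSE)
  }
  vals <- c("qt_ms", "rr_s", "hr_bpm", "pr_ms", "qrs_ms")
  out <- key
  for (v in vals) {
    out[[v]] <- if (v %in% names(replicates)) {
      mean(replicates[[v]], na.rm = TRUE)
    } else NA_real_
  }
  out$n_replicates <- nrow(replicates)
  tibble::as_tibble(out)
}

# Vectorised replicate averaging over a whole replicate-level table.
average_all_replicates <- function(ecg) {
  ecg |>
    dplyr::group_by(.data$subject_id, .data$day, .data$time_h) |>
    dplyr::summarise(dplyr::across(dplyr::any_of(
      c("qt_ms", "rr_s", "hr_bpm", "pr_ms", "qrs_ms")),
      ~ mean(.x, na.rm = TRUE)),
      n_replicates = dplyr::n(), .groups = "drop")
}

#' Estimate a subject's individual QT/RR exponent
#'
#' Ordinary least-squares regression of `log(QT)` on `log(RR)` over the
#' supplied drug-free pairs (replicate level, not triplicate means); the
#' slope is the exponent `b` of `QTcI = QT/RR^b`.  The power law is
#' linear on the log-log scale, which is where the regression is run.
#'
#' @param qt_ms,rr_s replicate-level drug-free QT (ms) and RR (s) pairs.
#' @param subject_id optional identifier carried into the result.
#' @return tibble with `subject_id`, `exponent_b`, `n_pairs`, `r_squared`.
#' @export
estimate_individual_exponent <- function(qt_ms, rr_s, subject_id = NA_character_) {
  keep <- is.finite(qt_ms) & is.finite(rr_s) & qt_ms > 0 & rr_s > 0
  qt_ms <- qt_ms[keep]; rr_s <- rr_s[keep]
  if (length(qt_ms) < 2L) {
    stop("need at least 2 (QT, RR) pairs to estimate the exponent",
         call. = FALSE)
  }
  if (max(rr_s) - min(rr_s) < 1e-12) {
    stop("all RR values identical: exponent fit is singular", call. = FALSE)
  }
  fit <- stats::lm(log(qt_ms) ~ log(rr_s))
  lq <- log(qt_ms)
  r2 <- if (stats::var(lq) > 0) {
    1 - sum(stats::residuals(fit)^2) / sum((lq - mean(lq))^2)
  } else NA_real_
  tibble::tibble(subject_id = subject_id,
                 exponent_b = unname(stats::coef(fit)[2L]),
                 n_pairs = length(qt_ms),
                 r_squared = r2)
}

# Baseline pairs for the exponent fit: all Day -1 replicates plus the
# Day 1 predose (0 h) replicates.
baseline_pairs <- function(ecg) {
  ecg[ecg$day == -1 | (ecg$day == 1 & ecg$time_h == 0), , drop = FALSE]
}

#' Per-subject individual correction exponents for a cohort
#'
#' Applies [estimate_individual_exponent()] to every subject's drug-free
#' pairs: all Day -1 replicates together with the Day 1 predose (0 h)
#' replicates.
#'
#' @param ecg replicate-level ECG table (`subject_id`, `day`, `time_h`,
#'   `replicate`, `qt_ms`, `rr_s`, ...).
#' @return tibble of per-subject corrections.
#' @export
estimate_cohort_exponents <- function(ecg) {
  base <- baseline_pairs(ecg)
  base |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(~ estimate_individual_exponent(
      .x$qt_ms, .x$rr_s)[, c("exponent_b", "n_pairs", "r_squared")]) |>
    dplyr::ungroup()
}

#' Replicate-average and correct a cohort's ECG data
#'
#' Averages triplicates per subject/day/time, then applies the requested
#' QT corrections to the averaged point (correction after averaging is
#' the pipeline's fixed order).  The individual exponent is estimated per
#' subject from drug-free replicate pairs.
#'
#' @param ecg replicate-level ECG table.
#' @param methods corrections to compute, subset of
#'   `c("QTcI", "QTcF", "QTcB")`.
#' @return list with `points` (averaged points plus one column per
#'   correction) and `corrections` (per-subject exponent table; only when
#'   QTcI requested).
#' @export
correct_ecg <- function(ecg, methods = c("QTcI", "QTcF")) {
  methods <- match.arg(methods, c("QTcI", "QTcF", "QTcB"), several.ok = TRUE)
  pts <- average_all_replicates(ecg)
  corrections <- NULL
  if ("QTcF" %in% methods) pts$QTcF <- qtc_fridericia(pts$qt_ms, pts$rr_s)
  if ("QTcB" %in% methods) pts$QTcB <- qtc_bazett(pts$qt_ms, pts$rr_s)
  if ("QTcI" %in% methods) {
    corrections <- estimate_cohort_exponents(ecg)
    pts <- dplyr::left_join(
      pts, corrections[, c("subject_id", "exponent_b")], by = "subject_id")
    pts$QTcI <- qtc_individual(pts$qt_ms, pts$rr_s, pts$exponent_b)
    pts$exponent_b <- NULL
  }
  list(points = pts, corrections = corrections)
}

#' Time-matched changes from the baseline day
#'
#' For each metric, subtracts the subject's Day -1 value from the
#' drug-day value at the same nominal time.  Drug-day times without a
#' baseline counterpart are dropped (and reported in the `dropped`
#' attribute), mirroring how a 24 h Day 1 point has no Day 10 partner.
#'
#' @param points replicate-averaged (and corrected) points, long or wide;
#'   must contain `subject_id`, `day`, `time_h` plus the metric columns.
#' @param metrics column names to difference (e.g. `c("QTcI", "QTcF",
#'   "hr_bpm")`).
#' @param baseline_day study day serving as baseline (default -1).
#' @return tidy tibble `subject_id`, `day`, `time_h`, `metric`, `delta`,
#'   with dropped (unmatched) drug-day points in `attr(, "dropped")`.
#' @export
time_matched_delta <- function(points, metrics = c("QTcI", "QTcF"),
                               baseline_day = -1) {
  metrics <- intersect(metrics, names(points))
  if (length(metrics) == 0L) stop("no requested metric present", call. = FALSE)
  long <- points |>
    dplyr::select(dplyr::all_of(c("subject_id", "day", "time_h", metrics))) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value")
  base <- long |>
    dplyr::filter(.data$day == baseline_day) |>
    dplyr::select("subject_id", "time_h", "metric", baseline = "value")
  drug <- dplyr::filter(long, .data$day != baseline_day)
  joined <- dplyr::left_join(drug, base,
                             by = c("subject_id", "time_h", "metric"))
  dropped <- joined |>
    dplyr::filter(is.na(.data$baseline)) |>
    dplyr::select("subject_id", "day", "time_h", "metric")
  out <- joined |>
    dplyr::filter(!is.na(.data$baseline)) |>
    dplyr::mutate(delta = .data$value - .data$baseline) |>
    dplyr::select("subject_id", "day", "time_h", "metric", "delta",
                  "baseline", "value")
  attr(out, "dropped") <- dropped
  out
}
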