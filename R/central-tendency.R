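# Central-tendency analysis of time-matched baseline changes: a
# repeated-measures mixed model with day-by-time cells and one-sided 95%
# upper confidence bounds on the least-squares means.

#' Repeated-measures analysis of baseline changes
#'
#' Fits, per metric, a linear mixed model with a fixed effect for every
#' day-by-time cell and a random subject intercept (compound symmetry),
#' estimated by REML.  Inference is on the least-squares (cell) means;
#' for each cell a one-sided upper confidence bound
#' `LS mean + t(level, df) * SE` is reported with containment degrees of
#' freedom (subjects in the cell minus one).  Days are modelled jointly.
#'
#' On balanced complete data the LS means equal the raw cell means.  When
#' the response is degenerate (zero variance) the model collapses to the
#' cell means with zero SE.
#'
#' @param deltas tidy change-from-baseline table (`subject_id`, `day`,
#'   `time_h`, `metric`, `delta`), e.g. from [time_matched_delta()].
#' @param level one-sided confidence level for the upper bound.
#' @return tibble `metric`, `day`, `time_h`, `n`, `ls_mean`, `se`, `df`,
#'   `ucb`.
#' @export
fit_repeated_measures <- function(deltas, level = 0.95) {
  stopifnot(all(c("subject_id", "day", "time_h", "metric", "delta") %in%
                  names(deltas)))
  deltas <- deltas[is.finite(deltas$delta), , drop = FALSE]
  if (nrow(deltas) == 0L) stop("no change-from-baseline data", call. = FALSE)
  out <- lapply(split(deltas, deltas$metric), function(dd) {
    cells <- dd |>
      dplyr::distinct(.data$day, .data$time_h) |>
      dplyr::arrange(.data$day, .data$time_h)
    dd$cell <- factor(paste(dd$day, dd$time_h, sep = "@"),
                      levels = paste(cells$day, cells$time_h, sep = "@"))
    cell_n <- dd |>
      dplyr::group_by(.data$cell) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$subject_id),
                       .groups = "drop")

    est <- NULL
    if (stats::sd(dd$delta) > 1e-10 && dplyr::n_distinct(dd$subject_id) >= 2L) {
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(delta ~ 0 + cell + (1 | subject_id), data = dd,
                     REML = TRUE))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cf <- summary(fit)$coefficients
        est <- tibble::tibble(
          cell = sub("^cell", "", rownames(cf)),
          ls_mean = cf[, "Estimate"], se = cf[, "Std. Error"])
      }
    }
    if (is.null(est)) {
      # degenerate or tiny data: per-cell one-sample summary
      est <- dd |>
        dplyr::group_by(cell = as.character(.data$cell)) |>
        dplyr::summarise(
          ls_mean = mean(.data$delta),
          se = if (dplyr::n() > 1L) {
            stats::sd(.data$delta) / sqrt(dplyr::n())
          } else 0,
          .groups = "drop")
      est$se[!is.finite(est$se)] <- 0
    }
    est <- dplyr::inner_join(est,
                             dplyr::mutate(cell_n, cell = as.character(.data$cell)),
                             by = "cell")
    parts <- strsplit(est$cell, "@", fixed = TRUE)
    tibble::tibble(
      metric = dd$metric[1L],
      day = as.numeric(vapply(parts, `[[`, "", 1L)),
      time_h = as.numeric(vapply(parts, `[[`, "", 2L)),
      n = est$n,
      ls_mean = est$ls_mean,
      se = est$se,
      df = pmax(est$n - 1L, 1L),
      ucb = est$ls_mean +
        stats::qt(level, pmax(est$n - 1L, 1L)) * est$se)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$metric, .data$day, .data$time_h)
}

#' Planned one-sided upper-confidence-bound half-width
#'
#' The design-stage width `z_level * sd / sqrt(n)` of a one-sided upper
#' confidence bound on a mean change, using the standard normal quantile
#' (the planning approximation).
#'
#' @param sd assumed SD of the change from baseline (ms).
#' @param n number of subjects.
#' @param level one-sided confidence level.
#' @return half-width in the units of `sd`.
#' @export
#' @examples
#' plan_ucb_halfwidth(9, 36)  # 2.47 ms
plan_ucb_halfwidth <- function(sd, n, level = 0.95) {
  stopifnot_scalar(sd, "sd", nonneg = TRUE)
  stopifnot_scalar(n, "n", positive = TRUE)
  stats::qnorm(level) * sd / sqrt(n)
}

#' Apply the steady-state evaluability rule
#'
#' Restricts a drug-day dataset to subjects flagged as having received
#' the minimum run of dosing days before the steady-state ECG day.
#'
#' @param data any table with a `subject_id` column.
#' @param subjects subject table with `evaluable_day10`.
#' @param day10 study day the rule protects (rows with `day` equal to it
#'   are filtered; other rows pass through).
#' @return filtered table.
#' @export
apply_evaluability <- function(data, subjects, day10 = 10) {
  if (!"evaluable_day10" %in% names(subjects)) return(data)
  ok <- subjects$subject_id[subjects$evaluable_day10]
  if (!"day" %in% names(data)) {
    return(data[data$subject_id %in% ok, , drop = FALSE])
  }
  data[data$day != day10 | data$subject_id %in% ok, , drop = FALSE]
}
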