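# End-to-end assembly: ECG correction -> central tendency and categorical
# analyses -> NCA -> concentration-QTc hierarchy -> effect simulation.

#' Build the concentration-response dataset
#'
#' Merges change-from-baseline records with the time-matched parent drug
#' concentration (same subject, day and nominal time) and any subject
#' covariates.  Day 1 predose records are excluded (the predose
#' extraction belongs to the drug-free baseline); records without a
#' concentration sample at the matched time are dropped.
#'
#' @param deltas change-from-baseline table from [time_matched_delta()].
#' @param pk concentration table (parent analyte rows are used).
#' @param subjects optional covariate table (`subject_id`, `sex`, `bmi`,
#'   `ecog`).
#' @param metric which delta metric to model (e.g. `"QTcI"`).
#' @return tibble `subject_id`, `conc_nM`, `value` (+ covariates).
#' @export
make_cqt_data <- function(deltas, pk, subjects = NULL, metric = "QTcI") {
  parent <- pk[pk$analyte == "parent" & is.finite(pk$conc_nM),
               c("subject_id", "day", "time_h", "conc_nM")]
  dd <- deltas[deltas$metric == metric &
                 !(deltas$day == 1 & deltas$time_h == 0), , drop = FALSE]
  out <- dplyr::inner_join(
    dd[, c("subject_id", "day", "time_h", "delta")], parent,
    by = c("subject_id", "day", "time_h")) |>
    dplyr::rename(value = "delta")
  if (!is.null(subjects)) {
    out <- dplyr::left_join(
      out, subjects[, intersect(c("subject_id", "sex", "bmi", "ecog"),
                                names(subjects))],
      by = "subject_id")
  }
  out
}

#' Heart-rate dataset for the concentration-HR model
#'
#' By default uses the time-matched change in heart rate from the
#' baseline day, matched to the parent concentration: subtracting the
#' same-clock-time baseline removes the circadian HR swing, which would
#' otherwise be partly collinear with the post-dose concentration
#' profile and masquerade as a drug effect.  `type = "absolute"` gives
#' the raw heart rate instead (baseline-day records entering at
#' concentration zero), whose intercept estimates the population HR.
#'
#' @param points replicate-averaged ECG points with `hr_bpm`.
#' @param pk concentration table.
#' @param type `"delta"` (time-matched change) or `"absolute"`.
#' @return tibble `subject_id`, `conc_nM`, `value`.
#' @export
make_hr_data <- function(points, pk, type = c("delta", "absolute")) {
  type <- match.arg(type)
  parent <- pk[pk$analyte == "parent" & is.finite(pk$conc_nM),
               c("subject_id", "day", "time_h", "conc_nM")]
  if (type == "delta") {
    d <- time_matched_delta(points, metrics = "hr_bpm")
    d <- d[!(d$day == 1 & d$time_h == 0), , drop = FALSE]
    out <- dplyr::inner_join(d[, c("subject_id", "day", "time_h", "delta")],
                             parent, by = c("subject_id", "day", "time_h"))
    return(dplyr::tibble(subject_id = out$subject_id,
                         conc_nM = out$conc_nM, value = out$delta))
  }
  pts <- points[, c("subject_id", "day", "time_h", "hr_bpm")]
  out <- dplyr::left_join(pts, parent,
                          by = c("subject_id", "day", "time_h"))
  out$conc_nM[out$day == -1] <- 0
  out <- out[is.finite(out$conc_nM) & is.finite(out$hr_bpm), , drop = FALSE]
  dplyr::tibble(subject_id = out$subject_id, conc_nM = out$conc_nM,
                value = out$hr_bpm)
}

#' Run the full cardiodynamic analysis pipeline
#'
#' Executes every stage on the configured inputs: replicate averaging
#' and QT correction, time-matched baseline changes, the
#' repeated-measures central-tendency analysis with one-sided upper
#' confidence bounds, categorical threshold analyses,
#' non-compartmental PK with a summary table, the concentration-QTc
#' structural hierarchy with model selection, covariate screening and
#' subject-resampling bootstrap, the concentration-HR model, and the
#' effect-size simulation at the reference concentration.  Report tables
#' are written to `config$out_dir` when set, together with a run log.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional in-memory `cqt_cohort` (overrides the
#'   configured CSV paths).
#' @return list of class `cqt_report` with every stage's output.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("cqtr pipeline run: %s", format(Sys.time())),
                 sprintf("bootstrap seed: %s; simulation seed: %s",
                         config$bootstrap_seed, config$sim_seed))
  if (!is.null(cohort)) {
    ecg <- cohort$ecg; pk <- cohort$pk; subjects <- cohort$subjects
  } else {
    if (is.null(config$ecg_csv) || is.null(config$pk_csv)) {
      stop("config must provide ecg_csv and pk_csv (or pass a cohort)",
           call. = FALSE)
    }
    ecg <- read_ecg_csv(config$ecg_csv)
    pk <- read_pk_csv(config$pk_csv)
    subjects <- if (!is.null(config$subjects_csv)) {
      tibble::as_tibble(utils::read.csv(config$subjects_csv,
                                        stringsAsFactors = FALSE))
    } else NULL
  }

  # --- ECG correction and baseline changes ---------------------------------
  corrected <- correct_ecg(ecg, methods = config$methods)
  pts <- corrected$points
  metrics <- c(config$methods, "hr_bpm", "pr_ms", "qrs_ms")
  deltas <- time_matched_delta(pts, metrics = metrics)
  dropped <- attr(deltas, "dropped")
  if (nrow(dropped) > 0L) {
    log_lines <- c(log_lines, sprintf(
      "dropped %d drug-day records without a time-matched baseline",
      nrow(dropped)))
  }
  deltas_ct <- deltas[!(deltas$day == 1 & deltas$time_h == 0), , drop = FALSE]
  if (!is.null(subjects)) {
    n_before <- nrow(deltas_ct)
    deltas_ct <- apply_evaluability(deltas_ct, subjects)
    if (nrow(deltas_ct) < n_before) {
      log_lines <- c(log_lines, sprintf(
        "evaluability rule removed %d Day-10 records", n_before - nrow(deltas_ct)))
    }
  }

  # --- central tendency ----------------------------------------------------
  central <- fit_repeated_measures(deltas_ct)

  # --- categorical ---------------------------------------------------------
  flags <- flag_observations(pts, deltas, pts[pts$day == -1, , drop = FALSE],
                             methods = config$methods,
                             thresholds = config$thresholds)
  incidence <- tabulate_flags(flags)

  # --- NCA -----------------------------------------------------------------
  nca <- run_nca(pk)
  nca_tab <- nca_summary(nca)

  # --- concentration-QTc ---------------------------------------------------
  primary_metric <- config$methods[1L]
  cqt_data <- make_cqt_data(deltas_ct, pk, subjects, metric = primary_metric)
  hierarchy <- fit_cqt_hierarchy(cqt_data, alpha = config$selection_alpha)
  final <- hierarchy$final
  log_lines <- c(log_lines, paste("model selection:", attr(final, "rationale")))

  boot <- NULL
  if (config$bootstrap_B >= 1) {
    boot <- bootstrap_cqt(final, B = config$bootstrap_B,
                          seed = config$bootstrap_seed)
  }
  screening <- NULL
  if (!is.null(subjects) &&
      all(c("sex", "bmi", "ecog") %in% names(cqt_data))) {
    screening <- tryCatch(
      screen_covariates(cqt_data, form = final$form,
                        alpha = config$covariate_alpha),
      error = function(e) {
        log_lines <<- c(log_lines,
                        paste("covariate screening skipped:",
                              conditionMessage(e)))
        NULL
      })
    if (!is.null(screening) && length(screening$skipped) > 0L) {
      log_lines <- c(log_lines, paste("constant covariates skipped:",
                                      paste(screening$skipped, collapse = ", ")))
    }
  }
  hr_data <- make_hr_data(pts, pk)
  hr_hier <- fit_cqt_hierarchy(hr_data, forms = c("no_effect", "linear"),
                               alpha = config$selection_alpha)

  # --- effect simulation ---------------------------------------------------
  sim <- simulate_population(final, config$sim_conc_nM, n = config$sim_n,
                             seed = config$sim_seed,
                             thresholds = config$thresholds$dqtc)

  report <- structure(list(
    points = pts, corrections = corrected$corrections,
    deltas = deltas, central_tendency = central,
    flags = flags, incidence = incidence,
    nca = nca, nca_summary = nca_tab,
    cqt_data = cqt_data, cqt_fits = hierarchy$fits, cqt_final = final,
    bootstrap = boot, covariate_screen = screening,
    hr_final = hr_hier$final,
    simulation = sim$summary,
    log = log_lines, config = config), class = "cqt_report")

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pts, file.path(d, "corrected_ecg.csv"), row.names = FALSE)
    utils::write.csv(deltas, file.path(d, "deltas.csv"), row.names = FALSE)
    utils::write.csv(central, file.path(d, "central_tendency.csv"),
                     row.names = FALSE)
    utils::write.csv(incidence, file.path(d, "categorical_incidence.csv"),
                     row.names = FALSE)
    utils::write.csv(nca, file.path(d, "nca_subject.csv"), row.names = FALSE)
    utils::write.csv(nca_tab, file.path(d, "nca_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$summary, file.path(d, "effect_simulation.csv"),
                     row.names = FALSE)
    write_fit_json(final, file.path(d, "cqt_fit.json"))
    if (!is.null(boot)) {
      utils::write.csv(boot$param_summary,
                       file.path(d, "bootstrap_params.csv"),
                       row.names = FALSE)
      utils::write.csv(boot$band, file.path(d, "bootstrap_band.csv"),
                       row.names = FALSE)
    }
    writeLines(report$log, file.path(d, "run_log.txt"))
  }
  report
}

#' @export
print.cqt_report <- function(x, ...) {
  cat("Cardiodynamic analysis report\n")
  cat(sprintf("  final concentration-QTc model: %s\n", x$cqt_final$form))
  cat(sprintf("  max one-sided 95%% UCB (%s): %.2f ms\n",
              x$config$methods[1L],
              max(x$central_tendency$ucb[
                x$central_tendency$metric == x$config$methods[1L]])))
  cat(sprintf("  simulated %% > 60 ms at %g nM: %g\n",
              x$simulation$reference_conc_nM, x$simulation$pct_gt_60))
  invisible(x)
}
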