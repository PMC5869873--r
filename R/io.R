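# CSV dialects, validation, and configuration.
#
# ecg.csv: subject_id, day, time_h, replicate, qt_ms, rr_s, hr_bpm,
#          pr_ms, qrs_ms        (QT/PR/QRS in ms, RR in seconds)
# pk.csv:  subject_id, day, time_h, analyte, conc_nM
# truth.csv: subject_id, parameter, value
# subjects.csv: subject_id, sex, bmi, ecog, evaluable_day10

ecg_csv_cols <- c("subject_id", "day", "time_h", "replicate", "qt_ms",
                  "rr_s", "hr_bpm", "pr_ms", "qrs_ms")
pk_csv_cols <- c("subject_id", "day", "time_h", "analyte", "conc_nM")
known_analytes <- c("parent", "M1", "M2")

collect_row_errors <- function(problems) {
  if (length(problems) > 0L) {
    stop("input validation failed:\n  ",
         paste(utils::head(problems, 20L), collapse = "\n  "),
         if (length(problems) > 20L) sprintf("\n  ... and %d more",
                                             length(problems) - 20L),
         call. = FALSE)
  }
}

#' Read and validate a replicate-level ECG table
#'
#' Enforces the fixed column schema and units (QT in ms, RR in seconds),
#' rejects non-positive QT/RR and duplicated
#' subject/day/time/replicate keys, and applies a unit-sanity guard: RR
#' values above 10 are taken to indicate an RR column in milliseconds.
#' Row-level problems are collected and reported together.
#'
#' @param path CSV file path.
#' @return tibble of replicate-level records.
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ecg_csv_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("ecg.csv is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[, ecg_csv_cols])
  probs <- character(0)
  if (nrow(df) > 0L) {
    bad_qt <- which(!is.na(df$qt_ms) & df$qt_ms <= 0)
    if (length(bad_qt)) probs <- c(probs, sprintf("row %d: non-positive qt_ms", bad_qt))
    bad_rr <- which(!is.na(df$rr_s) & df$rr_s <= 0)
    if (length(bad_rr)) probs <- c(probs, sprintf("row %d: non-positive rr_s", bad_rr))
    if (any(df$rr_s > 10, na.rm = TRUE)) {
      probs <- c(probs, "rr_s values exceed 10: RR must be in seconds, not ms")
    }
    key <- paste(df$subject_id, df$day, df$time_h, df$replicate)
    dup <- which(duplicated(key))
    if (length(dup)) {
      probs <- c(probs, sprintf("duplicated replicate key: %s", key[dup]))
    }
  }
  collect_row_errors(probs)
  df
}

#' Read and validate a plasma concentration table
#'
#' @param path CSV file path.
#' @return tibble of concentration records (`conc_nM` may be `NA` for
#'   missing samples; negative values and unknown analytes are errors).
#' @export
read_pk_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(pk_csv_cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("pk.csv is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(df[, pk_csv_cols])
  probs <- character(0)
  if (nrow(df) > 0L) {
    bad_an <- which(!df$analyte %in% known_analytes)
    if (length(bad_an)) {
      probs <- c(probs, sprintf("row %d: unknown analyte '%s'",
                                bad_an, df$analyte[bad_an]))
    }
    bad_c <- which(!is.na(df$conc_nM) & df$conc_nM < 0)
    if (length(bad_c)) probs <- c(probs, sprintf("row %d: negative conc_nM", bad_c))
    bad_t <- which(!is.na(df$time_h) & df$time_h < 0)
    if (length(bad_t)) probs <- c(probs, sprintf("row %d: negative time_h", bad_t))
    key <- paste(df$subject_id, df$day, df$time_h, df$analyte)
    dup <- which(duplicated(key))
    if (length(dup)) probs <- c(probs, sprintf("duplicated sample key: %s", key[dup]))
  }
  collect_row_errors(probs)
  df
}

#' Write a generated cohort to CSV files
#'
#' Writes `ecg.csv`, `pk.csv`, `subjects.csv` and `truth.csv` (the
#' simulation-truth sidecar) in the package's fixed dialects.
#'
#' @param cohort a `cqt_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cqt_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ecg.csv", "pk.csv", "subjects.csv", "truth.csv"))
  utils::write.csv(cohort$ecg, paths[1L], row.names = FALSE)
  utils::write.csv(cohort$pk, paths[2L], row.names = FALSE)
  utils::write.csv(cohort$subjects, paths[3L], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[4L], row.names = FALSE)
  invisible(paths)
}

#' Write a concentration-QTc fit as JSON
#'
#' Schema: `form`, `theta` (intercept/slope/emax/ec50/gamma as
#' applicable), `omega`, `sigma`, `se`, `ofv`, `n_subjects`, `n_obs`.
#'
#' @param fit a `cqt_fit`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cqt_fit"))
  obj <- list(form = fit$form, theta = fit$theta,
              omega = fit$omega, sigma = fit$sigma,
              se = as.list(fit$se), ofv = fit$ofv,
              n_subjects = fit$n_subjects, n_obs = fit$n_obs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline configuration
#'
#' All analysis settings in one validated object; every randomized step
#' carries an explicit seed.
#'
#' @param ecg_csv,pk_csv,subjects_csv input paths (any may be `NULL` when
#'   the pipeline is run on in-memory tables).
#' @param out_dir output directory for report tables (`NULL` disables
#'   writing).
#' @param methods QTc correction methods to run.
#' @param min_dosing_days_day10 evaluability rule: minimum consecutive
#'   dosing days required before the steady-state ECG day.
#' @param selection_alpha likelihood-ratio alpha for structural model
#'   selection.
#' @param covariate_alpha forward-inclusion alpha for covariate
#'   screening.
#' @param bootstrap_B,bootstrap_seed bootstrap settings.
#' @param sim_conc_nM reference concentration for the effect simulation
#'   (default 2760 nM, a geometric-mean steady-state Cmax scale).
#' @param sim_n,sim_seed effect-simulation settings.
#' @param thresholds categorical thresholds, see [flag_observations()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(ecg_csv = NULL, pk_csv = NULL,
                            subjects_csv = NULL, out_dir = NULL,
                            methods = c("QTcI", "QTcF"),
                            min_dosing_days_day10 = 4,
                            selection_alpha = 0.05,
                            covariate_alpha = 0.01,
                            bootstrap_B = 1000, bootstrap_seed = NULL,
                            sim_conc_nM = 2760, sim_n = 1000,
                            sim_seed = NULL,
                            thresholds = list()) {
  if (selection_alpha <= 0 || selection_alpha >= 1 ||
      covariate_alpha <= 0 || covariate_alpha >= 1) {
    stop("alpha levels must lie in (0, 1)", call. = FALSE)
  }
  if (bootstrap_B >= 1 && is.null(bootstrap_seed)) {
    stop("`bootstrap_seed` must be set explicitly", call. = FALSE)
  }
  if (sim_n >= 1 && is.null(sim_seed)) {
    stop("`sim_seed` must be set explicitly", call. = FALSE)
  }
  th <- utils::modifyList(
    list(qtc_abs = c(450, 480, 500), dqtc = c(30, 60),
         pr_ms = 200, qrs_ms = 110, rel_increase = 0.25), thresholds)
  if (any(unlist(th) <= 0)) stop("thresholds must be positive", call. = FALSE)
  structure(list(ecg_csv = ecg_csv, pk_csv = pk_csv,
                 subjects_csv = subjects_csv, out_dir = out_dir,
                 methods = methods,
                 min_dosing_days_day10 = min_dosing_days_day10,
                 selection_alpha = selection_alpha,
                 covariate_alpha = covariate_alpha,
                 bootstrap_B = bootstrap_B, bootstrap_seed = bootstrap_seed,
                 sim_conc_nM = sim_conc_nM, sim_n = sim_n,
                 sim_seed = sim_seed, thresholds = th),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
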