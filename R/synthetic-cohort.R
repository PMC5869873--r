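# Virtual cohort generator emulating a Holter + PK cardiodynamic study:
# triplicate ECG extractions on Days -1/1/10, plasma sampling on Days 1
# (0-72 h) and 10 (0-10 h), single dose on Day 1 and BID dosing from Day 4
# through the Day 10 morning dose.

#' Population pharmacokinetic parameters for the cohort generator
#'
#' One-compartment, first-order absorption, linear elimination.  The
#' defaults are calibrated so that on the study sampling grid the
#' population median single-dose Tmax is 4 h and the terminal half-life is
#' about 16.4 h, with Day 1 Cmax near 1500 nM at a 50 mg dose.
#'
#' @param ka first-order absorption rate constant (1/h).
#' @param CL_F apparent oral clearance (L/h).
#' @param V_F apparent volume of distribution (L).
#' @param bsv_cv log-normal between-subject CV (as a fraction) applied
#'   independently to `CL_F` and `V_F`.
#' @param dose_mg dose per administration (mg).
#' @param mw_scale factor converting a mg/L amount scale to nM.  The
#'   default corresponds to a molecular weight of 518.9 g/mol
#'   (1e6 / 518.9).
#' @param met_scale named numeric: metabolite/parent concentration scale
#'   factors for the two metabolites.
#' @param met_ka named numeric: metabolite apparent absorption (formation)
#'   rate constants (1/h); smaller values lag the metabolite profile.
#' @return object of class `pk_parameters`.
#' @export
pk_parameters <- function(ka = 0.76, CL_F = 2.48, V_F = 58.7,
                          bsv_cv = 0.40, dose_mg = 50,
                          mw_scale = 1e6 / 518.9,
                          met_scale = c(M1 = 0.45, M2 = 0.41),
                          met_ka = c(M1 = 0.35, M2 = 0.15)) {
  stopifnot_scalar(ka, "ka", positive = TRUE)
  stopifnot_scalar(CL_F, "CL_F", positive = TRUE)
  stopifnot_scalar(V_F, "V_F", positive = TRUE)
  stopifnot_scalar(bsv_cv, "bsv_cv", nonneg = TRUE)
  stopifnot_scalar(dose_mg, "dose_mg", nonneg = TRUE)
  stopifnot_scalar(mw_scale, "mw_scale", positive = TRUE)
  ke <- CL_F / V_F
  if (abs(ka - ke) < 1e-8) {
    stop("degenerate PK parameters: ka equals ke (flip-flop); ",
         "choose distinct absorption and elimination rates", call. = FALSE)
  }
  structure(list(ka = ka, CL_F = CL_F, V_F = V_F, bsv_cv = bsv_cv,
                 dose_mg = dose_mg, mw_scale = mw_scale,
                 met_scale = met_scale, met_ka = met_ka),
            class = "pk_parameters")
}

#' ECG physiology parameters for the cohort generator
#'
#' Each subject's uncorrected QT follows the power law `QT = a * RR^b`
#' with a log-normally distributed subject exponent `b`; RR varies over
#' the day through a circadian cosine around `rr_mean` plus a
#' time-point-level jitter.  QT noise enters at three levels: a
#' subject-by-day shift (day-to-day baseline drift, the source of
#' between-subject variability in baseline-corrected QTc), a
#' between-time-point residual, and within-triplicate replicate noise.
#' Defaults give a total SD of time-matched QTc change near 9 ms,
#' matching what a thorough-QT planning assumption would use.
#'
#' @param qt_intercept_a QT at RR = 1 s (ms).
#' @param exponent_b_mean,exponent_b_sd mean and SD of the log-normal
#'   population distribution of the subject exponent `b`.
#' @param rr_mean population mean RR interval (s); the default gives a
#'   population heart rate near 75 bpm.
#' @param rr_subject_sd between-subject SD of the mean RR interval (s).
#' @param rr_circadian_amp circadian RR amplitude (s).
#' @param rr_circadian_phase nominal hour (post-morning-timepoint) of the
#'   RR maximum.
#' @param rr_noise_sd time-point-level RR jitter SD (s); the jitter is
#'   shared by the replicates of a triplicate.
#' @param replicate_sd within-triplicate QT noise SD (ms).
#' @param residual_sd between-time-point QT noise SD (ms).
#' @param day_shift_sd SD of the subject-by-day QT baseline shift (ms).
#' @param pr_mean,pr_sd PR interval population mean and between-subject SD (ms).
#' @param qrs_mean,qrs_sd QRS duration population mean and between-subject SD (ms).
#' @param pr_within_sd,qrs_within_sd replicate-level noise SDs (ms).
#' @return object of class `ecg_physiology`.
#' @export
ecg_physiology <- function(qt_intercept_a = 410,
                           exponent_b_mean = 0.33, exponent_b_sd = 0.07,
                           rr_mean = 0.80, rr_subject_sd = 0.08,
                           rr_circadian_amp = 0.08,
                           rr_circadian_phase = 20, rr_noise_sd = 0.04,
                           replicate_sd = 4.0, residual_sd = 4.5,
                           day_shift_sd = 3.9,
                           pr_mean = 160, pr_sd = 15,
                           qrs_mean = 95, qrs_sd = 7,
                           pr_within_sd = 2.0, qrs_within_sd = 1.5) {
  stopifnot_scalar(qt_intercept_a, "qt_intercept_a", positive = TRUE)
  if (exponent_b_mean <= 0 || exponent_b_mean >= 1) {
    stop("`exponent_b_mean` must lie in (0, 1)", call. = FALSE)
  }
  if (rr_mean - rr_circadian_amp <= 0) {
    stop("`rr_mean - rr_circadian_amp` must be > 0", call. = FALSE)
  }
  for (nm in c("exponent_b_sd", "rr_subject_sd", "rr_noise_sd",
               "replicate_sd", "residual_sd",
               "day_shift_sd", "pr_sd", "qrs_sd", "pr_within_sd",
               "qrs_within_sd", "rr_circadian_amp")) {
    stopifnot_scalar(get(nm), nm, nonneg = TRUE)
  }
  structure(list(qt_intercept_a = qt_intercept_a,
                 exponent_b_mean = exponent_b_mean,
                 exponent_b_sd = exponent_b_sd,
                 rr_mean = rr_mean, rr_subject_sd = rr_subject_sd,
                 rr_circadian_amp = rr_circadian_amp,
                 rr_circadian_phase = rr_circadian_phase,
                 rr_noise_sd = rr_noise_sd,
                 replicate_sd = replicate_sd, residual_sd = residual_sd,
                 day_shift_sd = day_shift_sd,
                 pr_mean = pr_mean, pr_sd = pr_sd,
                 qrs_mean = qrs_mean, qrs_sd = qrs_sd,
                 pr_within_sd = pr_within_sd, qrs_within_sd = qrs_within_sd),
            class = "ecg_physiology")
}

#' Drug effect on QT injected by the generator
#'
#' Mirrors the structural classes of the concentration-QTc hierarchy:
#' no effect, a linear concentration slope, or a (sigmoid) Emax effect.
#'
#' @param form one of `"none"`, `"linear"`, `"emax"`.
#' @param slope linear effect (ms per nM).
#' @param emax maximal effect (ms).
#' @param ec50 concentration of half-maximal effect (nM); required and
#'   positive when `form = "emax"`.
#' @param gamma Hill coefficient (sigmoidicity); 1 gives the ordinary
#'   Emax model.
#' @return object of class `drug_effect`.
#' @export
drug_effect <- function(form = c("none", "linear", "emax"),
                        slope = 0, emax = 0, ec50 = NULL, gamma = 1) {
  form <- match.arg(form)
  if (form == "emax") {
    if (is.null(ec50) || !is.numeric(ec50) || ec50 <= 0) {
      stop("`ec50` must be a positive number when form = \"emax\"",
           call. = FALSE)
    }
    stopifnot_scalar(gamma, "gamma", positive = TRUE)
  }
  structure(list(form = form, slope = slope, emax = emax,
                 ec50 = ec50, gamma = gamma),
            class = "drug_effect")
}

# Evaluate the injected drug effect (ms) at concentrations conc (nM).
effect_value <- function(effect, conc) {
  switch(effect$form,
         none = rep(0, length(conc)),
         linear = effect$slope * conc,
         emax = effect$emax * conc^effect$gamma /
           (effect$ec50^effect$gamma + conc^effect$gamma))
}

#' Study design for the cohort generator
#'
#' Encodes the Holter/PK schedule: triplicate ECG extractions on Days -1,
#' 1 and 10 at the Day 1 PK sampling times (to 24 h on Days -1/1, to 10 h
#' on Day 10), plasma sampling to 72 h on Day 1 and 10 h on Day 10, a
#' single dose on Day 1 and BID dosing from Day 4 through the Day 10
#' morning dose.
#'
#' @param n_subjects number of subjects.
#' @param ecg_days integer study days with ECG extraction.
#' @param ecg_times_h named list of nominal ECG times (h) per day; names
#'   are the study days.
#' @param n_replicates replicates per extraction (>= 1).
#' @param pk_times_day1_h,pk_times_day10_h PK sampling times (h postdose).
#' @param dosing_schedule data frame with columns `day` and `time_h`
#'   giving dose events.
#' @param seed master RNG seed for the cohort.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_subjects = 50,
                         ecg_days = c(-1, 1, 10),
                         ecg_times_h = NULL,
                         n_replicates = 3,
                         pk_times_day1_h = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 24, 48, 72),
                         pk_times_day10_h = c(0, 0.5, 1, 2, 3, 4, 6, 8, 10),
                         dosing_schedule = NULL,
                         seed = 1L) {
  full_times <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 24)
  if (is.null(ecg_times_h)) {
    ecg_times_h <- list(`-1` = full_times, `1` = full_times,
                        `10` = full_times[full_times <= 10])
  }
  if (is.null(dosing_schedule)) {
    dosing_schedule <- tibble::tibble(
      day = c(1L, rep(4:9, each = 2L), 10L),
      time_h = c(0, rep(c(0, 12), 6L), 0))
  }
  if (n_subjects < 0 || n_replicates < 1) {
    stop("`n_subjects` must be >= 0 and `n_replicates` >= 1", call. = FALSE)
  }
  days <- as.character(ecg_days)
  if (!all(days %in% names(ecg_times_h))) {
    stop("`ecg_times_h` must name every day in `ecg_days`", call. = FALSE)
  }
  # time-matching must be possible: baseline day must cover every drug-day
  # ECG time up to 24 h
  if (all(c("-1", "1") %in% days)) {
    t1 <- ecg_times_h[["1"]]
    if (!all(t1[t1 <= 24] %in% ecg_times_h[["-1"]])) {
      stop("inconsistent design: Day -1 ECG times must include all Day 1 ",
           "times up to 24 h", call. = FALSE)
    }
  }
  structure(list(n_subjects = as.integer(n_subjects), ecg_days = ecg_days,
                 ecg_times_h = ecg_times_h,
                 n_replicates = as.integer(n_replicates),
                 pk_times_day1_h = pk_times_day1_h,
                 pk_times_day10_h = pk_times_day10_h,
                 dosing_schedule = dosing_schedule,
                 seed = seed),
            class = "study_design")
}

# Absolute study time (h), with Day 1, 0 h as the origin and the Day -1
# session starting 24 h earlier.
day_time_abs <- function(day, time_h) {
  offset <- ifelse(day >= 1, (day - 1) * 24, day * 24)
  offset + time_h
}

# Single oral dose concentration (nM) at s hours post dose.
one_cpt_conc <- function(s, dose_mg, ka, ke, V_F, mw_scale) {
  out <- numeric(length(s))
  pos <- s >= 0
  out[pos] <- dose_mg * mw_scale / V_F * ka / (ka - ke) *
    (exp(-ke * s[pos]) - exp(-ka * s[pos]))
  pmax(out, 0)
}

# Superpose single-dose terms over the dosing schedule at absolute times.
superpose_conc <- function(t_abs, schedule, dose_mg, ka, ke, V_F, mw_scale) {
  dose_abs <- day_time_abs(schedule$day, schedule$time_h)
  conc <- numeric(length(t_abs))
  for (d in dose_abs) {
    conc <- conc + one_cpt_conc(t_abs - d, dose_mg, ka, ke, V_F, mw_scale)
  }
  conc
}

# Draw subject-level PK parameters (log-normal BSV on CL_F and V_F).
draw_pk_subject <- function(params, seed) {
  with_seed_(seed, {
    sdlog <- sqrt(log(1 + params$bsv_cv^2))
    list(CL_F = params$CL_F * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)),
         V_F = params$V_F * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)))
  })
}

#' Simulate a subject's plasma concentration profile
#'
#' One-compartment first-order absorption model with superposition over
#' the dosing schedule; metabolites M1 and M2 are scaled, lagged copies of
#' the parent profile (fixed concentration ratio, slower apparent
#' formation rate).  Concentrations are returned at the design's PK
#' sampling times for Days 1 and 10.
#'
#' @param params a [pk_parameters()] object.
#' @param design a [study_design()] object.
#' @param subject_seed RNG seed for this subject's between-subject draw;
#'   `NULL` disables between-subject variability.
#' @param subject_pars optional pre-drawn list with `CL_F` and `V_F`
#'   (overrides `subject_seed`).
#' @return tibble with columns `day`, `time_h`, `analyte`, `conc_nM`.
#' @export
simulate_pk_profile <- function(params, design, subject_seed = NULL,
                                subject_pars = NULL) {
  stopifnot(inherits(params, "pk_parameters"), inherits(design, "study_design"))
  if (nrow(design$dosing_schedule) == 0L) {
    stop("dosing schedule is empty", call. = FALSE)
  }
  if (is.null(subject_pars)) {
    subject_pars <- if (params$bsv_cv > 0) {
      draw_pk_subject(params, subject_seed)
    } else {
      list(CL_F = params$CL_F, V_F = params$V_F)
    }
  }
  ke <- subject_pars$CL_F / subject_pars$V_F
  if (abs(params$ka - ke) < 1e-8) {
    stop("degenerate PK parameters: ka equals ke for this subject",
         call. = FALSE)
  }
  grid <- dplyr::bind_rows(
    tibble::tibble(day = 1L, time_h = design$pk_times_day1_h),
    tibble::tibble(day = 10L, time_h = design$pk_times_day10_h))
  t_abs <- day_time_abs(grid$day, grid$time_h)
  analytes <- c("parent", names(params$met_scale))
  out <- lapply(analytes, function(a) {
    if (a == "parent") {
      ka_a <- params$ka
      scale_a <- 1
    } else {
      ka_a <- params$met_ka[[a]]
      scale_a <- params$met_scale[[a]]
    }
    conc <- scale_a * superpose_conc(t_abs, design$dosing_schedule,
                                     params$dose_mg, ka_a, ke,
                                     subject_pars$V_F, params$mw_scale)
    tibble::tibble(day = grid$day, time_h = grid$time_h,
                   analyte = a, conc_nM = conc)
  })
  dplyr::bind_rows(out)
}

# Model-predicted parent concentration at arbitrary (day, time) points for
# one subject -- used to link drug exposure to the ECG times.
predict_parent_conc <- function(params, design, subject_pars, day, time_h) {
  ke <- subject_pars$CL_F / subject_pars$V_F
  conc <- superpose_conc(day_time_abs(day, time_h), design$dosing_schedule,
                         params$dose_mg, params$ka, ke,
                         subject_pars$V_F, params$mw_scale)
  conc[day < 1] <- 0  # no drug on the baseline day
  conc
}

#' Simulate a subject's replicate-level ECG extractions
#'
#' QT is generated as `a * RR^b` plus the injected drug effect at the
#' supplied concentration plus day/time-point/replicate noise; RR follows
#' a circadian cosine around its mean with a time-point jitter shared by
#' the triplicate.
#'
#' @param physio an [ecg_physiology()] object.
#' @param effect a [drug_effect()] object.
#' @param conc data frame with columns `day`, `time_h`, `conc_nM` giving
#'   the drug concentration at every drug-day ECG time (baseline-day
#'   times are taken as drug free).
#' @param design a [study_design()] object.
#' @param subject_seed RNG seed for this subject.
#' @return tibble with columns `day`, `time_h`, `replicate`, `qt_ms`,
#'   `rr_s`, `hr_bpm`, `pr_ms`, `qrs_ms` and attribute `truth` (the
#'   subject's exponent `b`).
#' @export
simulate_ecg <- function(physio, effect, conc, design, subject_seed = NULL) {
  stopifnot(inherits(physio, "ecg_physiology"), inherits(effect, "drug_effect"),
            inherits(design, "study_design"))
  with_seed_(subject_seed, {
    m <- physio$exponent_b_mean
    s <- physio$exponent_b_sd
    b <- if (s > 0) {
      sdlog <- sqrt(log(1 + (s / m)^2))
      m * exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
    } else m
    pr_subj <- physio$pr_mean + stats::rnorm(1, 0, physio$pr_sd)
    qrs_subj <- physio$qrs_mean + stats::rnorm(1, 0, physio$qrs_sd)
    rr_subj <- physio$rr_mean + stats::rnorm(1, 0, physio$rr_subject_sd)
    if (rr_subj - physio$rr_circadian_amp <= 0.2) {
      rr_subj <- physio$rr_mean  # guard against an implausibly short draw
    }

    rows <- list()
    for (day in design$ecg_days) {
      times <- design$ecg_times_h[[as.character(day)]]
      day_shift <- stats::rnorm(1, 0, physio$day_shift_sd)
      for (t in times) {
        rr <- NA_real_
        for (try in 1:20) {
          rr <- rr_subj + physio$rr_circadian_amp *
            cos(2 * pi * (t - physio$rr_circadian_phase) / 24) +
            stats::rnorm(1, 0, physio$rr_noise_sd)
          if (rr > 0.2) break
          rr <- NA_real_
        }
        if (is.na(rr)) {
          stop("failed to generate a positive RR interval after 20 draws",
               call. = FALSE)
        }
        c_t <- if (day >= 1) {
          idx <- which(conc$day == day & conc$time_h == t)
          if (length(idx) != 1L) {
            stop(sprintf(
              "no concentration supplied for drug-day ECG time (day %s, %s h)",
              day, t), call. = FALSE)
          }
          conc$conc_nM[idx]
        } else 0
        qt_base <- physio$qt_intercept_a * rr^b +
          effect_value(effect, c_t) + day_shift +
          stats::rnorm(1, 0, physio$residual_sd)
        for (rep_i in seq_len(design$n_replicates)) {
          qt <- qt_base + stats::rnorm(1, 0, physio$replicate_sd)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            day = day, time_h = t, replicate = rep_i,
            qt_ms = qt, rr_s = rr, hr_bpm = 60 / rr,
            pr_ms = pr_subj + stats::rnorm(1, 0, physio$pr_within_sd),
            qrs_ms = qrs_subj + stats::rnorm(1, 0, physio$qrs_within_sd))
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    attr(out, "truth") <- list(exponent_b = b)
    out
  })
}

#' Generator configuration
#'
#' Bundles the design, PK, physiology and injected-effect settings of a
#' virtual cohort.
#'
#' @param n_subjects number of subjects (overrides the design's).
#' @param pk a [pk_parameters()] object.
#' @param physio an [ecg_physiology()] object.
#' @param effect a [drug_effect()] object.
#' @param design a [study_design()] object.
#' @param day10_evaluable_prob probability that a subject completes all
#'   protocol doses before Day 10 (the Day 10 evaluability flag).
#' @param seed master RNG seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 50, pk = pk_parameters(),
                          physio = ecg_physiology(),
                          effect = drug_effect("none"),
                          design = NULL, day10_evaluable_prob = 0.75,
                          seed = 1L) {
  if (is.null(design)) design <- study_design(n_subjects = n_subjects)
  design$n_subjects <- as.integer(n_subjects)
  if (is.null(seed)) stop("`seed` must be supplied", call. = FALSE)
  if (day10_evaluable_prob < 0 || day10_evaluable_prob > 1) {
    stop("`day10_evaluable_prob` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), pk = pk,
                 physio = physio, effect = effect, design = design,
                 day10_evaluable_prob = day10_evaluable_prob,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a virtual cohort
#'
#' Draws subject-level PK parameters, covariates (sex, BMI, ECOG) and ECG
#' physiology, simulates concentration profiles and replicate-level ECG
#' extractions for every subject, and records the simulation truth.
#' Re-running with the same configuration (including its seed) reproduces
#' the cohort exactly.
#'
#' @param config a [cohort_config()] object.
#' @return list of class `cqt_cohort` with tibbles `ecg` (replicate-level
#'   ECG), `pk` (concentration records), `subjects` (covariates and the
#'   Day 10 evaluability flag) and `truth` (long table of per-subject
#'   simulated parameters and the injected effect).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  empty <- function() {
    list(ecg = tibble::tibble(subject_id = character(), day = integer(),
                              time_h = double(), replicate = integer(),
                              qt_ms = double(), rr_s = double(),
                              hr_bpm = double(), pr_ms = double(),
                              qrs_ms = double()),
         pk = tibble::tibble(subject_id = character(), day = integer(),
                             time_h = double(), analyte = character(),
                             conc_nM = double()),
         subjects = tibble::tibble(subject_id = character(), sex = character(),
                                   bmi = double(), ecog = integer(),
                                   evaluable_day10 = logical()),
         truth = tibble::tibble(subject_id = character(),
                                parameter = character(), value = double()))
  }
  if (n == 0L) {
    return(structure(c(empty(), list(config = config)), class = "cqt_cohort"))
  }
  ecg_l <- vector("list", n); pk_l <- vector("list", n)
  sub_l <- vector("list", n); truth_l <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    seed_i <- child_seed(config$seed, i)
    covs <- with_seed_(child_seed(seed_i, 1L), {
      list(sex = if (stats::runif(1) < 0.64) "F" else "M",
           bmi = round(exp(stats::rnorm(1, log(26.5), 0.18)), 1),
           ecog = as.integer(stats::runif(1) < 0.55),
           evaluable_day10 = stats::runif(1) < config$day10_evaluable_prob)
    })
    pk_pars <- if (config$pk$bsv_cv > 0) {
      draw_pk_subject(config$pk, child_seed(seed_i, 2L))
    } else {
      list(CL_F = config$pk$CL_F, V_F = config$pk$V_F)
    }
    pk_i <- simulate_pk_profile(config$pk, config$design,
                                subject_pars = pk_pars)
    ecg_days_drug <- config$design$ecg_days[config$design$ecg_days >= 1]
    conc_link <- dplyr::bind_rows(lapply(ecg_days_drug, function(d) {
      tt <- config$design$ecg_times_h[[as.character(d)]]
      tibble::tibble(day = d, time_h = tt,
                     conc_nM = predict_parent_conc(
                       config$pk, config$design, pk_pars, rep(d, length(tt)), tt))
    }))
    ecg_i <- simulate_ecg(config$physio, config$effect, conc_link,
                          config$design, child_seed(seed_i, 3L))
    b_i <- attr(ecg_i, "truth")$exponent_b
    ecg_l[[i]] <- dplyr::bind_cols(tibble::tibble(subject_id = sid), ecg_i)
    pk_l[[i]] <- dplyr::bind_cols(tibble::tibble(subject_id = sid), pk_i)
    sub_l[[i]] <- tibble::tibble(subject_id = sid, sex = covs$sex,
                                 bmi = covs$bmi, ecog = covs$ecog,
                                 evaluable_day10 = covs$evaluable_day10)
    truth_l[[i]] <- tibble::tibble(
      subject_id = sid,
      parameter = c("exponent_b", "CL_F", "V_F", "ka"),
      value = c(b_i, pk_pars$CL_F, pk_pars$V_F, config$pk$ka))
  }
  eff <- config$effect
  eff_truth <- tibble::tibble(
    subject_id = "(population)",
    parameter = paste0("effect_", c("form", "slope", "emax", "ec50", "gamma")),
    value = c(match(eff$form, c("none", "linear", "emax")),
              eff$slope %||% 0, eff$emax %||% 0, eff$ec50 %||% NA_real_,
              eff$gamma %||% 1))
  structure(list(ecg = dplyr::bind_rows(ecg_l),
                 pk = dplyr::bind_rows(pk_l),
                 subjects = dplyr::bind_rows(sub_l),
                 truth = dplyr::bind_rows(c(truth_l, list(eff_truth))),
                 config = config),
            class = "cqt_cohort")
}

#' @export
print.cqt_cohort <- function(x, ...) {
  cat("Virtual cardiodynamic cohort\n")
  cat(sprintf("  subjects: %d (Day 10 evaluable: %d)\n",
              nrow(x$subjects), sum(x$subjects$evaluable_day10)))
  cat(sprintf("  ECG replicates: %d rows; PK records: %d rows\n",
              nrow(x$ecg), nrow(x$pk)))
  cat(sprintf("  injected effect: %s\n", x$config$effect$form))
  invisible(x)
}
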