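test_that("PK profile honors closed-form one-compartment identities", {
  params <- pk_parameters(bsv_cv = 0)
  design <- study_design(n_subjects = 1,
                         pk_times_day1_h = seq(0, 168, by = 0.25),
                         dosing_schedule = data.frame(day = 1, time_h = 0))
  prof <- simulate_pk_profile(params, design)
  parent <- prof[prof$analyte == "parent" & prof$day == 1, ]
  expect_true(all(parent$conc_nM >= 0))
  # dense-grid AUC to infinity matches F*Dose/CL
  auc <- auc_linlog(parent$time_h, pmax(parent$conc_nM, 1e-12))
  lam <- params$CL_F / params$V_F
  c_last <- parent$conc_nM[nrow(parent)]
  auc_inf <- auc + c_last / lam
  expect_equal(auc_inf, params$dose_mg * params$mw_scale / params$CL_F,
               tolerance = 1e-3)

  # zero dose: flat zero everywhere
  prof0 <- simulate_pk_profile(pk_parameters(dose_mg = 0, bsv_cv = 0), design)
  expect_true(all(prof0$conc_nM == 0))
})

test_that("degenerate absorption equal to elimination is refused", {
  expect_error(pk_parameters(ka = 0.05, CL_F = 5, V_F = 100),
               "flip-flop")
})

test_that("population median Tmax on the sampling grid is 4 h", {
  params <- pk_parameters()
  design <- study_design(n_subjects = 1)
  tmax <- vapply(1:400, function(i) {
    pars <- cqtr:::draw_pk_subject(params, cqtr:::child_seed(2024, i))
    prof <- simulate_pk_profile(params, design, subject_pars = pars)
    p1 <- prof[prof$analyte == "parent" & prof$day == 1, ]
    cmax_tmax(p1$time_h, p1$conc_nM)$tmax
  }, numeric(1))
  expect_equal(stats::median(tmax), 4)
})

test_that("between-subject Cmax CV converges to the configured level", {
  params <- pk_parameters(bsv_cv = 0.40)
  design <- study_design(n_subjects = 1,
                         pk_times_day1_h = c(0, 1, 2, 3, 4, 6, 8, 10, 24),
                         pk_times_day10_h = c(0, 4),
                         dosing_schedule = data.frame(day = 1, time_h = 0))
  cmax <- vapply(1:2000, function(i) {
    pars <- cqtr:::draw_pk_subject(params, cqtr:::child_seed(77, i))
    prof <- simulate_pk_profile(params, design, subject_pars = pars)
    p1 <- prof[prof$analyte == "parent" & prof$day == 1, ]
    max(p1$conc_nM)
  }, numeric(1))
  # Cmax inherits roughly the 40% log-normal CV applied to CL and V
  expect_gt(stats::sd(cmax) / mean(cmax), 0.40 * 0.6)
  expect_lt(stats::sd(cmax) / mean(cmax), 0.40 * 1.4)
})

test_that("noise-free ECG generation is an exact power law", {
  physio <- noise_free_physio()
  design <- study_design(n_subjects = 1)
  t1 <- design$ecg_times_h[["1"]]; t10 <- design$ecg_times_h[["10"]]
  conc <- data.frame(day = rep(c(1, 10), c(length(t1), length(t10))),
                     time_h = c(t1, t10), conc_nM = 0)
  ecg <- simulate_ecg(physio, drug_effect("none"), conc, design,
                      subject_seed = 5)
  b <- attr(ecg, "truth")$exponent_b
  expect_equal(ecg$qt_ms, physio$qt_intercept_a * ecg$rr_s^b,
               tolerance = 1e-12)
  # exponent estimator inverts the generator exactly
  fit <- estimate_individual_exponent(ecg$qt_ms, ecg$rr_s)
  expect_equal(fit$exponent_b, b, tolerance = 1e-9)

  # constant RR when circadian amplitude and RR noise are removed
  physio2 <- noise_free_physio(rr_circadian_amp = 0, rr_noise_sd = 0)
  ecg2 <- simulate_ecg(physio2, drug_effect("none"), conc, design,
                       subject_seed = 5)
  expect_true(all(ecg2$rr_s == physio2$rr_mean))
})

test_that("injected linear effect shifts drug-day QT by slope * conc", {
  physio <- noise_free_physio(rr_circadian_amp = 0, rr_noise_sd = 0)
  design <- study_design(n_subjects = 1)
  t1 <- design$ecg_times_h[["1"]]; t10 <- design$ecg_times_h[["10"]]
  conc <- data.frame(day = rep(c(1, 10), c(length(t1), length(t10))),
                     time_h = c(t1, t10), conc_nM = 2760)
  base <- simulate_ecg(physio, drug_effect("none"), conc, design, 3)
  eff <- simulate_ecg(physio, drug_effect("linear", slope = 0.002),
                      conc, design, 3)
  drug_rows <- base$day >= 1
  expect_equal(eff$qt_ms[drug_rows] - base$qt_ms[drug_rows],
               rep(5.52, sum(drug_rows)), tolerance = 1e-9)
  expect_equal(eff$qt_ms[!drug_rows], base$qt_ms[!drug_rows])
})

test_that("cohort generation is deterministic and handles n = 0", {
  cfg <- cohort_config(n_subjects = 3, seed = 123)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$ecg, c2$ecg)
  expect_identical(c1$pk, c2$pk)
  expect_identical(c1$truth, c2$truth)

  c0 <- generate_cohort(cohort_config(n_subjects = 0, seed = 1))
  expect_identical(nrow(c0$ecg), 0L)
  expect_identical(names(c0$pk),
                   c("subject_id", "day", "time_h", "analyte", "conc_nM"))
})

test_that("inconsistent designs are rejected", {
  expect_error(
    study_design(ecg_times_h = list(`-1` = c(0, 1), `1` = c(0, 1, 2),
                                    `10` = c(0, 1))),
    "time-matched|Day -1")
  expect_error(drug_effect("emax", emax = 5), "ec50")
})
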