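# Shared fixtures, built in code.

# Directly simulated concentration-response dataset with a subject random
# intercept: the sampling model of the mixed-effects fitter.
sim_cqt_data <- function(n_subjects = 50, n_obs = 10, conc_max = 3000,
                         intercept = 0, slope = 0, omega = 7.17,
                         sigma = 6.5, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      conc <- stats::runif(n_obs, 0, conc_max)
      data.frame(subject_id = sprintf("S%03d", i), conc_nM = conc,
                 value = intercept + slope * conc +
                   stats::rnorm(1, 0, omega) + stats::rnorm(n_obs, 0, sigma))
    }))
  })
}

# Exact one-compartment oral profile (for NCA closed-form checks).
one_cpt_profile <- function(times, dose = 50, F_scale = 1927.3, ka = 0.76,
                            CL = 2.48, V = 58.7) {
  ke <- CL / V
  conc <- dose * F_scale / V * ka / (ka - ke) *
    (exp(-ke * times) - exp(-ka * times))
  pmax(conc, 0)
}

# Small noise-free cohort configuration (exact QT = a * RR^b).
noise_free_physio <- function(...) {
  ecg_physiology(replicate_sd = 0, residual_sd = 0, day_shift_sd = 0,
                 rr_subject_sd = 0, pr_within_sd = 0, qrs_within_sd = 0, ...)
}
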