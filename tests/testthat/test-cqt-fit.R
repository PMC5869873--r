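test_that("noise-free linear data are recovered essentially exactly", {
  obs <- sim_cqt_data(n_subjects = 15, n_obs = 8, intercept = 2,
                      slope = 0.001, omega = 1e-5, sigma = 1e-5, seed = 4)
  fit <- fit_cqt(obs, "linear")
  expect_equal(fit$theta$intercept, 2, tolerance = 1e-5)
  expect_equal(fit$theta$slope, 0.001, tolerance = 1e-6)
})

test_that("marginal likelihood and estimates agree with an independent
           linear mixed-model fit", {
  skip_if_not_installed("nlme")
  obs <- sim_cqt_data(n_subjects = 25, n_obs = 6, intercept = 1,
                      slope = 0.002, omega = 6, sigma = 5, seed = 42)
  fit <- fit_cqt(obs, "linear")
  ref <- nlme::lme(value ~ conc_nM, random = ~ 1 | subject_id,
                   data = obs, method = "ML")
  expect_equal(fit$ofv, -2 * as.numeric(stats::logLik(ref)),
               tolerance = 1e-5)
  expect_equal(fit$theta$intercept, unname(nlme::fixef(ref)[1]),
               tolerance = 1e-4)
  expect_equal(fit$theta$slope, unname(nlme::fixef(ref)[2]),
               tolerance = 1e-4)
  expect_equal(fit$omega,
               as.numeric(nlme::VarCorr(ref)["(Intercept)", "StdDev"]),
               tolerance = 1e-3)
  # SEs from the observed information match the reference within a few
  # percent (the reference uses expected information at REML-like scaling)
  expect_equal(unname(fit$se["slope"]),
               summary(ref)$tTable["conc_nM", "Std.Error"],
               tolerance = 0.05)
})

test_that("the no-effect fit matches method-of-moments variance components", {
  obs <- sim_cqt_data(n_subjects = 60, n_obs = 10, intercept = 0,
                      omega = 7.17, sigma = 6.5, seed = 7)
  fit <- fit_cqt(obs, "no_effect")
  expect_equal(fit$theta$intercept, mean(obs$value), tolerance = 0.05)
  sub_means <- tapply(obs$value, obs$subject_id, mean)
  within_sd <- sqrt(mean(tapply(obs$value, obs$subject_id, stats::var)))
  expect_equal(fit$sigma, within_sd, tolerance = 0.05)
  # between-subject SD of subject means overstates omega by sigma^2/n_obs
  expect_equal(fit$omega^2, stats::var(sub_means) - fit$sigma^2 / 10,
               tolerance = 0.15)
})

test_that("richer nested models never have a worse objective", {
  for (seed in c(13, 14)) {
    obs <- sim_cqt_data(n_subjects = 30, n_obs = 8, intercept = 1,
                        slope = 0.001, seed = seed)
    h <- fit_cqt_hierarchy(obs)
    ofv <- vapply(h$fits, function(f) f$ofv, numeric(1))
    expect_lte(ofv["linear"], ofv["no_effect"] + 1e-4)
    expect_lte(ofv["emax"], ofv["no_effect"] + 1e-4)
    expect_lte(ofv["sigmoid_emax"], ofv["emax"] + 1e-4)
  }
})

test_that("Emax model recovery on a study-scale design", {
  # 100 subjects x 19 observations (the Holter schedule's per-subject
  # count); Emax 10 ms, EC50 1000 nM.  Emax and the fitted curve are
  # well identified; EC50 itself is the weakly identified parameter and
  # is only held to a looser band.
  errs <- sapply(1:100, function(s) {
    obs <- sim_cqt_data(n_subjects = 100, n_obs = 19, conc_max = 5000,
                        omega = 5, sigma = 5, seed = 100 + s)
    obs$value <- obs$value + 10 * obs$conc_nM / (1000 + obs$conc_nM)
    fit <- fit_cqt(obs, "emax")
    eff_hat <- fit$theta$emax * 1000 / (fit$theta$ec50 + 1000)
    c(emax = abs(fit$theta$emax - 10) / 10,
      ec50 = abs(fit$theta$ec50 - 1000) / 1000,
      eff = abs(eff_hat - 5) / 5)
  })
  expect_lt(stats::median(errs["emax", ]), 0.2)
  expect_lt(stats::median(errs["eff", ]), 0.2)
  expect_lt(stats::median(errs["ec50", ]), 0.35)
})

test_that("model selection ties favor the simpler form", {
  obs <- sim_cqt_data(n_subjects = 10, n_obs = 5, seed = 2)
  f0 <- fit_cqt(obs, "no_effect")
  f1 <- fit_cqt(obs, "linear")
  f1$ofv <- f0$ofv  # force an exact tie
  sel <- select_model(list(f0, f1))
  expect_equal(sel$form, "no_effect")
  expect_error(select_model(list()), "no candidate")
})

test_that("covariate screening finds an injected sex shift and skips constants", {
  hits <- vapply(1:10, function(s) {
    obs <- sim_cqt_data(n_subjects = 50, n_obs = 10, omega = 7.17,
                        sigma = 6.5, seed = 300 + s)
    sexes <- withr::with_seed(600 + s,
                              sample(c("F", "M"), 50, replace = TRUE))
    obs$sex <- sexes[as.integer(factor(obs$subject_id))]
    obs$value <- obs$value + ifelse(obs$sex == "M", 10, 0)
    sc <- screen_covariates(obs, covariates = "sex")
    "sex" %in% sc$retained
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  obs <- sim_cqt_data(n_subjects = 20, n_obs = 5, seed = 5)
  obs$sex <- "F"
  sc <- screen_covariates(obs, covariates = "sex")
  expect_equal(sc$skipped, "sex")
  expect_length(sc$retained, 0)
})

test_that("heart-rate model recovers the population value and drug effects", {
  # no drug effect: intercept near the simulated 75 bpm
  ints <- vapply(1:7, function(s) {
    obs <- sim_cqt_data(n_subjects = 50, n_obs = 10, intercept = 75,
                        omega = 8, sigma = 3, seed = 400 + s)
    fit_hr_model(obs, "no_effect")$theta$intercept
  }, numeric(1))
  expect_lt(abs(stats::median(ints) - 75), 1)

  # zero-variance data: exact intercept, omega at its floor
  obs0 <- sim_cqt_data(n_subjects = 10, n_obs = 4, intercept = 75,
                       omega = 1e-9, sigma = 1e-9, seed = 1)
  f0 <- fit_hr_model(obs0, "no_effect")
  expect_equal(f0$theta$intercept, 75, tolerance = 1e-6)
  expect_lt(f0$omega, 1e-3)

  # injected concentration effect on HR is detected
  rejected <- vapply(1:7, function(s) {
    obs <- sim_cqt_data(n_subjects = 50, n_obs = 10, intercept = 75,
                        slope = 0.004, omega = 8, sigma = 3, seed = 500 + s)
    h <- fit_cqt_hierarchy(obs, forms = c("no_effect", "linear"))
    h$final$form != "no_effect"
  }, logical(1))
  expect_true(all(rejected))
})

test_that("manually constructed fits expose the same interface", {
  f <- as_cqt_fit("no_effect", intercept = 0.325, omega = 7.17,
                  sigma = sqrt(9.68^2 - 7.17^2))
  expect_s3_class(f, "cqt_fit")
  expect_equal(sqrt(f$omega^2 + f$sigma^2), 9.68, tolerance = 1e-12)
  expect_error(as_cqt_fit("emax", emax = 5), "ec50")
})
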