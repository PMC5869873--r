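test_that("linear-log trapezoid applies the right rule per segment", {
  expect_equal(auc_linlog(c(0, 2), c(10, 10)), 20)           # flat: linear
  expect_equal(auc_linlog(c(0, 1), c(10, 5)), 5 / log(2))    # fall: log
  expect_equal(auc_linlog(c(0, 1), c(0, 10)), 5)             # rise: linear
  expect_equal(auc_linlog(c(0, 1), c(10, 0)), 5)             # fall to 0: linear
  expect_error(auc_linlog(c(1, 0), c(1, 2)), "increasing")
  expect_error(auc_linlog(c(0, 1), c(-1, 2)), "non-negative")
})

test_that("log trapezoid is below the linear chord and AUC is additive", {
  withr::with_seed(11, {
    for (i in 1:25) {
      c1 <- runif(1, 1, 100)
      c2 <- runif(1, 1e-3, c1 * 0.999)
      dt <- runif(1, 0.1, 12)
      expect_lt(auc_linlog(c(0, dt), c(c1, c2)),
                (c1 + c2) * dt / 2 + 1e-12)
    }
    times <- sort(runif(12, 0, 48))
    concs <- exp(rnorm(12, 3, 1))
    k <- 6
    expect_equal(auc_linlog(times, concs),
                 auc_linlog(times[1:k], concs[1:k]) +
                   auc_linlog(times[k:12], concs[k:12]))
  })
})

test_that("Cmax/Tmax take the first maximum", {
  ct <- cmax_tmax(c(0, 1, 3, 4, 8), c(0, 8, 10, 10, 4))
  expect_equal(ct$cmax, 10)
  expect_equal(ct$tmax, 3)
  rising <- cmax_tmax(c(0, 2, 4), c(1, 2, 3))
  expect_equal(rising$tmax, 4)
})

test_that("terminal slope recovers an exact exponential and flags flat data", {
  t <- c(24, 48, 72)
  lam <- log(2) / 16.4
  fit <- fit_lambda_z(c(1, 4, t), c(50, 100, 100 * exp(-lam * t)))
  expect_true(fit$estimable)
  expect_equal(fit$t_half, 16.4, tolerance = 1e-10)

  flat <- fit_lambda_z(c(0, 4, 24, 48, 72), rep(10, 5))
  expect_false(flat$estimable)
  expect_true(is.na(flat$t_half))
})

test_that("noisy exponential half-life is recovered within 5% in the median", {
  lam <- log(2) / 16.4
  t <- c(6, 8, 10, 24, 48, 72)
  est <- vapply(1:200, function(s) {
    withr::with_seed(1000 + s, {
      conc <- 100 * exp(-lam * t) * exp(rnorm(length(t), 0, 0.1))
      profile <- c(0, 80, conc)
      fit_lambda_z(c(0, 3, t), profile)$t_half
    })
  }, numeric(1))
  expect_lt(abs(stats::median(est, na.rm = TRUE) - 16.4) / 16.4, 0.05)
})

test_that("AUC extrapolation and accumulation arithmetic", {
  ext <- auc_extrapolate(100, 10, 0.1)
  expect_equal(ext$auc_inf, 200)
  expect_equal(ext$extrapolated_fraction, 0.5)
  expect_equal(auc_extrapolate(100, 0, 0.1)$auc_inf, 100)
  expect_true(is.na(auc_extrapolate(100, 10, NA)$auc_inf))

  expect_equal(accumulation_ratio(20, 20), 1)
  expect_equal(accumulation_ratio(40, 20), 2)
  expect_true(is.na(accumulation_ratio(NA, 20)))
  # linear-kinetics prediction for a 12 h interval at a 16.4 h half-life
  expect_equal(predicted_accumulation(12, 16.4), 2.51, tolerance = 2e-3)
})

test_that("steady-state fraction and unbound concentration closed forms", {
  expect_equal(steady_state_fraction(10, 10), 0.5)
  expect_equal(steady_state_fraction(10, 1e6), 1, tolerance = 1e-12)
  expect_gt(steady_state_fraction(16.4, 96), 0.90)
  expect_equal(unbound_concentration(2.76, 0.025), 0.069)
  expect_equal(unbound_concentration(5, 1), 5)
  expect_equal(unbound_concentration(5, 0), 0)
  expect_error(unbound_concentration(5, 1.2), "free_fraction")
})

test_that("dense NCA on an exact one-compartment profile matches closed forms", {
  times <- c(seq(0, 24, by = 0.1), seq(24.5, 240, by = 0.5))
  conc <- one_cpt_profile(times)
  auc <- auc_linlog(times, conc)
  lam <- fit_lambda_z(times, conc)
  ext <- auc_extrapolate(auc, conc[length(conc)], lam$lambda_z)
  expect_equal(ext$auc_inf, 50 * 1927.3 / 2.48, tolerance = 0.01)
  expect_equal(lam$t_half, log(2) / (2.48 / 58.7), tolerance = 0.01)
})

test_that("summary statistics follow the stated conventions", {
  s <- summarize_parameter(c(5, 5, 5), "geometric")
  expect_equal(s$geo_mean, 5)
  expect_equal(s$geo_cv_pct, 0)
  expect_equal(summarize_parameter(c(1, 100), "geometric")$geo_mean, 10)
  expect_error(geo_stats(c(1, -2)), "positive")

  # geometric CV% uses the log-variance formula
  x <- exp(rnorm(50, 1, 0.3))
  expect_equal(summarize_parameter(x, "geometric")$geo_cv_pct,
               100 * sqrt(exp(stats::var(log(x))) - 1))

  expect_equal(metabolite_ratio(c(0.4, 0.5) * c(10, 20), c(10, 20)), 0.45)
  expect_error(metabolite_ratio(1:3, 1:2), "matched")
})

test_that("per-subject NCA assembles the parameter set by day", {
  times1 <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 24, 48, 72)
  times10 <- c(0, 0.5, 1, 2, 3, 4, 6, 8, 10)
  pk <- rbind(
    data.frame(day = 1, time_h = times1, conc_nM = one_cpt_profile(times1)),
    data.frame(day = 10, time_h = times10,
               conc_nM = 2.5 * one_cpt_profile(times10)))
  res <- nca_subject(pk)
  expect_equal(nrow(res), 2)
  d1 <- res[res$day == 1, ]; d10 <- res[res$day == 10, ]
  expect_equal(d1$tmax_h, 4)
  expect_gt(d1$auc_inf_nM_h, d1$auc_last_nM_h)
  # Day 10 profile spans one interval only: no terminal-phase estimates
  expect_true(is.na(d10$t_half_h))
  expect_equal(d10$r_ac, 2.5, tolerance = 1e-9)
})
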