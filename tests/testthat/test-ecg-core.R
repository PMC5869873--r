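test_that("Fridericia and individual corrections satisfy their identities", {
  expect_equal(qtc_fridericia(400, 1), 400)
  expect_equal(qtc_fridericia(360, 0.729), 400)      # 0.729^(1/3) = 0.9
  expect_equal(qtc_fridericia(350, 0.64), 406.13, tolerance = 1e-4)
  expect_error(qtc_fridericia(400, 0), "positive")

  # RR = 1 s leaves QT unchanged for every exponent
  for (b in c(0, 0.2, 1 / 3, 0.5, 0.8)) {
    expect_equal(qtc_individual(412, 1, b), 412)
  }
  expect_equal(qtc_individual(380, 0.7, 0), 380)      # b = 0: no correction
  expect_equal(qtc_individual(380, 0.7, 1 / 3), qtc_fridericia(380, 0.7))
  expect_equal(qtc_individual(380, 0.81, 0.5), 380 / 0.9)
  expect_equal(qtc_bazett(380, 0.81), 380 / 0.9)
})

test_that("replicate averaging takes field-wise means with bookkeeping", {
  reps <- data.frame(subject_id = "A", day = 1, time_h = 2,
                     qt_ms = c(400, 402, 404), rr_s = c(0.9, 0.92, 0.91),
                     hr_bpm = 60 / c(0.9, 0.92, 0.91),
                     pr_ms = c(160, 162, NA), qrs_ms = 95)
  avg <- average_replicates(reps)
  expect_equal(avg$qt_ms, 402)
  expect_equal(avg$pr_ms, 161)        # missing replicate values are dropped
  expect_equal(avg$n_replicates, 3L)

  single <- average_replicates(reps[1, ])
  expect_equal(single$qt_ms, 400)
  expect_equal(single$n_replicates, 1L)

  mixed <- reps; mixed$time_h <- c(2, 2, 3)
  expect_error(average_replicates(mixed), "more than one")
  expect_error(average_replicates(reps[0, ]), "no replicates")
})

test_that("exponent estimation recovers exact power laws and edge cases", {
  rr <- seq(0.6, 1.2, length.out = 20)
  fit <- estimate_individual_exponent(400 * rr^0.5, rr)
  expect_equal(fit$exponent_b, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  flat <- estimate_individual_exponent(rep(400, 20), rr)
  expect_equal(flat$exponent_b, 0, tolerance = 1e-12)

  expect_error(estimate_individual_exponent(400, 0.9), "at least 2")
  expect_error(estimate_individual_exponent(c(400, 410), c(0.9, 0.9)),
               "singular")
})

test_that("fitted individual correction removes the RR dependence", {
  # noise-free cohort: per-subject correlation of QTcI with RR is 0
  coh <- generate_cohort(cohort_config(
    n_subjects = 4, physio = noise_free_physio(), seed = 9))
  cor_res <- correct_ecg(coh$ecg, methods = "QTcI")
  pts <- cor_res$points
  for (sid in unique(pts$subject_id)) {
    sub <- pts[pts$subject_id == sid, ]
    # exact removal: QTcI collapses to the subject constant a
    expect_lt(stats::sd(sub$QTcI), 1e-9)
    expect_equal(mean(sub$QTcI), 410, tolerance = 1e-9)
  }
})

test_that("time-matched deltas subtract the same-time baseline and drop the rest", {
  pts <- expand.grid(subject_id = c("A", "B"), day = c(-1, 1, 10),
                     time_h = c(0, 1, 24), stringsAsFactors = FALSE)
  pts$QTcI <- 400
  pts$QTcI[pts$subject_id == "A" & pts$day == 10 & pts$time_h == 1] <- 396
  pts$QTcI[pts$subject_id == "A" & pts$day == -1 & pts$time_h == 1] <- 400
  # Day 10 has no 24 h extraction
  pts <- pts[!(pts$day == 10 & pts$time_h == 24), ]

  d <- time_matched_delta(pts, metrics = "QTcI")
  expect_true(all(d$delta[!(d$subject_id == "A" & d$day == 10 &
                              d$time_h == 1)] == 0))
  expect_equal(d$delta[d$subject_id == "A" & d$day == 10 & d$time_h == 1], -4)
  expect_false(any(d$day == 10 & d$time_h == 24))

  # a drug-day time missing from baseline is dropped and logged
  pts2 <- pts[!(pts$day == -1 & pts$time_h == 24), ]
  d2 <- time_matched_delta(pts2, metrics = "QTcI")
  expect_false(any(d2$day == 1 & d2$time_h == 24))
  dropped <- attr(d2, "dropped")
  expect_true(all(dropped$time_h == 24) && all(dropped$day == 1))
})
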