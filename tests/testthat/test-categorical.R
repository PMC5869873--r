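make_flag_fixture <- function() {
  pts <- expand.grid(subject_id = c("A", "B"), day = c(-1, 1),
                     time_h = c(0, 2), stringsAsFactors = FALSE)
  pts$QTcI <- 430
  pts$pr_ms <- 170; pts$qrs_ms <- 95
  # A at day 1, 2 h: extreme QTc; B: PR above 200 but < 25% over baseline
  pts$QTcI[pts$subject_id == "A" & pts$day == 1 & pts$time_h == 2] <- 501
  pts$pr_ms[pts$subject_id == "B" & pts$day == -1] <- 190
  pts$pr_ms[pts$subject_id == "B" & pts$day == 1] <- 210
  pts
}

test_that("absolute QTc flags nest and compound rules need both conditions", {
  pts <- make_flag_fixture()
  d <- time_matched_delta(pts, metrics = "QTcI")
  flags <- flag_observations(pts, d, pts[pts$day == -1, ], methods = "QTcI")

  hot <- flags[flags$subject_id == "A" & flags$time_h == 2, ]
  expect_true(hot$qtc_gt_450 && hot$qtc_gt_480 && hot$qtc_gt_500)
  expect_true(hot$dqtc_gt_30 && hot$dqtc_gt_60)   # 501 - 430 = 71 ms

  # nesting invariants on every row
  expect_true(all(!flags$qtc_gt_500 | flags$qtc_gt_480))
  expect_true(all(!flags$qtc_gt_480 | flags$qtc_gt_450))
  expect_true(all(!flags$dqtc_gt_60 | flags$dqtc_gt_30, na.rm = TRUE))

  # PR 210 with baseline 190: above 200 ms but only a 10.5% increase
  expect_false(any(flags$pr_flag[flags$subject_id == "B"]))
  expect_false(any(flags$qrs_flag))
})

test_that("incidence counts subjects once and are order/duplication invariant", {
  pts <- make_flag_fixture()
  d <- time_matched_delta(pts, metrics = "QTcI")
  flags <- flag_observations(pts, d, pts[pts$day == -1, ], methods = "QTcI")
  tab <- tabulate_flags(flags)

  g500 <- tab[tab$category == "qtc_gt_500" & tab$day == 1, ]
  expect_equal(g500$n_flagged, 1)
  expect_equal(g500$n_total, 2)
  expect_equal(g500$pct, 50)
  expect_equal(tab$n_flagged[tab$category == "dqtc_gt_60" & tab$day == 1], 1)

  shuffled <- flags[rev(seq_len(nrow(flags))), ]
  duplicated_rows <- rbind(flags, flags)
  expect_equal(tabulate_flags(shuffled), tab)
  expect_equal(tabulate_flags(duplicated_rows), tab)
})

test_that("a cohort without large changes yields empty exceedance categories", {
  pts <- expand.grid(subject_id = sprintf("S%d", 1:6), day = c(-1, 1),
                     time_h = c(0, 2, 4), stringsAsFactors = FALSE)
  withr::with_seed(15, {
    pts$QTcI <- 410 + rnorm(nrow(pts), 0, 5)
    pts$pr_ms <- 160; pts$qrs_ms <- 95
  })
  d <- time_matched_delta(pts, metrics = "QTcI")
  expect_true(all(abs(d$delta) < 60))
  flags <- flag_observations(pts, d, pts[pts$day == -1, ], methods = "QTcI")
  tab <- tabulate_flags(flags)
  expect_equal(sum(tab$n_flagged[tab$category == "dqtc_gt_60"]), 0)
})

test_that("missing baselines disable relative flags but keep absolute ones", {
  pts <- data.frame(subject_id = "A", day = 1, time_h = 2,
                    QTcI = 460, pr_ms = 260, qrs_ms = 95)
  base <- data.frame(subject_id = character(), time_h = numeric(),
                     pr_ms = numeric(), qrs_ms = numeric())
  d <- data.frame(subject_id = character(), day = numeric(),
                  time_h = numeric(), metric = character(),
                  delta = numeric())
  flags <- flag_observations(pts, d, base, methods = "QTcI")
  expect_true(flags$qtc_gt_450)
  expect_true(is.na(flags$pr_flag))
  expect_true(is.na(flags$dqtc_gt_30))
})
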