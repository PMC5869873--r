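test_that("LS means equal cell means on balanced complete data", {
  withr::with_seed(21, {
    subjects <- sprintf("S%02d", 1:12)
    grid <- expand.grid(subject_id = subjects, day = c(1, 10),
                        time_h = c(1, 2, 4), stringsAsFactors = FALSE)
    grid$metric <- "QTcI"
    grid$delta <- rnorm(nrow(grid), 0, 8) +
      rep(rnorm(12, 0, 5), times = 6)   # subject effect
    res <- fit_repeated_measures(grid)
    cell_means <- aggregate(delta ~ day + time_h, grid, mean)
    merged <- merge(res, cell_means, by = c("day", "time_h"))
    expect_equal(merged$ls_mean, merged$delta, tolerance = 1e-6)
    expect_true(all(res$ucb >= res$ls_mean))
    expect_true(all(res$df == 11))
  })
})

test_that("degenerate all-zero deltas give zero means and bounds", {
  grid <- expand.grid(subject_id = c("A", "B", "C"), day = 1,
                      time_h = c(1, 2), stringsAsFactors = FALSE)
  grid$metric <- "QTcI"; grid$delta <- 0
  res <- fit_repeated_measures(grid)
  expect_true(all(res$ls_mean == 0))
  expect_true(all(res$ucb == 0))
})

test_that("a single cell reduces to the one-sample t upper bound", {
  withr::with_seed(8, {
    x <- rnorm(20, 1, 6)
    d <- data.frame(subject_id = sprintf("S%02d", 1:20), day = 1,
                    time_h = 2, metric = "QTcI", delta = x)
    res <- fit_repeated_measures(d)
    expect_equal(res$ls_mean, mean(x), tolerance = 1e-6)
    expect_equal(res$ucb,
                 mean(x) + stats::qt(0.95, 19) * stats::sd(x) / sqrt(20),
                 tolerance = 1e-4)
  })
})

test_that("cells missing on one day are simply absent", {
  grid <- expand.grid(subject_id = c("A", "B", "C", "D"), day = c(1, 10),
                      time_h = c(1, 24), stringsAsFactors = FALSE)
  grid <- grid[!(grid$day == 10 & grid$time_h == 24), ]
  grid$metric <- "QTcI"
  withr::with_seed(3, grid$delta <- rnorm(nrow(grid)))
  res <- fit_repeated_measures(grid)
  expect_false(any(res$day == 10 & res$time_h == 24))
  expect_equal(nrow(res), 3)
})

test_that("planning half-width follows the normal closed form", {
  expect_equal(plan_ucb_halfwidth(9, 36), qnorm(0.95) * 1.5)
  expect_equal(plan_ucb_halfwidth(9, 36), 2.47, tolerance = 5e-3)
  expect_lt(plan_ucb_halfwidth(9, 36), 2.5)
  expect_equal(plan_ucb_halfwidth(0, 10), 0)
  expect_equal(plan_ucb_halfwidth(9, 9), 3 * plan_ucb_halfwidth(9, 81))
  # monotone: decreasing in n, increasing in sd
  ns <- c(9, 16, 25, 36, 49)
  w <- vapply(ns, function(n) plan_ucb_halfwidth(9, n), numeric(1))
  expect_true(all(diff(w) < 0))
  sds <- c(3, 6, 9, 12)
  w2 <- vapply(sds, function(s) plan_ucb_halfwidth(s, 36), numeric(1))
  expect_true(all(diff(w2) > 0))
})

test_that("the evaluability rule filters only the steady-state day", {
  subjects <- data.frame(subject_id = c("A", "B"),
                         evaluable_day10 = c(TRUE, FALSE))
  d <- expand.grid(subject_id = c("A", "B"), day = c(1, 10),
                   stringsAsFactors = FALSE)
  out <- apply_evaluability(d, subjects)
  expect_true(all(out$subject_id[out$day == 10] == "A"))
  expect_equal(sum(out$day == 1), 2)
})
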