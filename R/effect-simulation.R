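# Simulation of the QTc effect-size distribution at a reference
# concentration from a fitted concentration-QTc model, with analytic
# tail probabilities for the 30/60 ms thresholds of concern.

#' Simulate the change-from-baseline QTc distribution at a concentration
#'
#' Each simulated patient draws
#' `intercept + f(conc; theta) + eta + eps` with
#' `eta ~ N(0, omega^2)` (between-subject) and `eps ~ N(0, sigma^2)`
#' (residual), so the spread of the simulated distribution is the total
#' SD `sqrt(omega^2 + sigma^2)`.
#'
#' @param fit a `cqt_fit`.
#' @param conc_nM reference concentration (nM), e.g. the geometric mean
#'   steady-state Cmax.
#' @param n number of simulated patients.
#' @param seed RNG seed.
#' @param thresholds exceedance thresholds (ms) summarized as
#'   percentages of draws above each.
#' @return list with `draws` (numeric n) and `summary` (a
#'   [summarize_draws()] tibble including the exceedance percentages and
#'   the reference concentration).
#' @export
simulate_population <- function(fit, conc_nM, n = 1000, seed = 1L,
                                thresholds = c(30, 60)) {
  stopifnot(inherits(fit, "cqt_fit"), n >= 1)
  stopifnot_scalar(conc_nM, "conc_nM", nonneg = TRUE)
  draws <- with_seed_(seed, {
    mu <- fit$theta$intercept + cqt_effect(fit$form, fit$theta, conc_nM)
    mu + stats::rnorm(n, 0, fit$omega) + stats::rnorm(n, 0, fit$sigma)
  })
  summ <- summarize_draws(draws, thresholds = thresholds)
  summ$reference_conc_nM <- conc_nM
  list(draws = draws, summary = summ)
}

#' Summarize simulated effect-size draws
#'
#' Median, mean, SD, CV% (`100 * SD / |mean|`, reported missing when the
#' mean is 0), range, 5th/95th percentiles (linear interpolation between
#' order statistics), and the percentage of draws above each threshold
#' (strict inequality).
#'
#' @param draws numeric vector of simulated changes (ms).
#' @param thresholds thresholds (ms) for exceedance percentages.
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return one-row tibble.
#' @export
summarize_draws <- function(draws, thresholds = c(30, 60),
                            quantile_type = 7) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0L) stop("no draws to summarize", call. = FALSE)
  m <- mean(draws)
  s <- if (length(draws) > 1L) stats::sd(draws) else 0
  out <- tibble::tibble(
    n_simulated = length(draws),
    median = stats::median(draws),
    mean = m, sd = s,
    cv_pct = if (m == 0) NA_real_ else 100 * s / abs(m),
    min = min(draws),
    p5 = stats::quantile(draws, 0.05, names = FALSE, type = quantile_type),
    p95 = stats::quantile(draws, 0.95, names = FALSE, type = quantile_type),
    max = max(draws))
  for (th in thresholds) {
    out[[sprintf("pct_gt_%g", th)]] <- 100 * mean(draws > th)
  }
  out
}

#' Analytic normal tail probability above a threshold
#'
#' `100 * (1 - Phi((threshold - mean) / sd))`: the percentage of a
#' normal effect-size distribution exceeding a threshold, the analytic
#' counterpart of the simulated exceedance percentages.
#'
#' @param mean,sd moments of the effect distribution (ms); `sd` must be
#'   positive.
#' @param threshold threshold (ms).
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' tail_probability(0, 1, 0)          # 50
#' tail_probability(0.323, 9.39, 30)  # 0.0786: about 0.1% at one decimal
tail_probability <- function(mean, sd, threshold) {
  if (!is.numeric(sd) || any(sd <= 0)) {
    stop("`sd` must be positive", call. = FALSE)
  }
  100 * stats::pnorm((threshold - mean) / sd, lower.tail = FALSE)
}
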