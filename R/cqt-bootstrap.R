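# Subject-resampling bootstrap for the concentration-QTc model.

#' Bootstrap a concentration-QTc fit by resampling subjects
#'
#' Draws `B` bootstrap datasets by resampling subjects with replacement
#' (each draw keeps all of a subject's observations, under a fresh
#' subject label so duplicated subjects stay distinct), refits the
#' structural model on each, and summarizes the parameters by their
#' bootstrap median and percentile interval.  A percentile band for the
#' fitted concentration-response line over the observed concentration
#' range is also returned.  Replicates that fail to converge are dropped;
#' more than 20% failures raises a warning.
#'
#' @param fit a `cqt_fit` (its stored data are resampled and its
#'   estimates warm-start every replicate).
#' @param B number of bootstrap datasets.
#' @param seed RNG seed governing the resampling.
#' @param level central coverage of the percentile interval (default
#'   0.90: 5th and 95th percentiles).
#' @param grid_n number of concentrations in the prediction-band grid.
#' @return object of class `cqt_bootstrap`: `param_summary` (parameter,
#'   median, lower, upper), `band` (conc_nM, lower, median, upper),
#'   `draws` (matrix B_ok x parameters), `B`, `n_failed`.
#' @export
bootstrap_cqt <- function(fit, B = 1000, seed = 1L, level = 0.90,
                          grid_n = 50L) {
  stopifnot(inherits(fit, "cqt_fit"), B >= 1)
  obs <- fit$data
  ids <- unique(obs$subject_id)
  by_id <- split(obs, obs$subject_id)[ids]
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  grid <- seq(0, max(obs$conc_nM), length.out = grid_n)

  draws <- with_seed_(seed, {
    out <- vector("list", B)
    for (b in seq_len(B)) {
      pick <- sample(ids, length(ids), replace = TRUE)
      dat <- dplyr::bind_rows(lapply(seq_along(pick), function(j) {
        d <- by_id[[pick[j]]]
        d$subject_id <- sprintf("bs%04d", j)
        d
      }))
      rf <- tryCatch(
        fit_cqt(dat, fit$form, covariates = fit$covariates,
                start = fit$par, n_starts = 1L),
        error = function(e) NULL)
      out[[b]] <- if (!is.null(rf) && rf$convergence %in% c(0L, 1L)) {
        rf$estimates
      } else NULL
    }
    out
  })
  keep <- !vapply(draws, is.null, logical(1))
  n_failed <- sum(!keep)
  if (n_failed > 0.2 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, B), call. = FALSE)
  }
  if (!any(keep)) stop("all bootstrap replicates failed", call. = FALSE)
  mat <- do.call(rbind, draws[keep])

  qs <- apply(mat, 2L, stats::quantile, probs = probs, names = FALSE,
              type = 7)
  param_summary <- tibble::tibble(
    parameter = colnames(mat),
    lower = qs[1L, ], median = qs[2L, ], upper = qs[3L, ])

  lines <- apply(mat, 1L, function(est) {
    theta <- as.list(est)
    theta$intercept + cqt_effect(fit$form, theta, grid)
  })
  if (is.null(dim(lines))) lines <- matrix(lines, nrow = 1L)
  bq <- apply(lines, 1L, stats::quantile, probs = probs, names = FALSE)
  band <- tibble::tibble(conc_nM = grid, lower = bq[1L, ],
                         median = bq[2L, ], upper = bq[3L, ])

  structure(list(param_summary = param_summary, band = band, draws = mat,
                 B = B, n_failed = n_failed, level = level,
                 form = fit$form, seed = seed),
            class = "cqt_bootstrap")
}

#' @export
print.cqt_bootstrap <- function(x, ...) {
  cat(sprintf("Subject-resampling bootstrap: %s model, B = %d (%d failed)\n",
              x$form, x$B, x$n_failed))
  print(as.data.frame(x$param_summary))
  invisible(x)
}
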