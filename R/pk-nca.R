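# Non-compartmental pharmacokinetics: linear-log trapezoidal AUC,
# terminal slope, Cmax/Tmax, accumulation, and cohort summary statistics.

#' Linear-log trapezoidal AUC
#'
#' Per segment: the linear trapezoid `(C1 + C2) * dt / 2` when the
#' concentration is rising or flat (`C2 >= C1`) or when either endpoint is
#' zero; the logarithmic trapezoid `(C1 - C2) * dt / log(C1/C2)` when the
#' concentration is strictly declining between positive values.  Segments
#' are summed over the profile.
#'
#' @param times strictly increasing sampling times (h).
#' @param concs concentrations (>= 0) at `times`.
#' @return AUC in concentration x time units.
#' @export
#' @examples
#' auc_linlog(c(0, 2), c(10, 10))  # 20, flat segment
#' auc_linlog(c(0, 1), c(10, 5))   # 5/log(2) = 7.213
auc_linlog <- function(times, concs) {
  if (length(times) != length(concs) || length(times) < 2L) {
    stop("need >= 2 matched (time, concentration) points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(concs < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  keep <- is.finite(times) & is.finite(concs)
  times <- times[keep]; concs <- concs[keep]
  if (length(times) < 2L) return(NA_real_)
  auc <- 0
  for (i in seq_len(length(times) - 1L)) {
    c1 <- concs[i]; c2 <- concs[i + 1L]; dt <- times[i + 1L] - times[i]
    auc <- auc + if (c1 > c2 && c2 > 0) {
      (c1 - c2) * dt / log(c1 / c2)
    } else {
      (c1 + c2) * dt / 2
    }
  }
  auc
}

#' Maximum observed concentration and its first time
#'
#' @param times sampling times (h).
#' @param concs concentrations at `times`.
#' @return list with `cmax` and `tmax`; ties in the maximum resolve to
#'   the earliest time.
#' @export
cmax_tmax <- function(times, concs) {
  keep <- is.finite(concs)
  times <- times[keep]; concs <- concs[keep]
  if (length(concs) == 0L) stop("empty concentration profile", call. = FALSE)
  ord <- order(times)
  times <- times[ord]; concs <- concs[ord]
  i <- which.max(concs)  # which.max returns the first maximum
  list(cmax = concs[i], tmax = times[i])
}

#' Terminal elimination rate from log-linear regression
#'
#' Fits `log(C)` against time over a terminal point set.  When
#' `selection = "auto"`, candidate sets are the last k >= 3 positive
#' concentrations strictly after Tmax; among candidates the set with the
#' highest adjusted R-squared wins, preferring (when attainable) sets
#' whose time span covers at least two estimated half-lives.
#'
#' @param times,concs the concentration-time profile.
#' @param selection `"auto"` or an integer vector of indices into
#'   `times` to use directly.
#' @return list with `lambda_z` (1/h), `t_half` (h), `n_points`,
#'   `r_squared_adj`, `span_h`, and `estimable` (FALSE, with `NA`
#'   estimates, when no valid terminal fit exists -- a flag, not an error).
#' @export
fit_lambda_z <- function(times, concs, selection = "auto") {
  not_estimable <- list(lambda_z = NA_real_, t_half = NA_real_,
                        n_points = 0L, r_squared_adj = NA_real_,
                        span_h = NA_real_, estimable = FALSE)
  keep <- is.finite(times) & is.finite(concs)
  times <- times[keep]; concs <- concs[keep]
  if (length(times) < 3L) return(not_estimable)
  ord <- order(times); times <- times[ord]; concs <- concs[ord]

  fit_set <- function(idx) {
    tt <- times[idx]; cc <- concs[idx]
    if (length(tt) < 3L || any(cc <= 0)) return(NULL)
    f <- stats::lm(log(cc) ~ tt)
    slope <- unname(stats::coef(f)[2L])
    # require a genuine decline; a numerically-zero slope on flat data is
    # not an estimable terminal phase
    if (!is.finite(slope) || slope >= -1e-12) return(NULL)
    lc <- log(cc)
    r2 <- 1 - sum(stats::residuals(f)^2) / sum((lc - mean(lc))^2)
    n <- length(tt)
    list(lambda_z = -slope, t_half = log(2) / -slope,
         n_points = n,
         r_squared_adj = 1 - (1 - r2) * (n - 1) / (n - 2),
         span_h = max(tt) - min(tt), estimable = TRUE)
  }

  if (!identical(selection, "auto")) {
    res <- fit_set(selection)
    return(res %||% not_estimable)
  }
  tmax_i <- which.max(concs)
  post <- which(seq_along(times) > tmax_i & concs > 0)
  if (length(post) < 3L) return(not_estimable)
  candidates <- lapply(3:length(post), function(k) {
    fit_set(utils::tail(post, k))
  })
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0L) return(not_estimable)
  spans_ok <- vapply(candidates, function(x) x$span_h >= 2 * x$t_half,
                     logical(1))
  pool <- if (any(spans_ok)) candidates[spans_ok] else candidates
  r2 <- vapply(pool, function(x) x$r_squared_adj, numeric(1))
  pool[[which.max(r2)]]
}

#' Extrapolate AUC to infinite time
#'
#' `AUC_inf = AUC_last + C_last / lambda_z`; the extrapolated fraction of
#' the total is recorded.
#'
#' @param auc_last AUC to the last quantifiable point.
#' @param c_last last quantifiable concentration.
#' @param lambda_z terminal rate constant (1/h); `NA` propagates.
#' @return list with `auc_inf` and `extrapolated_fraction`.
#' @export
auc_extrapolate <- function(auc_last, c_last, lambda_z) {
  if (is.na(lambda_z)) {
    return(list(auc_inf = NA_real_, extrapolated_fraction = NA_real_))
  }
  if (lambda_z <= 0) stop("`lambda_z` must be positive", call. = FALSE)
  tail_auc <- c_last / lambda_z
  auc_inf <- auc_last + tail_auc
  list(auc_inf = auc_inf,
       extrapolated_fraction = if (auc_inf > 0) tail_auc / auc_inf else 0)
}

#' Accumulation ratio over the common partial-AUC window
#'
#' Ratio of the steady-state to first-dose exposure over the same window
#' (here AUC over 0-10 h on Day 10 versus Day 1).
#'
#' @param auc_window_ss steady-state window AUC (Day 10).
#' @param auc_window_d1 first-dose window AUC (Day 1).
#' @return the ratio, or `NA` when the Day 1 window AUC is missing.
#' @export
accumulation_ratio <- function(auc_window_ss, auc_window_d1) {
  if (is.na(auc_window_ss) || is.na(auc_window_d1)) return(NA_real_)
  if (auc_window_ss <= 0 || auc_window_d1 <= 0) {
    stop("window AUCs must be positive", call. = FALSE)
  }
  auc_window_ss / auc_window_d1
}

#' Predicted accumulation ratio under linear kinetics
#'
#' For repeated dosing every `tau_h` with half-life `t_half_h`,
#' `Rac = 1 / (1 - 2^(-tau/t_half))`.
#'
#' @param tau_h dosing interval (h).
#' @param t_half_h half-life (h).
#' @return predicted accumulation ratio.
#' @export
predicted_accumulation <- function(tau_h, t_half_h) {
  stopifnot_scalar(tau_h, "tau_h", positive = TRUE)
  stopifnot_scalar(t_half_h, "t_half_h", positive = TRUE)
  1 / (1 - 2^(-tau_h / t_half_h))
}

#' Fraction of steady state attained after a dosing duration
#'
#' `1 - 2^(-duration/t_half)` under linear first-order kinetics.
#'
#' @param t_half_h half-life (h).
#' @param duration_h dosing duration (h).
#' @return fraction in `[0, 1)`.
#' @export
#' @examples
#' steady_state_fraction(16.4, 96)  # 0.983
steady_state_fraction <- function(t_half_h, duration_h) {
  stopifnot_scalar(t_half_h, "t_half_h", positive = TRUE)
  stopifnot_scalar(duration_h, "duration_h", nonneg = TRUE)
  1 - 2^(-duration_h / t_half_h)
}

#' Unbound concentration from the plasma free fraction
#'
#' @param total_conc total concentration (any unit).
#' @param free_fraction unbound fraction in `[0, 1]`.
#' @return unbound concentration in the same unit.
#' @export
unbound_concentration <- function(total_conc, free_fraction) {
  if (any(free_fraction < 0 | free_fraction > 1)) {
    stop("`free_fraction` must lie in [0, 1]", call. = FALSE)
  }
  total_conc * free_fraction
}

#' Per-subject non-compartmental analysis of one analyte
#'
#' Day 1: Cmax, first Tmax, AUC to the last quantifiable point, AUC
#' extrapolated to infinity, terminal half-life, plus the 0-10 h window
#' AUC needed for the accumulation ratio.  Day 10: Cmax, Tmax,
#' AUC over 0-10 h, and the accumulation ratio against the Day 1 window.
#' Predose values below quantitation enter as zero; embedded missing
#' values are excluded point-wise.
#'
#' Terminal-phase quantities (lambda-z, half-life, extrapolated AUC) are
#' only attempted when the profile extends beyond `min_terminal_span_h`,
#' so a steady-state profile sampled within one dosing interval reports
#' window quantities only.
#'
#' @param pk concentration table for one subject and analyte
#'   (`day`, `time_h`, `conc_nM`).
#' @param min_terminal_span_h minimum last sampling time (h) for a
#'   terminal-phase fit to be attempted.
#' @return one-row tibble per day with the NCA parameter set.
#' @export
nca_subject <- function(pk, min_terminal_span_h = 12) {
  out <- list()
  for (d in sort(unique(pk$day))) {
    prof <- pk[pk$day == d & is.finite(pk$conc_nM), , drop = FALSE]
    prof <- prof[order(prof$time_h), , drop = FALSE]
    if (nrow(prof) < 2L) next
    ct <- cmax_tmax(prof$time_h, prof$conc_nM)
    # last quantifiable point
    pos <- which(prof$conc_nM > 0)
    row <- tibble::tibble(day = d, cmax_nM = ct$cmax, tmax_h = ct$tmax,
                          auc_last_nM_h = NA_real_, auc_0_10_nM_h = NA_real_,
                          auc_inf_nM_h = NA_real_, lambda_z_per_h = NA_real_,
                          t_half_h = NA_real_,
                          extrapolated_fraction = NA_real_)
    if (length(pos) >= 2L) {
      last_i <- max(pos)
      row$auc_last_nM_h <- auc_linlog(prof$time_h[seq_len(last_i)],
                                      prof$conc_nM[seq_len(last_i)])
      lam <- if (max(prof$time_h) > min_terminal_span_h) {
        fit_lambda_z(prof$time_h, prof$conc_nM)
      } else {
        list(estimable = FALSE)
      }
      if (lam$estimable) {
        row$lambda_z_per_h <- lam$lambda_z
        row$t_half_h <- lam$t_half
        ext <- auc_extrapolate(row$auc_last_nM_h, prof$conc_nM[last_i],
                               lam$lambda_z)
        row$auc_inf_nM_h <- ext$auc_inf
        row$extrapolated_fraction <- ext$extrapolated_fraction
      }
    }
    in10 <- prof$time_h <= 10
    if (sum(in10) >= 2L) {
      row$auc_0_10_nM_h <- auc_linlog(prof$time_h[in10], prof$conc_nM[in10])
    }
    out[[as.character(d)]] <- row
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(res)
  # accumulation ratio on the steady-state day against the Day 1 window
  if (all(c(1, 10) %in% res$day)) {
    res$r_ac <- NA_real_
    res$r_ac[res$day == 10] <- accumulation_ratio(
      res$auc_0_10_nM_h[res$day == 10], res$auc_0_10_nM_h[res$day == 1])
  } else {
    res$r_ac <- NA_real_
  }
  res
}

#' Cohort-level NCA
#'
#' Runs [nca_subject()] for every subject x analyte in a concentration
#' table.
#'
#' @param pk concentration table (`subject_id`, `day`, `time_h`,
#'   `analyte`, `conc_nM`).
#' @return tibble of per-subject NCA parameters.
#' @export
run_nca <- function(pk) {
  pk |>
    dplyr::group_by(.data$subject_id, .data$analyte) |>
    dplyr::group_modify(~ nca_subject(.x)) |>
    dplyr::ungroup()
}

#' Summary statistics for a PK parameter
#'
#' Geometric mean with geometric CV% (log-normal convention), arithmetic
#' mean with SD, and median with range -- the three summary kinds used for
#' exposure parameters, half-life/accumulation, and Tmax respectively.
#'
#' @param values numeric vector (`NA` dropped).
#' @param kind `"geometric"`, `"arithmetic"` or `"median_range"`.
#' @return one-row tibble of class-appropriate statistics (all columns
#'   always present).
#' @export
summarize_parameter <- function(values,
                                kind = c("geometric", "arithmetic",
                                         "median_range")) {
  kind <- match.arg(kind)
  v <- values[is.finite(values)]
  out <- tibble::tibble(n = length(v), geo_mean = NA_real_,
                        geo_cv_pct = NA_real_, arith_mean = NA_real_,
                        sd = NA_real_, median = NA_real_,
                        min = NA_real_, max = NA_real_)
  if (length(v) == 0L) return(out)
  out$arith_mean <- mean(v)
  out$sd <- if (length(v) > 1L) stats::sd(v) else 0
  out$median <- stats::median(v)
  out$min <- min(v); out$max <- max(v)
  if (kind == "geometric") {
    gs <- geo_stats(v)
    out$geo_mean <- gs$geo_mean
    out$geo_cv_pct <- gs$geo_cv_pct
  }
  out
}

#' Mean metabolite/parent exposure ratio
#'
#' The arithmetic mean of per-subject ratios (not the ratio of summary
#' means) of a metabolite exposure parameter to the parent's.
#'
#' @param metabolite,parent per-subject values, matched by position.
#' @return mean ratio over subjects with both values present.
#' @export
metabolite_ratio <- function(metabolite, parent) {
  if (length(metabolite) != length(parent)) {
    stop("metabolite and parent vectors must be matched by subject",
         call. = FALSE)
  }
  keep <- is.finite(metabolite) & is.finite(parent) & parent > 0
  if (!any(keep)) return(NA_real_)
  mean(metabolite[keep] / parent[keep])
}

#' Table-style NCA summary by analyte, day and parameter
#'
#' Applies the conventional summary kind per parameter: geometric
#' mean/CV% for Cmax and AUCs, median (min, max) for Tmax, arithmetic
#' mean (SD) for half-life and the accumulation ratio.
#'
#' @param nca output of [run_nca()].
#' @return tidy tibble (`analyte`, `day`, `parameter`, statistics).
#' @export
nca_summary <- function(nca) {
  kinds <- c(cmax_nM = "geometric", auc_last_nM_h = "geometric",
             auc_inf_nM_h = "geometric", auc_0_10_nM_h = "geometric",
             tmax_h = "median_range", t_half_h = "arithmetic",
             r_ac = "arithmetic")
  rows <- list()
  for (a in unique(nca$analyte)) {
    for (d in sort(unique(nca$day))) {
      sub <- nca[nca$analyte == a & nca$day == d, , drop = FALSE]
      if (nrow(sub) == 0L) next
      for (p in names(kinds)) {
        vals <- sub[[p]]
        if (all(!is.finite(vals))) next
        stat <- summarize_parameter(vals, kinds[[p]])
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(analyte = a, day = d, parameter = p,
                         kind = kinds[[p]]), stat)
      }
    }
  }
  dplyr::bind_rows(rows)
}
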