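# Concentration-QTc (and concentration-HR) mixed-effects model hierarchy.
#
# Model: y_ij = intercept + f(conc_ij; theta) + x_ij' beta + eta_i + eps_ij,
# with eta_i ~ N(0, omega^2) a subject random intercept and
# eps_ij ~ N(0, sigma^2) additive residual error.  Because the random
# effect enters additively, the marginal distribution of each subject's
# vector is multivariate normal with compound-symmetric covariance
# sigma^2 I + omega^2 J, so the marginal likelihood is available in
# closed form (no linearization) and is maximized directly.
#
# Structural forms f:
#   no_effect     0
#   linear        slope * C
#   emax          Emax * C / (EC50 + C)
#   sigmoid_emax  Emax * C^gamma / (EC50^gamma + C^gamma)

cqt_forms <- c("no_effect", "linear", "emax", "sigmoid_emax")

# Number of structural fixed effects (incl. intercept) per form.
form_npar <- c(no_effect = 1L, linear = 2L, emax = 3L, sigmoid_emax = 4L)

# Structural drug effect at concentrations conc for a theta list.
cqt_effect <- function(form, theta, conc) {
  switch(form,
         no_effect = rep(0, length(conc)),
         linear = theta$slope * conc,
         emax = theta$emax * conc / (theta$ec50 + conc),
         sigmoid_emax = {
           cg <- conc^theta$gamma
           theta$emax * cg / (theta$ec50^theta$gamma + cg)
         })
}

# Unpack the working parameter vector into natural-scale components.
unpack_pars <- function(par, form, n_cov) {
  k <- form_npar[[form]]
  theta <- list(intercept = par[1L])
  if (form == "linear") theta$slope <- par[2L]
  if (form %in% c("emax", "sigmoid_emax")) {
    theta$emax <- par[2L]
    theta$ec50 <- exp(par[3L])
  }
  if (form == "sigmoid_emax") theta$gamma <- exp(par[4L])
  beta <- if (n_cov > 0L) par[k + seq_len(n_cov)] else numeric(0)
  list(theta = theta, beta = beta,
       omega = exp(par[k + n_cov + 1L]), sigma = exp(par[k + n_cov + 2L]))
}

# Structural regressor g(conc) multiplying the linear coefficient
# (slope or Emax); NULL for the no-effect model.
struct_col <- function(form, conc, ec50 = NULL, gamma = 1) {
  switch(form,
         no_effect = NULL,
         linear = conc,
         emax = conc / (ec50 + conc),
         sigmoid_emax = {
           cg <- conc^gamma
           cg / (ec50^gamma + cg)
         })
}

# Exact -2 log marginal likelihood with all linear coefficients
# (intercept, slope/Emax, covariate shifts) profiled out by GLS for
# given nonlinear/variance parameters.  Returns the objective with the
# GLS coefficients in attribute "beta".
cqt_neg2ll_profiled <- function(par_red, form, conc, y, subj, X, n_i) {
  nl <- switch(form, no_effect = 0L, linear = 0L, emax = 1L,
               sigmoid_emax = 2L)
  ec50 <- if (nl >= 1L) exp(par_red[1L]) else NULL
  gamma <- if (nl >= 2L) exp(par_red[2L]) else 1
  w2 <- exp(par_red[nl + 1L])^2
  s2 <- exp(par_red[nl + 2L])^2
  Z <- cbind(rep(1, length(y)), struct_col(form, conc, ec50, gamma), X)
  c_i <- w2 / (s2 + n_i * w2)
  Zs <- rowsum(Z, subj, reorder = FALSE)
  ys <- rowsum(y, subj, reorder = FALSE)[, 1L]
  A <- crossprod(Z) - crossprod(Zs, Zs * c_i)
  b <- crossprod(Z, y) - crossprod(Zs, ys * c_i)
  beta <- tryCatch(solve(A, b)[, 1L], error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(1e10)
  r <- y - drop(Z %*% beta)
  sr <- rowsum(r, subj, reorder = FALSE)[, 1L]
  ssr <- rowsum(r * r, subj, reorder = FALSE)[, 1L]
  val <- sum(n_i * log(2 * pi * s2) + log1p(n_i * w2 / s2) +
               (ssr - w2 * sr^2 / (s2 + n_i * w2)) / s2)
  attr(val, "beta") <- beta
  val
}

# -2 log marginal likelihood, exact, via the Woodbury identity for the
# compound-symmetric subject covariance.
cqt_neg2ll <- function(par, form, conc, y, subj, X) {
  p <- unpack_pars(par, form, if (is.null(X)) 0L else ncol(X))
  mu <- p$theta$intercept + cqt_effect(form, p$theta, conc)
  if (!is.null(X)) mu <- mu + drop(X %*% p$beta)
  r <- y - mu
  s2 <- p$sigma^2; w2 <- p$omega^2
  n_i <- tabulate(subj)
  sr <- rowsum(r, subj, reorder = FALSE)[, 1L]
  ssr <- rowsum(r * r, subj, reorder = FALSE)[, 1L]
  denom <- s2 + n_i * w2
  sum(n_i * log(2 * pi * s2) + log1p(n_i * w2 / s2) +
        (ssr - w2 * sr^2 / denom) / s2)
}

# Build a covariate design matrix (no intercept column) from named
# columns; factors/characters are dummy-coded, numerics centered.
covariate_matrix <- function(data, covariates) {
  if (is.null(covariates) || length(covariates) == 0L) return(NULL)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0L) {
    stop("covariates not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  cols <- lapply(covariates, function(cv) {
    x <- data[[cv]]
    if (is.numeric(x) && length(unique(x)) > 2L) {
      m <- matrix(x - mean(x), ncol = 1L,
                  dimnames = list(NULL, cv))
    } else {
      f <- factor(x)
      if (nlevels(f) < 2L) {
        stop(sprintf("covariate `%s` is constant", cv), call. = FALSE)
      }
      m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
      colnames(m) <- paste0(cv, levels(f)[-1L])
      m
    }
    m
  })
  do.call(cbind, cols)
}

#' Fit a concentration-QTc mixed-effects model
#'
#' Maximizes the exact marginal likelihood of an additive
#' random-intercept model for change-from-baseline QTc (or heart rate)
#' against time-matched plasma concentration, for one of four structural
#' forms: no drug effect, linear slope, Emax, or sigmoid Emax.  The
#' between-subject SD applies to the intercept only and the residual
#' error is additive, so the marginal likelihood is a closed-form
#' multivariate normal and no linearization is involved.
#'
#' @param observations tibble with `subject_id`, `conc_nM` (>= 0;
#'   baseline-day records carry 0) and `value` (the response, e.g.
#'   change-from-baseline QTc in ms), plus any covariate columns.
#' @param form structural model, one of `"no_effect"`, `"linear"`,
#'   `"emax"`, `"sigmoid_emax"`.
#' @param covariates optional character vector of covariate columns
#'   entering as additive shifts on the intercept.
#' @param start optional working-scale start vector (used by the
#'   bootstrap and for warm starts from a nested parent fit).
#' @param n_starts number of EC50 starting points tried for the Emax
#'   forms.
#' @return object of class `cqt_fit`: `form`, `theta` (natural-scale
#'   fixed effects), `beta`, `omega`, `sigma`, `se` (natural scale),
#'   `se_pct`, `ofv` (-2 log-likelihood), `aic`, `n_subjects`, `n_obs`,
#'   `n_par`, `convergence`, `boundary`, and the data used.
#' @export
fit_cqt <- function(observations, form = c("no_effect", "linear", "emax",
                                           "sigmoid_emax"),
                    covariates = NULL, start = NULL, n_starts = 2L) {
  form <- match.arg(form)
  obs <- observations[is.finite(observations$value) &
                        is.finite(observations$conc_nM), , drop = FALSE]
  if (any(obs$conc_nM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (dplyr::n_distinct(obs$subject_id) < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  subj <- as.integer(factor(obs$subject_id, levels = unique(obs$subject_id)))
  conc <- obs$conc_nM
  y <- obs$value
  X <- covariate_matrix(obs, covariates)
  n_cov <- if (is.null(X)) 0L else ncol(X)
  k <- form_npar[[form]]
  maxc <- max(conc)

  # The fixed effects are linear given EC50/gamma and the variance
  # components, so they are profiled out exactly by GLS and the search
  # runs over the (at most four) remaining parameters.
  n_i <- tabulate(subj)
  nl <- switch(form, no_effect = 0L, linear = 0L, emax = 1L,
               sigmoid_emax = 2L)
  sd_y <- max(stats::sd(y), 1e-6)
  lower <- c(if (nl >= 1L) log(max(maxc, 1e-6) * 1e-3),
             if (nl >= 2L) log(0.1),
             log(sd_y) - 14,     # omega floor
             log(sd_y) - 10)     # sigma floor
  upper <- c(if (nl >= 1L) log(max(maxc, 1e-6) * 1e2),
             if (nl >= 2L) log(10),
             rep(Inf, 2L))

  full_to_reduced <- function(p_full) {
    c(if (nl >= 1L) p_full[3L], if (nl >= 2L) p_full[4L],
      utils::tail(p_full, 2L))
  }
  sub_means <- rowsum(y, subj, reorder = FALSE)[, 1L] / n_i
  var_start <- c(log(max(stats::sd(sub_means), 1e-3)),
                 log(max(stats::sd(y - sub_means[subj]), 1e-3)))
  starts <- list()
  if (!is.null(start)) starts <- list(full_to_reduced(start))
  starts <- c(starts, list(c(if (nl >= 1L) log(max(maxc / 2, 1e-3)),
                             if (nl >= 2L) 0, var_start)))
  if (nl >= 1L && n_starts > 1L && maxc > 0) {
    for (frac in utils::head(c(0.1, 2), n_starts - 1L)) {
      starts <- c(starts, list(c(log(maxc * frac), if (nl >= 2L) 0,
                                 var_start)))
    }
  }
  obj_red <- function(p) {
    as.numeric(cqt_neg2ll_profiled(p, form, conc, y, subj, X, n_i))
  }
  best <- NULL
  for (s0 in starts) {
    s0 <- pmin(pmax(s0, lower), upper)
    fit <- tryCatch(
      stats::nlminb(s0, obj_red, lower = lower, upper = upper,
                    control = list(iter.max = 500, eval.max = 1000)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (fit$convergence != 0L) {
      # restart from the stalled point; this routinely clears nlminb's
      # false-convergence exits
      fit2 <- tryCatch(
        stats::nlminb(fit$par, obj_red, lower = lower, upper = upper,
                      control = list(iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (!is.null(fit2) && is.finite(fit2$objective) &&
          fit2$objective <= fit$objective) {
        fit <- fit2
      }
    }
    if (is.null(best) || fit$objective < best$objective - 1e-10) best <- fit
  }
  if (is.null(best)) {
    stop("concentration-QTc fit failed to converge from all starting points",
         call. = FALSE)
  }
  red <- best$par
  prof <- cqt_neg2ll_profiled(red, form, conc, y, subj, X, n_i)
  beta_gls <- attr(prof, "beta")
  # reassemble the full working vector (fixed effects + variances)
  theta_head <- c(beta_gls[1L],
                  if (form != "no_effect") beta_gls[2L],
                  if (nl >= 1L) red[1L],
                  if (nl >= 2L) red[2L])
  beta_cov <- if (n_cov > 0L) {
    utils::tail(beta_gls, n_cov)
  } else numeric(0)
  par <- c(theta_head, beta_cov, utils::tail(red, 2L))
  p <- unpack_pars(par, form, n_cov)
  obj <- function(pp) cqt_neg2ll(pp, form, conc, y, subj, X)

  # boundary diagnostics (EC50 pinned to its box, omega at the floor)
  boundary <- nl >= 1L &&
    (red[1L] <= lower[1L] + 1e-6 || red[1L] >= upper[1L] - 1e-6)
  omega_floor <- red[nl + 1L] <= lower[nl + 1L] + 1e-6

  # SEs: numerical Hessian of the -2LL on the working scale, delta-method
  # back to the natural scale for log-parameterized components
  se_work <- rep(NA_real_, length(par))
  vcov_ok <- tryCatch({
    H <- stats::optimHess(par, obj)
    V <- 2 * solve(H)
    d <- diag(V)
    se_work <- ifelse(d > 0, sqrt(pmax(d, 0)), NA_real_)
    TRUE
  }, error = function(e) FALSE)

  nm <- c("intercept",
          switch(form, no_effect = NULL, linear = "slope",
                 emax = c("emax", "ec50"),
                 sigmoid_emax = c("emax", "ec50", "gamma")),
          if (n_cov > 0L) colnames(X), "omega", "sigma")
  est <- c(unlist(p$theta), p$beta, omega = p$omega, sigma = p$sigma)
  names(est) <- nm
  se <- se_work
  log_scale <- nm %in% c("ec50", "gamma", "omega", "sigma")
  se[log_scale] <- se[log_scale] * est[log_scale]  # delta method
  names(se) <- nm

  structure(list(
    form = form, theta = p$theta, beta = stats::setNames(p$beta, colnames(X)),
    covariates = covariates,
    omega = p$omega, sigma = p$sigma,
    estimates = est, se = se,
    se_pct = ifelse(abs(est) > 0, 100 * se / abs(est), NA_real_),
    ofv = best$objective,
    n_par = length(par), aic = best$objective + 2 * length(par),
    n_subjects = max(subj), n_obs = length(y),
    convergence = best$convergence, boundary = boundary,
    omega_at_floor = omega_floor, vcov_ok = vcov_ok,
    par = par, data = obs), class = "cqt_fit")
}

#' @export
print.cqt_fit <- function(x, ...) {
  cat(sprintf("Concentration-QTc mixed-effects fit: %s model\n", x$form))
  cat(sprintf("  %d observations, %d subjects; OFV (-2LL) = %.3f, AIC = %.3f\n",
              x$n_obs, x$n_subjects, x$ofv, x$aic))
  tab <- data.frame(estimate = signif(x$estimates, 5),
                    se = signif(x$se, 4))
  print(tab)
  if (x$boundary) cat("  note: EC50 at a search bound\n")
  invisible(x)
}

#' Construct a concentration-QTc model from given parameter values
#'
#' Builds a `cqt_fit` object directly from stated parameters (for
#' example published model moments) so it can drive
#' [simulate_population()] or prediction without refitting.
#'
#' @param form structural form.
#' @param intercept intercept (ms).
#' @param slope,emax,ec50,gamma structural parameters as required by
#'   `form`.
#' @param omega between-subject SD of the intercept (ms).
#' @param sigma residual SD (ms).
#' @return a minimal `cqt_fit`.
#' @export
as_cqt_fit <- function(form = c("no_effect", "linear", "emax",
                                "sigmoid_emax"),
                       intercept = 0, slope = NULL, emax = NULL,
                       ec50 = NULL, gamma = 1, omega = 0, sigma = 0) {
  form <- match.arg(form)
  theta <- list(intercept = intercept)
  if (form == "linear") theta$slope <- slope %||% 0
  if (form %in% c("emax", "sigmoid_emax")) {
    theta$emax <- emax %||% 0
    theta$ec50 <- ec50 %||% stop("`ec50` required", call. = FALSE)
  }
  if (form == "sigmoid_emax") theta$gamma <- gamma
  est <- c(unlist(theta), omega = omega, sigma = sigma)
  structure(list(form = form, theta = theta, beta = numeric(0),
                 covariates = NULL, omega = omega, sigma = sigma,
                 estimates = est, se = rep(NA_real_, length(est)),
                 se_pct = rep(NA_real_, length(est)),
                 ofv = NA_real_, n_par = length(est),
                 aic = NA_real_, n_subjects = NA_integer_,
                 n_obs = NA_integer_, convergence = 0L,
                 boundary = FALSE, omega_at_floor = FALSE, vcov_ok = FALSE,
                 par = NULL, data = NULL), class = "cqt_fit")
}

#' Wald confidence interval for a fitted parameter
#'
#' @param fit a `cqt_fit`.
#' @param parameter parameter name (e.g. `"slope"`).
#' @param level two-sided confidence level.
#' @return named numeric `c(lower, estimate, upper)`.
#' @export
confint_cqt <- function(fit, parameter, level = 0.95) {
  est <- fit$estimates[[parameter]]
  se <- fit$se[[parameter]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = est - z * se, estimate = est, upper = est + z * se)
}

#' Select the final model from a fitted hierarchy
#'
#' Compares candidate structural fits on the same observations: nested
#' pairs by likelihood-ratio test (chi-squared with df equal to the
#' added parameters, default alpha 0.05), non-nested candidates by AIC;
#' ties favor fewer parameters.  The no-effect model is the root;
#' a sigmoid Emax candidate must additionally beat the plain Emax model
#' when one is supplied.
#'
#' @param fits list of `cqt_fit` objects sharing the same data.
#' @param alpha significance level per likelihood-ratio test.
#' @return the selected `cqt_fit`, with attributes `rationale` (character)
#'   and `comparison` (tibble of tests).
#' @export
select_model <- function(fits, alpha = 0.05) {
  if (length(fits) == 0L) stop("no candidate fits supplied", call. = FALSE)
  forms <- vapply(fits, function(f) f$form, character(1))
  names(fits) <- forms
  n_obs <- vapply(fits, function(f) f$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1L) {
    stop("candidate fits do not share the same observations", call. = FALSE)
  }
  ord <- order(form_npar[forms])
  fits <- fits[ord]; forms <- forms[ord]
  base <- fits[[1L]]

  parent_of <- function(form) {
    switch(form,
           linear = "no_effect",
           emax = "no_effect",
           sigmoid_emax = if ("emax" %in% forms) "emax" else "no_effect",
           NULL)
  }
  comp <- list(); sig <- logical(0)
  for (f in forms[-1L]) {
    pf <- parent_of(f)
    if (is.null(pf) || !pf %in% forms) pf <- forms[1L]
    d_ofv <- fits[[pf]]$ofv - fits[[f]]$ofv
    df <- fits[[f]]$n_par - fits[[pf]]$n_par
    pval <- stats::pchisq(max(d_ofv, 0), df = df, lower.tail = FALSE)
    ok <- d_ofv > stats::qchisq(1 - alpha, df = df)
    comp[[f]] <- tibble::tibble(model = f, parent = pf, d_ofv = d_ofv,
                                df = df, p_value = pval, significant = ok)
    sig[f] <- ok
  }
  # a candidate is retained only when every LRT along its nested chain
  # back to the root is significant (stepwise model building)
  chain_ok <- function(f) {
    while (f %in% names(sig)) {
      if (!sig[[f]]) return(FALSE)
      f <- comp[[f]]$parent
    }
    TRUE
  }
  passed <- Filter(chain_ok, forms[-1L])
  comparison <- dplyr::bind_rows(comp)
  if (length(passed) == 0L) {
    sel <- base
    why <- sprintf(
      "no candidate improved on the %s model by the likelihood-ratio criterion (alpha = %g)",
      base$form, alpha)
  } else {
    aics <- vapply(fits[passed], function(f) f$aic, numeric(1))
    npars <- form_npar[passed]
    best_aic <- min(aics)
    tied <- passed[aics <= best_aic + 1e-6]
    sel_form <- tied[which.min(npars[tied])]
    sel <- fits[[sel_form]]
    why <- sprintf("%s selected: significant LRT vs %s and lowest AIC among improving candidates",
                   sel_form, parent_of(sel_form) %||% base$form)
  }
  attr(sel, "rationale") <- why
  attr(sel, "comparison") <- comparison
  sel
}

#' Fit the full structural hierarchy and select a final model
#'
#' Fits the no-effect, linear, Emax and sigmoid Emax models (richer forms
#' warm-started from their nested parent so the objective can only
#' improve along the chain) and applies [select_model()].
#'
#' @inheritParams fit_cqt
#' @inheritParams select_model
#' @param forms structural forms to include.
#' @return list with `fits` (named list) and `final` (selected fit).
#' @export
fit_cqt_hierarchy <- function(observations,
                              forms = c("no_effect", "linear", "emax",
                                        "sigmoid_emax"),
                              covariates = NULL, alpha = 0.05) {
  forms <- match.arg(forms, cqt_forms, several.ok = TRUE)
  forms <- cqt_forms[cqt_forms %in% forms]
  fits <- list()
  n_cov <- if (is.null(covariates)) 0L else {
    ncol(covariate_matrix(observations, covariates))
  }
  grow_start <- function(parent, form) {
    # embed the parent solution into the richer parameter vector so the
    # optimizer starts at (and can only improve on) the parent's OFV
    if (is.null(parent)) return(NULL)
    pp <- parent$par
    k_p <- form_npar[[parent$form]]
    head_p <- pp[seq_len(k_p)]
    tail_p <- pp[(k_p + 1L):length(pp)]
    maxc <- max(observations$conc_nM, na.rm = TRUE)
    ec50_mid <- log(max(maxc / 2, 1e-3))
    new_head <- switch(form,
                       linear = c(head_p[1L], 0),
                       emax = if (parent$form == "no_effect") {
                         c(head_p[1L], 0, ec50_mid)
                       } else c(head_p[1L], 0, ec50_mid),
                       sigmoid_emax = if (parent$form == "emax") {
                         c(head_p, 0)
                       } else c(head_p[1L], 0, ec50_mid, 0))
    c(new_head, tail_p)
  }
  parent_fit <- NULL
  for (f in forms) {
    parent <- switch(f,
                     no_effect = NULL,
                     linear = fits[["no_effect"]],
                     emax = fits[["no_effect"]],
                     sigmoid_emax = fits[["emax"]] %||% fits[["no_effect"]])
    fits[[f]] <- fit_cqt(observations, f, covariates = covariates,
                         start = grow_start(parent, f))
  }
  list(fits = fits, final = select_model(fits, alpha = alpha))
}

#' Screen covariates on the model intercept
#'
#' Forward selection of additive intercept shifts: each candidate
#' covariate is added to the current model and kept when the
#' likelihood-ratio test is significant at `alpha` (default 0.01).
#' Constant covariates are skipped with a note.
#'
#' @param observations as in [fit_cqt()], including covariate columns.
#' @param form structural form of the base model.
#' @param covariates candidate covariate column names.
#' @param alpha forward-inclusion significance level.
#' @return list with `retained` (character), `p_values` (tibble over
#'   screening steps), `skipped` (constant covariates) and `final_fit`.
#' @export
screen_covariates <- function(observations, form = "no_effect",
                              covariates = c("sex", "bmi", "ecog"),
                              alpha = 0.01) {
  const <- vapply(covariates, function(cv) {
    length(unique(observations[[cv]])) < 2L
  }, logical(1))
  skipped <- covariates[const]
  pool <- covariates[!const]
  retained <- character(0)
  steps <- list()
  current <- fit_cqt(observations, form)
  repeat {
    if (length(pool) == 0L) break
    trials <- lapply(pool, function(cv) {
      f1 <- fit_cqt(observations, form, covariates = c(retained, cv))
      df <- f1$n_par - current$n_par
      p <- stats::pchisq(max(current$ofv - f1$ofv, 0), df = df,
                         lower.tail = FALSE)
      list(cov = cv, fit = f1, p = p, df = df)
    })
    ps <- vapply(trials, function(t) t$p, numeric(1))
    steps[[length(steps) + 1L]] <- tibble::tibble(
      step = length(steps) + 1L,
      covariate = vapply(trials, function(t) t$cov, character(1)),
      p_value = ps)
    best <- which.min(ps)
    if (ps[best] >= alpha) break
    retained <- c(retained, trials[[best]]$cov)
    current <- trials[[best]]$fit
    pool <- setdiff(pool, trials[[best]]$cov)
  }
  list(retained = retained,
       p_values = if (length(steps)) dplyr::bind_rows(steps) else
         tibble::tibble(step = integer(), covariate = character(),
                        p_value = double()),
       skipped = skipped, final_fit = current)
}

#' Concentration-heart-rate model
#'
#' The same mixed-effects machinery applied to heart rate: HR varies
#' between subjects about a population intercept (around 75 bpm in a
#' typical oncology cohort) and the structural forms test whether drug
#' concentration shifts it.
#'
#' @param observations tibble with `subject_id`, `conc_nM` and `value`
#'   (heart rate, bpm).
#' @inheritParams fit_cqt
#' @return a `cqt_fit` for the heart-rate response.
#' @export
fit_hr_model <- function(observations, form = "no_effect", ...) {
  fit_cqt(observations, form, ...)
}
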