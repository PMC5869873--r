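# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean and geometric CV% of positive values
#'
#' Geometric mean is `exp(mean(log(x)))`; the geometric coefficient of
#' variation uses the log-variance formula `100 * sqrt(exp(s^2) - 1)` with
#' `s` the SD of `log(x)`, i.e. the CV of a log-normal distribution with
#' that log-scale SD.
#'
#' @param x numeric vector of strictly positive values (`NA`s dropped).
#' @return named list with `geo_mean` and `geo_cv_pct`.
#' @export
geo_stats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    return(list(geo_mean = NA_real_, geo_cv_pct = NA_real_))
  }
  if (any(x <= 0)) {
    stop("geometric summary requires strictly positive values; offending: ",
         paste(utils::head(signif(x[x <= 0], 4), 5L), collapse = ", "),
         call. = FALSE)
  }
  lx <- log(x)
  s2 <- if (length(lx) > 1L) stats::var(lx) else 0
  list(geo_mean = exp(mean(lx)), geo_cv_pct = 100 * sqrt(exp(s2) - 1))
}

# Run `expr` under a temporary RNG state seeded with `seed`; NULL seed means
# use (and advance) the current RNG stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

# Derive a stream-specific child seed from a master seed, keeping the result
# inside the 32-bit signed integer range.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + as.double(index) * 10007) %% 2147483629)
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}
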