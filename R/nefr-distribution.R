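#' The New Extended Frechet Distribution
#'
#' Density, distribution function, quantile function, hazard rate and random
#' generation for the new extended Frechet (NE-Fr) distribution with scale
#' parameter `alpha` and shape parameters `beta` (tail) and `lambda`.
#'
#' The NE-Fr distribution arises from inserting the Frechet (inverse Weibull)
#' cumulative distribution function into a ratio-type generating family.  Its
#' cdf is
#' \deqn{F(z) = 1 - \left[\frac{1 - e^{-2\alpha z^{-\beta}}}
#'   {1 - \bar\lambda e^{-2\alpha z^{-\beta}}}\right]^{\lambda}, \quad z > 0,}
#' where \eqn{\bar\lambda = 1 - \lambda}.  For \eqn{\lambda = 1} the
#' distribution reduces to the Frechet distribution with scale \eqn{2\alpha}
#' and shape \eqn{\beta} (see [pfrechet()]).  The survival function has a
#' power-law tail \eqn{S(z) \sim (2\alpha/\lambda)^\lambda z^{-\beta\lambda}},
#' so the tail index is \eqn{\beta\lambda} and the \eqn{r}-th moment exists
#' if and only if \eqn{r < \beta\lambda}.
#'
#' All functions are evaluated through the log-scale identities
#' (`log1p`/`expm1`) so that extreme arguments (`z` between 1e-12 and 1e12,
#' probabilities within double precision of 0 or 1) do not produce `NaN`
#' through premature under- or overflow.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations to generate.
#' @param alpha positive scale-type parameter \eqn{\alpha}.
#' @param beta positive tail shape parameter \eqn{\beta}.
#' @param lambda positive shape parameter \eqn{\lambda}.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(Z \le z)}, otherwise \eqn{P(Z > z)} (the survival function).
#' @param extended logical; if `TRUE`, `qnefr()` additionally accepts the
#'   boundary probabilities 0 and 1, mapped to 0 and `Inf`.  The quantile
#'   grows like \eqn{(1-p)^{-1/(\beta\lambda)}} as \eqn{p \to 1}; it is not
#'   clamped.
#'
#' @return `dnefr` gives the density, `pnefr` the distribution (or survival)
#'   function, `qnefr` the quantile function, `hnefr` the hazard rate and
#'   `rnefr` generates random deviates by inversion.
#'
#' @examples
#' pnefr(1, alpha = 0.5, beta = 1, lambda = 2)
#' qnefr(0.5, alpha = 0.4, beta = 0.4, lambda = 0.9)   # median, approx 2.29
#' set.seed(1)
#' z <- rnefr(500, 0.5, 0.8, 0.3)
#' @name nefr-distribution
NULL

# -- parameter and argument validation ---------------------------------------

check_nefr_params <- function(alpha, beta, lambda) {
  if (!is.numeric(alpha) || !is.numeric(beta) || !is.numeric(lambda) ||
      length(alpha) != 1L || length(beta) != 1L || length(lambda) != 1L ||
      !is.finite(alpha) || !is.finite(beta) || !is.finite(lambda) ||
      alpha <= 0 || beta <= 0 || lambda <= 0) {
    stop("'alpha', 'beta' and 'lambda' must be single positive finite numbers",
         call. = FALSE)
  }
  invisible(NULL)
}

check_positive_data <- function(z, what = "x") {
  if (!is.numeric(z) || length(z) < 1L) {
    stop(sprintf("'%s' must be a non-empty numeric vector", what), call. = FALSE)
  }
  bad <- which(!is.finite(z) | z <= 0)
  if (length(bad)) {
    stop(sprintf("'%s' must be strictly positive and finite (offending element %d: %s)",
                 what, bad[1L], format(z[bad[1L]])), call. = FALSE)
  }
  invisible(NULL)
}

#' Parameter container for the NE-Fr distribution
#'
#' Bundles the parameter triple \eqn{(\alpha, \beta, \lambda)} after
#' validation, together with the derived quantity \eqn{\bar\lambda =
#' 1 - \lambda} used throughout the distribution's formulas.  `lam_bar`
#' is always derived, never set independently.
#'
#' @inheritParams nefr-distribution
#' @return An object of class `"nefr_params"`: a list with elements
#'   `alpha`, `beta`, `lambda` and `lam_bar`.
#' @examples
#' nefr_params(0.5, 1, 2)
#' @export
nefr_params <- function(alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  structure(list(alpha = alpha, beta = beta, lambda = lambda,
                 lam_bar = 1 - lambda),
            class = "nefr_params")
}

#' @export
print.nefr_params <- function(x, ...) {
  cat(sprintf("NE-Fr parameters: alpha = %g, beta = %g, lambda = %g (lam_bar = %g)\n",
              x$alpha, x$beta, x$lambda, x$lam_bar))
  cat(sprintf("tail index beta*lambda = %g\n", x$beta * x$lambda))
  invisible(x)
}

# log(1 - exp(-t)) for t > 0, accurate for both small and large t
log1mexp <- function(t) {
  ifelse(t > log(2), log1p(-exp(-t)), log(-expm1(-t)))
}

# log survival function; the numerically safe core used by everything else.
# t = 2 alpha z^-beta is formed on the log scale so z in [1e-12, 1e12] is safe.
nefr_logsf <- function(z, alpha, beta, lambda) {
  lam_bar <- 1 - lambda
  t <- exp(log(2 * alpha) - beta * log(z))
  u <- exp(-t)
  lambda * (log1mexp(t) - log1p(-lam_bar * u))
}

nefr_logpdf <- function(z, alpha, beta, lambda) {
  lam_bar <- 1 - lambda
  t <- exp(log(2 * alpha) - beta * log(z))
  u <- exp(-t)
  log(2) + 2 * log(lambda) + log(alpha) + log(beta) - (beta + 1) * log(z) -
    t + (lambda - 1) * log1mexp(t) - (lambda + 1) * log1p(-lam_bar * u)
}

#' @rdname nefr-distribution
#' @export
dnefr <- function(x, alpha, beta, lambda, log = FALSE) {
  check_nefr_params(alpha, beta, lambda)
  check_positive_data(x)
  lp <- nefr_logpdf(x, alpha, beta, lambda)
  if (log) lp else exp(lp)
}

#' @rdname nefr-distribution
#' @export
pnefr <- function(q, alpha, beta, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_nefr_params(alpha, beta, lambda)
  check_positive_data(q, "q")
  lsf <- nefr_logsf(q, alpha, beta, lambda)
  if (lower.tail) {
    if (log.p) log(-expm1(lsf)) else -expm1(lsf)
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname nefr-distribution
#' @export
qnefr <- function(p, alpha, beta, lambda, extended = FALSE) {
  check_nefr_params(alpha, beta, lambda)
  if (!is.numeric(p) || length(p) < 1L || anyNA(p)) {
    stop("'p' must be a numeric vector of probabilities", call. = FALSE)
  }
  lo <- if (extended) 0 else .Machine$double.xmin
  if (any(p < 0 | p > 1) || (!extended && any(p <= 0 | p >= 1))) {
    stop(if (extended) "'p' must lie in [0, 1]" else "'p' must lie strictly in (0, 1)",
         call. = FALSE)
  }
  w <- exp(log1p(-p) / lambda)
  lam_bar <- 1 - lambda
  # log[(1-w)/(1-lam_bar w)] via log1p keeps precision when both terms are
  # within rounding of 1 (p close to 1)
  lr <- log1p(-w) - log1p(-lam_bar * w)
  out <- exp((-1 / beta) * (log(-lr) - log(2 * alpha)))
  if (extended) {
    out[p == 0] <- 0
    out[p == 1] <- Inf
  }
  out
}

#' @rdname nefr-distribution
#' @export
rnefr <- function(n, alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  qnefr(stats::runif(n), alpha, beta, lambda)
}

#' @rdname nefr-distribution
#' @export
hnefr <- function(x, alpha, beta, lambda, log = FALSE) {
  check_nefr_params(alpha, beta, lambda)
  check_positive_data(x)
  lh <- nefr_logpdf(x, alpha, beta, lambda) - nefr_logsf(x, alpha, beta, lambda)
  if (log) lh else exp(lh)
}
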