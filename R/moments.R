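#' Raw moments of the NE-Fr distribution
#'
#' Computes \eqn{\mu'_r = E(Z^r)} either by adaptive quadrature (the
#' authoritative route) or by the truncated double-series expansion
#' \deqn{\mu'_r = \sum_{i,j} \varpi_{i,j}
#'   \frac{\Gamma(1 - r/\beta)}{\beta\,[2(i+j+1)\alpha]^{1-r/\beta}}.}
#'
#' Because the survival function decays like \eqn{z^{-\beta\lambda}}, the
#' moment of order `r` exists if and only if \eqn{r < \beta\lambda}; the
#' quadrature method flags non-existence via the `exists` field.  The series
#' expansion additionally needs \eqn{r < \beta} (each
#' \eqn{\Gamma(1 - r/\beta)} term has a pole at \eqn{r = \beta}) and
#' \eqn{\lambda < 2} (validity of the binomial expansion); within the joint
#' region both routes agree to at least five significant digits.
#'
#' @param r positive moment order (may be fractional).
#' @inheritParams nefr-distribution
#' @param method `"quadrature"` (default) integrates \eqn{Q(p)^r} over the
#'   unit interval; `"series"` sums the expansion above.
#' @param ctrl a [series_control()] object (series method only).
#' @return An object of class `"nefr_moment"`: a list with elements
#'   `order`, `value`, `exists` and `method`.  When `exists` is `FALSE`
#'   under the quadrature method, `value` carries the truncated-series
#'   number (if the series is computable) purely as a diagnostic.
#' @examples
#' nefr_moment(1, 0.5, 3, 2)
#' nefr_moment(1, 0.5, 3, 1.5, method = "series")
#' @export
nefr_moment <- function(r, alpha, beta, lambda,
                        method = c("quadrature", "series"),
                        ctrl = series_control()) {
  check_nefr_params(alpha, beta, lambda)
  method <- match.arg(method)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("'r' must be a single positive number", call. = FALSE)
  }
  exists <- r < beta * lambda
  if (method == "quadrature") {
    if (!exists) {
      val <- if (r < beta) {
        warning(sprintf(
          "moment of order %g does not exist (tail index beta*lambda = %g); ",
          r, beta * lambda), "reporting the truncated-series value",
          call. = FALSE)
        suppressWarnings(moment_series(r, alpha, beta, lambda, ctrl))
      } else {
        warning(sprintf(
          "moment of order %g does not exist (tail index beta*lambda = %g)",
          r, beta * lambda), call. = FALSE)
        NA_real_
      }
      return(structure(list(order = r, value = val, exists = FALSE,
                            method = method), class = "nefr_moment"))
    }
    val <- stats::integrate(function(p) qnefr(p, alpha, beta, lambda)^r,
                            0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
  } else {
    if (r >= beta) {
      stop(sprintf(
        "series moment undefined: Gamma(1 - r/beta) has a pole for r >= beta (r = %g, beta = %g)",
        r, beta), call. = FALSE)
    }
    val <- moment_series(r, alpha, beta, lambda, ctrl)
  }
  structure(list(order = r, value = val, exists = exists, method = method),
            class = "nefr_moment")
}

#' @export
print.nefr_moment <- function(x, ...) {
  cat(sprintf("E[Z^%g] = %g (%s method%s)\n", x$order, x$value, x$method,
              if (x$exists) "" else "; moment does not exist - diagnostic value"))
  invisible(x)
}

moment_series <- function(r, alpha, beta, lambda, ctrl) {
  g <- gamma(1 - r / beta)
  nefr_series_sum(alpha, beta, lambda,
                  function(k) g / (beta * (2 * (k + 1) * alpha)^(1 - r / beta)),
                  ctrl)
}

#' Laplace-type moment generating integral
#'
#' Evaluates \eqn{M(t) = \int_0^\infty e^{-tz} f(z)\,dz} by adaptive
#' quadrature.  Note the sign convention: the defining integral uses
#' \eqn{e^{-tz}}, so this is the Laplace transform of the density, finite
#' for every \eqn{t \ge 0} (the usual \eqn{E[e^{tZ}]} does not exist for a
#' heavy-tailed law).  \eqn{M(0) = 1} and \eqn{M} is nonincreasing in `t`.
#'
#' @param t nonnegative transform argument (vectorised).
#' @inheritParams nefr_moment
#' @return Numeric vector of transform values in (0, 1].
#' @examples
#' nefr_mgf(c(0, 1), 0.5, 1, 2)
#' @export
nefr_mgf <- function(t, alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  if (!is.numeric(t) || anyNA(t) || any(t < 0)) {
    stop("'t' must be nonnegative", call. = FALSE)
  }
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    stats::integrate(function(p) exp(-tt * qnefr(p, alpha, beta, lambda)),
                     0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1))
}

#' Incomplete and conditional moments, mean residual life, mean inactivity
#'
#' `nefr_incomplete_moment()` computes the lower incomplete moment
#' \eqn{\psi_s(t) = \int_0^t z^s f(z)\,dz}; `nefr_conditional_moment()`
#' computes \eqn{E(Z^s \mid Z > t) = \zeta_s(t) / S(t)} with
#' \eqn{\zeta_s(t) = \int_t^\infty z^s f(z)\,dz}; `nefr_mrl()` is the mean
#' residual life \eqn{\mu(t) = E(Z - t \mid Z > t)} and `nefr_mit()` the
#' mean inactivity time \eqn{M(t) = t - E(Z \mid Z \le t)}.
#'
#' Under the series method the incomplete moments use the expansion of the
#' density together with incomplete gamma integrals: with
#' \eqn{c = 2(i+j+1)\alpha},
#' \deqn{\psi_s(t) = \sum_{i,j} \varpi_{i,j}
#'   \frac{\Gamma(1-s/\beta,\; c\,t^{-\beta})}{\beta\, c^{1-s/\beta}}, \qquad
#'   \zeta_s(t) = \sum_{i,j} \varpi_{i,j}
#'   \frac{\gamma(1-s/\beta,\; c\,t^{-\beta})}{\beta\, c^{1-s/\beta}},}
#' where \eqn{\gamma} and \eqn{\Gamma} are the lower and upper incomplete
#' gamma functions.  (The substitution \eqn{y = c z^{-\beta}} is decreasing,
#' so the lower range of \eqn{z} maps to the upper tail of \eqn{y}.)
#' Existence requires \eqn{s < \beta\lambda} for \eqn{\zeta_s} (hence for
#' the conditional moment and the MRL, \eqn{\beta\lambda > 1}); the series
#' route further requires \eqn{s < \beta} and \eqn{\lambda < 2}.
#'
#' @param s positive moment order.
#' @param t positive time point.
#' @inheritParams nefr_moment
#' @return A single numeric value.
#' @examples
#' nefr_incomplete_moment(1, 1, 0.5, 3, 2)
#' nefr_mrl(1, 0.5, 3, 2)
#' nefr_mit(1, 0.5, 3, 2)
#' @name nefr-partial-moments
NULL

check_st <- function(s, t) {
  if (!is.numeric(s) || length(s) != 1L || s <= 0 ||
      !is.numeric(t) || length(t) != 1L || t <= 0) {
    stop("'s' and 't' must be single positive numbers", call. = FALSE)
  }
}

incgamma_lower <- function(a, x) gamma(a) * stats::pgamma(x, a)
incgamma_upper <- function(a, x) gamma(a) * stats::pgamma(x, a, lower.tail = FALSE)

#' @rdname nefr-partial-moments
#' @export
nefr_incomplete_moment <- function(s, t, alpha, beta, lambda,
                                   method = c("quadrature", "series"),
                                   ctrl = series_control()) {
  check_nefr_params(alpha, beta, lambda)
  check_st(s, t)
  method <- match.arg(method)
  if (method == "quadrature") {
    if (pnefr(t, alpha, beta, lambda) == 0) return(0)
    integrand <- function(z) exp(s * log(z) + nefr_logpdf(z, alpha, beta, lambda))
    if (s < beta * lambda) {
      # complement route: both pieces are numerically robust (quantile-space
      # full moment; infinite-range tail integral with QAGI's transformation)
      full <- stats::integrate(function(p) qnefr(p, alpha, beta, lambda)^s,
                               0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
      full - stats::integrate(integrand, t, Inf, rel.tol = 1e-10,
                              subdivisions = 500L)$value
    } else {
      # s-th moment does not exist globally but every truncated moment does;
      # split at the median to separate the two difficult regions
      m <- min(t, qnefr(0.5, alpha, beta, lambda))
      lower <- stats::integrate(integrand, 0, m, rel.tol = 1e-10,
                                subdivisions = 500L)$value
      upper <- if (t > m) stats::integrate(integrand, m, t, rel.tol = 1e-10,
                                           subdivisions = 500L)$value else 0
      lower + upper
    }
  } else {
    if (s >= beta) {
      stop("series incomplete moment requires s < beta", call. = FALSE)
    }
    a <- 1 - s / beta
    nefr_series_sum(alpha, beta, lambda, function(k) {
      cc <- 2 * (k + 1) * alpha
      incgamma_upper(a, cc * t^(-beta)) / (beta * cc^a)
    }, ctrl)
  }
}

#' @rdname nefr-partial-moments
#' @export
nefr_conditional_moment <- function(s, t, alpha, beta, lambda,
                                    method = c("quadrature", "series"),
                                    ctrl = series_control()) {
  check_nefr_params(alpha, beta, lambda)
  check_st(s, t)
  method <- match.arg(method)
  if (s >= beta * lambda) {
    stop(sprintf("E(Z^s | Z > t) does not exist for s >= beta*lambda (= %g)",
                 beta * lambda), call. = FALSE)
  }
  St <- pnefr(t, alpha, beta, lambda, lower.tail = FALSE)
  if (method == "quadrature") {
    # z-space with an infinite upper limit: integrate()'s transformation
    # handles the algebraic tail z^{s - beta*lambda - 1} reliably
    zeta <- stats::integrate(function(z) {
      exp(s * log(z) + nefr_logpdf(z, alpha, beta, lambda))
    }, t, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  } else {
    if (s >= beta) {
      stop("series conditional moment requires s < beta", call. = FALSE)
    }
    a <- 1 - s / beta
    zeta <- nefr_series_sum(alpha, beta, lambda, function(k) {
      cc <- 2 * (k + 1) * alpha
      incgamma_lower(a, cc * t^(-beta)) / (beta * cc^a)
    }, ctrl)
  }
  zeta / St
}

#' @rdname nefr-partial-moments
#' @export
nefr_mrl <- function(t, alpha, beta, lambda,
                     method = c("quadrature", "series"),
                     ctrl = series_control()) {
  if (beta * lambda <= 1) {
    stop(sprintf("mean residual life undefined: needs beta*lambda > 1 (= %g)",
                 beta * lambda), call. = FALSE)
  }
  nefr_conditional_moment(1, t, alpha, beta, lambda, method, ctrl) - t
}

#' @rdname nefr-partial-moments
#' @export
nefr_mit <- function(t, alpha, beta, lambda,
                     method = c("quadrature", "series"),
                     ctrl = series_control()) {
  check_nefr_params(alpha, beta, lambda)
  check_st(1, t)
  Ft <- pnefr(t, alpha, beta, lambda)
  if (Ft == 0) {
    stop("'t' is below the support of any observed mass (F(t) = 0)", call. = FALSE)
  }
  t - nefr_incomplete_moment(1, t, alpha, beta, lambda, method, ctrl) / Ft
}

#' Bonferroni and Lorenz curves
#'
#' The Lorenz curve \eqn{L(p) = \mu^{-1} \int_0^{Q(p)} z f(z)\,dz} and the
#' Bonferroni curve \eqn{B(p) = L(p)/p}, standard inequality and
#' reliability summaries of the lower tail of a positive distribution.
#' Both require the mean to exist (\eqn{\beta\lambda > 1}).
#'
#' @param p probability in (0, 1) (vectorised).
#' @inheritParams nefr_moment
#' @return Numeric vector of curve values.
#' @examples
#' nefr_lorenz(0.5, 0.5, 3, 2)
#' nefr_bonferroni(0.5, 0.5, 3, 2)
#' @name nefr-inequality-curves
NULL

#' @rdname nefr-inequality-curves
#' @export
nefr_lorenz <- function(p, alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  if (beta * lambda <= 1) {
    stop(sprintf("Lorenz curve undefined: mean requires beta*lambda > 1 (= %g)",
                 beta * lambda), call. = FALSE)
  }
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p >= 1)) {
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  }
  mu <- nefr_moment(1, alpha, beta, lambda)$value
  vapply(p, function(pp) {
    stats::integrate(function(u) qnefr(u, alpha, beta, lambda),
                     0, pp, rel.tol = 1e-10, subdivisions = 500L)$value / mu
  }, numeric(1))
}

#' @rdname nefr-inequality-curves
#' @export
nefr_bonferroni <- function(p, alpha, beta, lambda) {
  nefr_lorenz(p, alpha, beta, lambda) / p
}

#' Quantile-based summary: quartiles, Bowley skewness, Moors kurtosis
#'
#' Returns the three quartiles together with the quantile-based
#' (moment-free) shape measures
#' \deqn{BSK = \frac{Q_3 - 2 Q_2 + Q_1}{Q_3 - Q_1}, \qquad
#'   MKUR = \frac{Q(7/8) - Q(5/8) + Q(3/8) - Q(1/8)}{Q(6/8) - Q(2/8)},}
#' i.e. Bowley's skewness and Moors' kurtosis.  These exist for every
#' parameter triple, unlike the ordinary moments.  `BSK` is invariant
#' under the scale-type parameter `alpha` (quantiles scale by
#' \eqn{(2\alpha)^{1/\beta}}).
#'
#' @inheritParams nefr-distribution
#' @return A named numeric vector with elements `Q1`, `Q2`, `Q3`, `BSK`
#'   and `MKUR`.
#' @examples
#' nefr_quantile_summary(0.4, 0.4, 0.9)
#' @export
nefr_quantile_summary <- function(alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  q <- qnefr(c(1, 2, 3, 5, 6, 7) / 8, alpha, beta, lambda)
  names(q) <- c("o1", "q1", "o3", "o5", "q3", "o7")
  Q1 <- q[["q1"]]
  Q2 <- qnefr(0.5, alpha, beta, lambda)
  Q3 <- q[["q3"]]
  c(Q1 = Q1, Q2 = Q2, Q3 = Q3,
    BSK = (Q3 - 2 * Q2 + Q1) / (Q3 - Q1),
    MKUR = (q[["o7"]] - q[["o5"]] + q[["o3"]] - q[["o1"]]) / (Q3 - Q1))
}

#' Index of dispersion
#'
#' Variance-to-mean ratio \eqn{\sigma^2 / \mu}.  Defined only when the
#' second moment exists (\eqn{\beta\lambda > 2}).
#'
#' @inheritParams nefr-distribution
#' @return A single numeric value.
#' @export
nefr_index_of_dispersion <- function(alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  if (beta * lambda <= 2) {
    stop(sprintf("index of dispersion undefined: needs beta*lambda > 2 (= %g)",
                 beta * lambda), call. = FALSE)
  }
  m1 <- nefr_moment(1, alpha, beta, lambda)$value
  m2 <- nefr_moment(2, alpha, beta, lambda)$value
  (m2 - m1^2) / m1
}

#' Density of an order statistic
#'
#' Density of the \eqn{m}-th order statistic of an i.i.d. sample of size
#' \eqn{n} from the NE-Fr distribution,
#' \deqn{f_{(m)}(z) = \frac{n!}{(m-1)!\,(n-m)!}\,
#'   f(z)\,F(z)^{m-1}\,[1 - F(z)]^{n-m}.}
#' `m = 1` and `m = n` give the sample minimum and maximum.
#'
#' @param x vector of positive quantiles.
#' @param m rank of the order statistic, an integer in `1:n`.
#' @param n sample size.
#' @inheritParams nefr-distribution
#' @return Numeric vector of density values.
#' @examples
#' nefr_order_stat_pdf(1, m = 1, n = 5, 0.5, 1, 2)
#' @export
nefr_order_stat_pdf <- function(x, m, n, alpha, beta, lambda, log = FALSE) {
  check_nefr_params(alpha, beta, lambda)
  check_positive_data(x)
  if (!is.numeric(m) || !is.numeric(n) || length(m) != 1L || length(n) != 1L ||
      m < 1 || n < 1 || m > n || m != round(m) || n != round(n)) {
    stop("'m' and 'n' must be integers with 1 <= m <= n", call. = FALSE)
  }
  lcf <- lgamma(n + 1) - lgamma(m) - lgamma(n - m + 1)
  lp <- lcf + nefr_logpdf(x, alpha, beta, lambda)
  # skip zero-exponent terms: 0 * log(0) must contribute 0, not NaN
  if (m > 1) lp <- lp + (m - 1) * log(-expm1(nefr_logsf(x, alpha, beta, lambda)))
  if (m < n) lp <- lp + (n - m) * nefr_logsf(x, alpha, beta, lambda)
  if (log) lp else exp(lp)
}
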