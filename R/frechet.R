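#' The Frechet (Inverse Weibull) Distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the Frechet distribution parameterised as
#' \deqn{G(z; \alpha, \beta) = e^{-\alpha z^{-\beta}}, \quad z > 0,}
#' with \eqn{\alpha > 0} a scale-type parameter and \eqn{\beta > 0} the shape.
#' This is the baseline of the NE-Fr distribution: `pnefr(z, a, b, lambda = 1)`
#' equals `pfrechet(z, 2 * a, b)`.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations to generate.
#' @param alpha positive scale-type parameter.
#' @param beta positive shape parameter.
#' @param log,log.p logical; return values on the log scale.
#' @param lower.tail logical; if `FALSE`, return the survival function.
#' @return Numeric vector of densities, probabilities, quantiles or draws.
#' @examples
#' pfrechet(1, 1, 1)         # exp(-1)
#' qfrechet(0.5, 1, 2)
#' @name frechet-distribution
NULL

check_frechet_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1L ||
      length(beta) != 1L || !is.finite(alpha) || !is.finite(beta) ||
      alpha <= 0 || beta <= 0) {
    stop("'alpha' and 'beta' must be single positive finite numbers", call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname frechet-distribution
#' @export
dfrechet <- function(x, alpha, beta, log = FALSE) {
  check_frechet_params(alpha, beta)
  check_positive_data(x)
  lp <- log(alpha) + log(beta) - (beta + 1) * log(x) -
    exp(log(alpha) - beta * log(x))
  if (log) lp else exp(lp)
}

#' @rdname frechet-distribution
#' @export
pfrechet <- function(q, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_frechet_params(alpha, beta)
  check_positive_data(q, "q")
  lG <- -exp(log(alpha) - beta * log(q))
  if (lower.tail) {
    if (log.p) lG else exp(lG)
  } else {
    if (log.p) log(-expm1(lG)) else -expm1(lG)
  }
}

#' @rdname frechet-distribution
#' @export
qfrechet <- function(p, alpha, beta) {
  check_frechet_params(alpha, beta)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0 | p >= 1)) {
    stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  }
  (-log(p) / alpha)^(-1 / beta)
}

#' @rdname frechet-distribution
#' @export
rfrechet <- function(n, alpha, beta) {
  check_frechet_params(alpha, beta)
  qfrechet(stats::runif(n), alpha, beta)
}

frechet_loglik <- function(z, alpha, beta) {
  sum(dfrechet(z, alpha, beta, log = TRUE))
}
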