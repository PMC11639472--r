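#' The entropy integral of order rho
#'
#' Computes \eqn{I_\rho = \int_0^\infty f(z)^\rho\,dz}, the common building
#' block of the Renyi, q (Tsallis), Havrda-Charvat and Arimoto entropies.
#'
#' The quadrature route integrates \eqn{f^\rho} directly; because the density
#' decays like \eqn{z^{-(\beta\lambda+1)}}, tail integrability requires
#' \eqn{\rho(\beta\lambda + 1) > 1}.  The series route sums
#' \deqn{I_\rho = \sum_{i,j} \Xi_{i,j}\,
#'   \frac{\Gamma(\rho + (\rho-1)/\beta)}{\beta\,[2\alpha(\rho+i+j)]^{\rho+(\rho-1)/\beta}},}
#' with \eqn{\Xi_{i,j} = (2\lambda^2\alpha\beta)^\rho (-1)^j \bar\lambda^i
#' \binom{\rho(\lambda+1)+i-1}{i} \binom{\rho(\lambda-1)}{j}}, and requires a
#' positive gamma argument, \eqn{\rho + (\rho-1)/\beta > 0}, equivalently
#' \eqn{\rho(\beta + 1) > 1}, besides \eqn{\lambda < 2} for the validity of
#' the binomial expansion.  Violated conditions raise an error naming the
#' condition.
#'
#' @param rho positive entropy order, different from 1.
#' @inheritParams nefr_moment
#' @return The value of \eqn{I_\rho} (a positive number).
#' @examples
#' nefr_frho(1.5, 0.6, 3, 0.5)
#' nefr_frho(1.5, 0.6, 3, 0.5, method = "series")
#' @export
nefr_frho <- function(rho, alpha, beta, lambda,
                      method = c("quadrature", "series"),
                      ctrl = series_control()) {
  check_nefr_params(alpha, beta, lambda)
  method <- match.arg(method)
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0 ||
      rho == 1) {
    stop("'rho' must be a single positive number different from 1", call. = FALSE)
  }
  if (method == "quadrature") {
    if (rho * (beta * lambda + 1) <= 1) {
      stop(sprintf(
        "integral of f^rho diverges: tail integrability needs rho*(beta*lambda + 1) > 1 (got %g)",
        rho * (beta * lambda + 1)), call. = FALSE)
    }
    med <- qnefr(0.5, alpha, beta, lambda)
    f_rho <- function(z) exp(rho * nefr_logpdf(z, alpha, beta, lambda))
    stats::integrate(f_rho, 0, med, rel.tol = 1e-10, subdivisions = 500L)$value +
      stats::integrate(f_rho, med, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  } else {
    expo <- rho + (rho - 1) / beta
    if (expo <= 0) {
      stop(sprintf(
        "series entropy integral diverges: needs rho + (rho-1)/beta > 0, i.e. rho*(beta+1) > 1 (got %g)",
        rho * (beta + 1)), call. = FALSE)
    }
    if (abs(1 - lambda) >= 1) {
      warning("series representation requires 0 < lambda < 2; ",
              "prefer method = \"quadrature\"", call. = FALSE)
    }
    lam_bar <- 1 - lambda
    g <- gamma(expo)
    pref <- (2 * lambda^2 * alpha * beta)^rho
    total <- 0
    small_rows <- 0L
    block <- 512L
    for (i in 0:ctrl$max_index) {
      ci <- exp(lgamma(rho * (lambda + 1) + i) - lgamma(rho * (lambda + 1)) -
                  lgamma(i + 1)) * lam_bar^i
      row <- 0
      j0 <- 0L
      repeat {
        j <- j0:min(j0 + block - 1L, ctrl$max_index)
        terms <- pref * ci * (-1)^j * choose(rho * (lambda - 1), j) *
          g / (beta * (2 * alpha * (rho + i + j))^expo)
        terms[!is.finite(terms)] <- 0
        row <- row + sum(terms)
        if (sum(abs(terms)) < ctrl$term_tol * max(abs(total + row), 1e-300)) break
        if (j[length(j)] >= ctrl$max_index) break
        j0 <- j0 + block
      }
      total <- total + row
      if (abs(row) < ctrl$term_tol * max(abs(total), 1e-300)) {
        small_rows <- small_rows + 1L
        if (small_rows >= 2L && i >= 1L) return(total)
      } else small_rows <- 0L
    }
    warning(sprintf("entropy series truncated at max_index = %d", ctrl$max_index),
            call. = FALSE)
    total
  }
}

#' Entropy measures of the NE-Fr distribution
#'
#' Four generalised entropies, all deterministic functions of the shared
#' integral \eqn{I_\rho} (see [nefr_frho()]):
#' \describe{
#'   \item{Renyi}{\eqn{\log(I_\rho) / (1 - \rho)}}
#'   \item{q (Tsallis)}{\eqn{(1 - I_\rho) / (\rho - 1)}}
#'   \item{Havrda-Charvat}{\eqn{(I_\rho^{1/\rho} - 1) / (2^{1-\rho} - 1)}}
#'   \item{Arimoto}{\eqn{\rho\,(I_\rho^{1/\rho} - 1) / (1 - \rho)}}
#' }
#' As \eqn{\rho \to 1} the Renyi entropy tends to the differential Shannon
#' entropy \eqn{-\int f \log f}.
#'
#' @param rho positive entropy order, different from 1.
#' @param measure which entropy to return; `"all"` returns the four values
#'   as a named vector.
#' @inheritParams nefr_moment
#' @return A numeric value, or a named numeric vector when
#'   `measure = "all"`.
#' @examples
#' nefr_entropy(1.5, 0.6, 3, 0.5, measure = "renyi")
#' nefr_entropy(1.5, 0.6, 3, 0.5, measure = "all")
#' @export
nefr_entropy <- function(rho, alpha, beta, lambda,
                         measure = c("renyi", "q", "havrda_charvat",
                                     "arimoto", "all"),
                         method = c("quadrature", "series"),
                         ctrl = series_control()) {
  measure <- match.arg(measure)
  I <- nefr_frho(rho, alpha, beta, lambda, method, ctrl)
  vals <- c(renyi = log(I) / (1 - rho),
            q = (1 - I) / (rho - 1),
            havrda_charvat = (I^(1 / rho) - 1) / (2^(1 - rho) - 1),
            arimoto = rho * (I^(1 / rho) - 1) / (1 - rho))
  if (measure == "all") vals else vals[[measure]]
}

#' Differential Shannon entropy
#'
#' Computes \eqn{-\int_0^\infty f(z) \log f(z)\,dz} by adaptive quadrature
#' in quantile space; the \eqn{\rho \to 1} limit of the Renyi entropy.
#'
#' @inheritParams nefr-distribution
#' @return A single numeric value.
#' @examples
#' nefr_shannon(0.6, 3, 0.5)
#' @export
nefr_shannon <- function(alpha, beta, lambda) {
  check_nefr_params(alpha, beta, lambda)
  -stats::integrate(function(p) {
    nefr_logpdf(qnefr(p, alpha, beta, lambda), alpha, beta, lambda)
  }, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value
}
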