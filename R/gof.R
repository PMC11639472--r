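#' Goodness-of-fit criteria for a fitted model
#'
#' Computes the eight model-adequacy criteria used to compare fitted
#' lifetime models on a sample:
#' \describe{
#'   \item{tau1}{\eqn{-2\,\ell(\hat\theta)} (twice the negative maximised
#'     log-likelihood).}
#'   \item{tau2}{Akaike information criterion, \eqn{\tau_1 + 2k}.}
#'   \item{tau3}{corrected AIC, \eqn{\tau_2 + 2k(k+1)/(n-k-1)}.}
#'   \item{tau4}{Bayesian information criterion, \eqn{\tau_1 + k\log n}.}
#'   \item{tau5}{Hannan-Quinn criterion, \eqn{\tau_1 + 2k\log\log n}.}
#'   \item{tau6}{Cramer-von Mises statistic
#'     \eqn{W^2 = 1/(12n) + \sum_i [F(z_{(i)}) - (2i-1)/(2n)]^2}.}
#'   \item{tau7}{asymptotic one-sample Kolmogorov-Smirnov p-value against
#'     the fitted cdf (no correction for estimated parameters).}
#'   \item{tau8}{Anderson-Darling statistic \eqn{A^2} (identical to the
#'     ADE objective evaluated at the fitted parameters).}
#' }
#' The criteria are likelihood-based, so the fit must be a maximum
#' likelihood fit; `k` is the number of fitted parameters (3 for NE-Fr,
#' 2 for Frechet).  When \eqn{n \le k + 1} the corrected AIC is undefined
#' and reported as `NA`.
#'
#' @param fit a [nefr_fit()] object fitted with `method = "mle"`.
#' @return An object of class `"nefr_gof"`: a list with the named criteria
#'   vector `tau`, `n` and `k`.
#' @examples
#' set.seed(1)
#' z <- rnefr(100, 0.5, 0.8, 0.3)
#' gof_criteria(nefr_fit(z, "mle", starts = 6))
#' @export
gof_criteria <- function(fit) {
  if (!inherits(fit, "nefr_fit")) {
    stop("'fit' must be a 'nefr_fit' object", call. = FALSE)
  }
  if (fit$method != "mle") {
    stop("the information criteria are likelihood-based: refit with method = \"mle\"",
         call. = FALSE)
  }
  z <- sort(fit$data)
  n <- fit$n
  k <- length(fit$par)
  Fhat <- fitted_cdf(fit)
  Fi <- Fhat(z)
  i <- seq_len(n)
  tau1 <- -2 * fit$loglik
  tau3 <- if (n > k + 1) tau1 + 2 * k + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  w2 <- 1 / (12 * n) + sum((Fi - (2 * i - 1) / (2 * n))^2)
  ks <- suppressWarnings(stats::ks.test(fit$data, Fhat, exact = FALSE))
  p <- fit$par
  a2 <- if (fit$distribution == "nefr") {
    nefr_ade_objective(fit$data, p[["alpha"]], p[["beta"]], p[["lambda"]])
  } else {
    lF <- pfrechet(z, p[["alpha"]], p[["beta"]], log.p = TRUE)
    lS <- pfrechet(z, p[["alpha"]], p[["beta"]], lower.tail = FALSE, log.p = TRUE)
    -n - sum((2 * i - 1) * (lF + rev(lS))) / n
  }
  tau <- c(tau1 = tau1,
           tau2 = tau1 + 2 * k,
           tau3 = tau3,
           tau4 = tau1 + k * log(n),
           tau5 = tau1 + 2 * k * log(log(n)),
           tau6 = w2,
           tau7 = unname(ks$p.value),
           tau8 = a2)
  structure(list(tau = tau, n = n, k = k,
                 distribution = fit$distribution, label = fit$label),
            class = "nefr_gof")
}

#' @export
print.nefr_gof <- function(x, digits = 4, ...) {
  cat(sprintf("Goodness of fit: %s on %s (n = %d, k = %d)\n",
              if (x$distribution == "nefr") "NE-Fr" else "Frechet",
              x$label, x$n, x$k))
  lbl <- c("-2logL", "AIC", "AICc", "BIC", "HQIC", "CvM W2", "KS p", "AD A2")
  out <- format(signif(x$tau, digits))
  names(out) <- paste0(names(x$tau), " (", lbl, ")")
  print(out, quote = FALSE)
  invisible(x)
}

#' Descriptive statistics of a positive sample
#'
#' Sample size, mean, median, standard deviation (denominator \eqn{n-1}),
#' moment skewness \eqn{m_3/m_2^{3/2}} and kurtosis \eqn{m_4/m_2^2}
#' (central moments with denominator \eqn{n}; kurtosis is not
#' excess-corrected), minimum and maximum.  For a constant sample the
#' shape measures are undefined and reported as `NA`.
#'
#' @param x numeric vector, at least two observations.
#' @return A named numeric vector with elements `n`, `mean`, `median`,
#'   `sd`, `skewness`, `kurtosis`, `min` and `max`.
#' @examples
#' descriptive_stats(nefr_data("pakistan_covid_cases"))
#' @export
descriptive_stats <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) {
    stop("'x' must be a numeric vector with at least 2 non-missing values",
         call. = FALSE)
  }
  n <- length(x)
  m <- mean(x)
  cm <- function(k) mean((x - m)^k)
  m2 <- cm(2)
  skew <- if (m2 > 0) cm(3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) cm(4) / m2^2 else NA_real_
  c(n = n, mean = m, median = stats::median(x), sd = stats::sd(x),
    skewness = skew, kurtosis = kurt, min = min(x), max = max(x))
}

#' Scaled total-time-on-test transform
#'
#' The empirical scaled TTT curve
#' \deqn{T(i/n) = \frac{\sum_{j \le i} z_{(j)} + (n-i)\,z_{(i)}}{\sum_j z_j},
#'   \quad i = 0, \dots, n,}
#' a standard diagnostic for the shape of the hazard rate: a concave curve
#' above the diagonal indicates an increasing hazard, a convex curve below
#' it a decreasing hazard, and an S shape an upside-down (unimodal) hazard.
#' Exponential data fall close to the diagonal.
#'
#' @param x numeric vector of positive durations, at least two observations.
#' @return A data frame with columns `p` (= i/n) and `ttt` (= T(i/n));
#'   `T(0) = 0`, `T(1) = 1`, nondecreasing.
#' @examples
#' ttt_curve(nefr_data("bladder_cancer"))
#' @export
ttt_curve <- function(x) {
  check_positive_data(x)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  z <- sort(x)
  n <- length(z)
  cum <- cumsum(z)
  tot <- cum[n]
  ti <- (cum + (n - seq_len(n)) * z) / tot
  data.frame(p = (0:n) / n, ttt = c(0, ti))
}
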