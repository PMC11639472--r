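#' @export
print.nefr_fit <- function(x, digits = 4, ...) {
  dist_name <- if (x$distribution == "nefr") "NE-Fr" else "Frechet"
  cat(sprintf("%s fit by %s (n = %d, sample: %s)\n", dist_name,
              toupper(x$method), x$n, x$label))
  est <- format(signif(x$par, digits))
  if (x$method == "mle" && !all(is.na(x$se))) {
    tab <- rbind(estimate = est, se = format(signif(x$se, digits)))
    print(tab, quote = FALSE)
  } else {
    print(x$par, digits = digits)
  }
  obj_name <- if (x$method == "mle") "log-likelihood" else
    sprintf("%s distance", toupper(x$method))
  cat(sprintf("%s: %.*f%s\n", obj_name, digits, x$objective,
              if (x$converged) "" else " (optimiser did not converge)"))
  invisible(x)
}

#' @export
summary.nefr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.nefr_fit")
}

#' @export
print.summary.nefr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("-2 log-likelihood at estimates: %.3f\n", -2 * f$loglik))
  if (f$distribution == "nefr") {
    ti <- f$par[["beta"]] * f$par[["lambda"]]
    cat(sprintf("tail index beta*lambda = %.3f (moments of order < %.3f exist)\n",
                ti, ti))
    rel <- f$se[["lambda"]] / f$par[["lambda"]]
    if (is.finite(rel) && rel > 1) {
      cat("note: SE(lambda) exceeds the estimate - the likelihood is nearly\n",
          "flat in the lambda direction; interpret lambda-hat with caution.\n",
          sep = "")
    }
  }
  invisible(x)
}

#' @export
coef.nefr_fit <- function(object, ...) object$par

#' @export
logLik.nefr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$par), nobs = object$n,
            class = "logLik")
}

#' @export
vcov.nefr_fit <- function(object, ...) {
  if (is.null(object$vcov)) {
    stop("no covariance matrix available (only maximum-likelihood fits with ",
         "invertible observed information have one)", call. = FALSE)
  }
  object$vcov
}

#' Simulate from a fitted NE-Fr model
#'
#' Draws `nsim` samples of the original sample size from the fitted
#' distribution by inversion.
#'
#' @param object a [nefr_fit()] object.
#' @param nsim number of replicate samples.
#' @param seed optional seed, applied via a temporary RNG state.
#' @param ... unused.
#' @return A data frame with one column per replicate (`sim_1`, ...).
#' @export
simulate.nefr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  }
  p <- object$par
  draws <- replicate(nsim, if (object$distribution == "nefr") {
    rnefr(object$n, p[["alpha"]], p[["beta"]], p[["lambda"]])
  } else {
    rfrechet(object$n, p[["alpha"]], p[["beta"]])
  }, simplify = FALSE)
  names(draws) <- paste0("sim_", seq_len(nsim))
  as.data.frame(draws)
}

fitted_cdf <- function(object) {
  p <- object$par
  if (object$distribution == "nefr") {
    function(q) pnefr(q, p[["alpha"]], p[["beta"]], p[["lambda"]])
  } else {
    function(q) pfrechet(q, p[["alpha"]], p[["beta"]])
  }
}

fitted_pdf <- function(object) {
  p <- object$par
  if (object$distribution == "nefr") {
    function(q) dnefr(q, p[["alpha"]], p[["beta"]], p[["lambda"]])
  } else {
    function(q) dfrechet(q, p[["alpha"]], p[["beta"]])
  }
}

#' Diagnostic plots for a fitted NE-Fr model
#'
#' Four base-graphics panels: histogram with fitted density, empirical
#' versus fitted cdf, probability-probability plot, and the scaled
#' total-time-on-test curve of the data.
#'
#' @param x a [nefr_fit()] object.
#' @param which subset of `1:4` selecting panels.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.nefr_fit <- function(x, which = 1:4, ...) {
  z <- sort(x$data)
  Fhat <- fitted_cdf(x)
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(2, ceiling(length(which) / 2)))
    on.exit(graphics::par(op))
  }
  if (1 %in% which) {
    graphics::hist(z, freq = FALSE, main = "Histogram and fitted density",
                   xlab = x$label, ...)
    zz <- seq(min(z), max(z), length.out = 400)
    graphics::lines(zz, fitted_pdf(x)(zz), col = 2, lwd = 2)
  }
  if (2 %in% which) {
    graphics::plot(stats::ecdf(z), main = "Empirical and fitted cdf",
                   xlab = x$label)
    zz <- seq(min(z), max(z), length.out = 400)
    graphics::lines(zz, Fhat(zz), col = 2, lwd = 2)
  }
  if (3 %in% which) {
    n <- length(z)
    graphics::plot((seq_len(n) - 0.5) / n, Fhat(z), xlab = "empirical probability",
                   ylab = "fitted probability", main = "P-P plot")
    graphics::abline(0, 1, col = 2)
  }
  if (4 %in% which) {
    ttt <- ttt_curve(x$data)
    graphics::plot(ttt$p, ttt$ttt, type = "l", xlab = "i/n",
                   ylab = "scaled TTT", main = "Total time on test")
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
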