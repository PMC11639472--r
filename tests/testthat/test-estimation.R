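# Likelihood, score, minimum-distance objectives and the fitting harness.

test_that("log-likelihood equals the sum of log densities", {
  z <- nefr_data("pakistan_covid_cases")
  for (p in list(c(1, 1, 1), c(8.826, 0.064, 663), c(0.5, 0.3, 2))) {
    expect_equal(nefr_loglik(z, p[1], p[2], p[3]),
                 sum(dnefr(z, p[1], p[2], p[3], log = TRUE)),
                 tolerance = 1e-10)
  }
  # single observation: frozen high-precision log-density
  expect_equal(nefr_loglik(1, 0.5, 1, 2), -1.0121658468218598,
               tolerance = 1e-12)
  # duplicating the data doubles the log-likelihood exactly
  expect_equal(nefr_loglik(c(z, z), 1, 1, 1), 2 * nefr_loglik(z, 1, 1, 1),
               tolerance = 1e-12)
  # overflow of z^-beta gives -Inf, never NaN
  expect_identical(nefr_loglik(c(0.1, 0.2), 50, 400, 0.5), -Inf)
  expect_false(is.nan(nefr_loglik(c(0.1, 0.2), 50, 400, 0.5)))
  expect_error(nefr_loglik(c(1, -1), 1, 1, 1), "positive")
})

test_that("analytic score matches numerical gradients of the log-likelihood", {
  set.seed(11)
  panels <- list(c(1, 1, 1), c(0.5, 0.8, 0.3), c(2, 0.5, 1.5), c(4, 0.2, 30))
  for (rep in 1:3) {
    z <- rnefr(50, 0.5, 0.8, 0.5 + rep / 2)
    for (p in panels) {
      an <- nefr_score(z, p[1], p[2], p[3])
      nu <- num_grad(function(th) nefr_loglik(z, th[1], th[2], th[3]), p)
      expect_equal(unname(an), nu, tolerance = 1e-5)
    }
  }
  # first-order optimality at a computed maximum-likelihood solution:
  # the log-parameter gradient (score * parameter) is small per observation
  z <- nefr_data("bladder_cancer")
  fit <- quiet_fit(z, "mle", label = "bladder")
  sc <- nefr_score(z, fit$par[["alpha"]], fit$par[["beta"]], fit$par[["lambda"]])
  expect_lt(max(abs(sc * fit$par)) / fit$n, 1e-3)
})

test_that("least-squares objectives follow their formulas", {
  # a sample sitting exactly on the plotting positions scores zero
  p <- c(0.5, 0.8, 1.3)
  n <- 9
  z <- qnefr((1:n) / (n + 1), p[1], p[2], p[3])
  expect_lt(nefr_lse_objective(z, p[1], p[2], p[3]), 1e-18)
  expect_lt(nefr_wlse_objective(z, p[1], p[2], p[3]), 1e-12)
  # weight symmetry w_i = w_{n-i+1}
  i <- 1:7; nn <- 7
  w <- (nn + 1)^2 * (nn + 2) / (i * (nn - i + 1))
  expect_equal(w, rev(w))
  # three-point brute force
  z3 <- c(2, 0.7, 1.4)
  Fi <- pnefr(sort(z3), 1, 1, 1)
  lse_hand <- sum((Fi - (1:3) / 4)^2)
  w3 <- 16 * 5 / ((1:3) * (3 - (1:3) + 1))
  wlse_hand <- sum(w3 * (Fi - (1:3) / 4)^2)
  expect_equal(nefr_lse_objective(z3, 1, 1, 1), lse_hand, tolerance = 1e-14)
  expect_equal(nefr_wlse_objective(z3, 1, 1, 1), wlse_hand, tolerance = 1e-14)
})

test_that("Anderson-Darling objective equals the classical statistic", {
  # one observation: A2 = -1 - log F - log(1 - F), minimised at F = 1/2
  # with value -1 + 2 log 2
  z_med <- qnefr(0.5, 1, 1, 1)
  expect_equal(nefr_ade_objective(z_med, 1, 1, 1), -1 + 2 * log(2),
               tolerance = 1e-10)
  expect_gt(nefr_ade_objective(qnefr(0.9, 1, 1, 1), 1, 1, 1), -1 + 2 * log(2))
  # textbook formulation on a seeded sample (algebraically different
  # arrangement of the same statistic)
  set.seed(3)
  z <- rnefr(50, 0.5, 0.8, 0.3)
  Fi <- sort(pnefr(z, 0.6, 0.7, 0.4))
  i <- 1:50
  a2_text <- -50 - mean((2 * i - 1) * log(Fi) + (2 * (50 - i) + 1) * log(1 - Fi))
  expect_equal(nefr_ade_objective(z, 0.6, 0.7, 0.4), a2_text, tolerance = 1e-10)
  # probability-integral-transform invariance: the statistic depends on the
  # data only through F(z); transporting the sample to another parameter
  # triple through the quantile map leaves it unchanged
  p2 <- c(2, 1.5, 0.8)
  z2 <- qnefr(pnefr(z, 0.6, 0.7, 0.4), p2[1], p2[2], p2[3])
  expect_equal(nefr_ade_objective(z2, p2[1], p2[2], p2[3]),
               nefr_ade_objective(z, 0.6, 0.7, 0.4), tolerance = 1e-8)
})

test_that("maximum likelihood recovers simulated parameters", {
  set.seed(1)
  z <- rnefr(5000, 0.5, 0.8, 0.3)
  fit <- quiet_fit(z, "mle", starts = 8)
  expect_true(fit$converged)
  se <- fit$se
  truth <- c(alpha = 0.5, beta = 0.8, lambda = 0.3)
  for (nm in names(truth)) {
    expect_lt(abs(fit$par[[nm]] - truth[[nm]]), 3 * se[[nm]])
  }
})

test_that("fits are deterministic and all four methods work", {
  set.seed(5)
  z <- rnefr(120, 0.5, 0.8, 0.3)
  f1 <- quiet_fit(z, "mle", starts = 6, seed = 2)
  f2 <- quiet_fit(z, "mle", starts = 6, seed = 2)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$objective, f2$objective)
  for (m in c("lse", "wlse", "ade")) {
    f <- quiet_fit(z, m, starts = 6)
    expect_true(f$converged)
    expect_true(all(f$par > 0))
    expect_true(all(is.na(f$se)))  # distance estimators report no SEs
    # the reported objective really is the minimised criterion
    obj_fun <- switch(m, lse = nefr_lse_objective, wlse = nefr_wlse_objective,
                      ade = nefr_ade_objective)
    expect_equal(f$objective,
                 obj_fun(z, f$par[["alpha"]], f$par[["beta"]], f$par[["lambda"]]),
                 tolerance = 1e-12)
  }
  # methods on the fit object
  expect_named(coef(f1), c("alpha", "beta", "lambda"))
  expect_equal(as.numeric(logLik(f1)), f1$loglik)
  expect_equal(dim(vcov(f1)), c(3L, 3L))
  expect_output(print(f1), "MLE")
  expect_output(print(summary(f1)), "tail index")
})

test_that("standard errors shrink like n^(-1/2) and flag flat directions", {
  # numerical Hessian is exact on a quadratic
  H_true <- matrix(c(2, 0.5, 0.5, 3), 2)
  f_quad <- function(x) -0.5 * drop(t(x) %*% H_true %*% x)
  H_num <- -nefr:::num_hessian(f_quad, c(0.3, -0.2))
  expect_equal(H_num, H_true, tolerance = 1e-6)

  ses <- sapply(c(500, 2000, 8000), function(n) {
    set.seed(n)
    z <- rnefr(n, 0.5, 0.8, 0.3)
    quiet_fit(z, "mle", starts = 4)$se[["beta"]]
  })
  # each 4-fold n increase should halve the SE, within Monte-Carlo slack
  expect_gt(ses[1] / ses[2], 1.4)
  expect_lt(ses[1] / ses[2], 2.9)
  expect_gt(ses[2] / ses[3], 1.4)
  expect_lt(ses[2] / ses[3], 2.9)

  # real data with a nearly flat lambda ridge: SE(lambda) exceeds the estimate
  fit <- quiet_fit(nefr_data("bladder_cancer"), "mle", label = "bladder")
  expect_gt(fit$se[["lambda"]], fit$par[["lambda"]])
})

test_that("the Frechet baseline can be fitted with the same harness", {
  set.seed(8)
  z <- rfrechet(400, 2, 1.5)
  f <- quiet_fit(z, "mle", distribution = "frechet")
  expect_named(coef(f), c("alpha", "beta"))
  expect_lt(abs(f$par[["beta"]] - 1.5), 3 * f$se[["beta"]])
})
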