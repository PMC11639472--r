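# Derived quantities: moments, incomplete/conditional moments, MRL/MIT,
# inequality curves, quantile summaries, order statistics.

test_that("raw moments: series and quadrature agree on the validity region", {
  # joint validity region: r < beta, r < beta*lambda, lambda < 2.  The
  # truncation error of the inner binomial series decays like
  # N^-(lambda - r/beta), so five-digit agreement is asserted where that
  # exponent is large enough to be reachable
  cases <- list(c(0.5, 3, 1), c(0.6, 2.5, 1.5), c(0.5, 3, 1.8))
  for (p in cases) {
    mq <- nefr_moment(1, p[1], p[2], p[3], method = "quadrature")
    ms <- quiet(nefr_moment(1, p[1], p[2], p[3], method = "series",
                            ctrl = big_ctrl))
    expect_true(mq$exists)
    expect_equal(ms$value, mq$value, tolerance = 1e-5)
  }
  # for lambda < 1 convergence is only polynomial of low order: assert the
  # truncated series is converging toward the quadrature value
  mq <- nefr_moment(1, 0.5, 3, 0.5)$value
  e_small <- abs(quiet(nefr_moment(1, 0.5, 3, 0.5, method = "series",
                                   ctrl = series_control(max_index = 2e3))$value) - mq)
  e_big <- abs(quiet(nefr_moment(1, 0.5, 3, 0.5, method = "series",
                                 ctrl = big_ctrl)$value) - mq)
  expect_lt(e_big, e_small)
  # lambda = 1: classical Frechet closed form (2 alpha)^(r/beta) Gamma(1 - r/beta)
  for (r in c(1, 2)) {
    closed <- (2 * 0.5)^(r / 3) * gamma(1 - r / 3)
    expect_equal(nefr_moment(r, 0.5, 3, 1)$value, closed, tolerance = 1e-8)
    expect_equal(quiet(nefr_moment(r, 0.5, 3, 1, method = "series")$value),
                 closed, tolerance = 1e-8)
  }
})

test_that("moment existence is governed by the tail index beta*lambda", {
  # beta*lambda = 0.1 < 1: first moment does not exist
  m <- quiet(nefr_moment(1, 0.6, 0.2, 0.5))
  expect_false(m$exists)
  expect_warning(nefr_moment(1, 0.6, 0.2, 0.5), "does not exist")
  # series route: Gamma(1 - r/beta) pole for r >= beta
  expect_error(nefr_moment(1, 0.6, 0.2, 0.5, method = "series"), "pole")
  # quadrature works right up to the existence boundary region
  expect_true(nefr_moment(1, 0.5, 3, 2)$exists)
  expect_equal(nefr_moment(1, 0.5, 3, 2)$value, 0.8765753657595759,
               tolerance = 1e-8)  # frozen 40-digit quadrature reference
})

test_that("the Laplace-type mgf behaves as a Laplace transform", {
  expect_equal(nefr_mgf(0, 0.5, 1, 2), 1)
  vals <- nefr_mgf(c(0, 0.5, 1, 2, 5), 0.5, 1, 2)
  expect_true(all(diff(vals) < 0))
  # independent z-space quadrature oracle
  oracle <- integrate(function(z) exp(-z) * dnefr(z, 0.5, 1, 2),
                      0, Inf, rel.tol = 1e-12)$value
  expect_equal(nefr_mgf(1, 0.5, 1, 2), oracle, tolerance = 1e-6)
  expect_error(nefr_mgf(-1, 0.5, 1, 2), "nonnegative")
})

test_that("incomplete moments: series, quadrature and limits agree", {
  p <- c(0.5, 3, 1.5)
  iq <- nefr_incomplete_moment(1, 1, p[1], p[2], p[3])
  is <- quiet(nefr_incomplete_moment(1, 1, p[1], p[2], p[3],
                                     method = "series", ctrl = big_ctrl))
  expect_equal(is, iq, tolerance = 1e-5)
  # t -> infinity recovers the raw moment; t -> 0 gives 0
  expect_equal(nefr_incomplete_moment(1, 1e6, p[1], p[2], p[3]),
               nefr_moment(1, p[1], p[2], p[3])$value, tolerance = 1e-6)
  expect_lt(nefr_incomplete_moment(1, 1e-4, p[1], p[2], p[3]), 1e-10)
})

test_that("conditional moments, MRL and MIT match their oracles", {
  p <- c(0.5, 3, 1.5)
  # MRL survival-integral identity: mrl(t) = int_t^Inf S(u) du / S(t)
  for (t in c(0.5, 1, 2)) {
    oracle <- integrate(function(z) pnefr(z, p[1], p[2], p[3], lower.tail = FALSE),
                        t, Inf, rel.tol = 1e-12)$value /
      pnefr(t, p[1], p[2], p[3], lower.tail = FALSE)
    expect_equal(nefr_mrl(t, p[1], p[2], p[3]), oracle, tolerance = 1e-5)
  }
  expect_equal(quiet(nefr_mrl(1, p[1], p[2], p[3], method = "series",
                              ctrl = big_ctrl)),
               nefr_mrl(1, p[1], p[2], p[3]), tolerance = 1e-5)
  # mrl(t -> 0) + t -> mean
  mu <- nefr_moment(1, p[1], p[2], p[3])$value
  expect_equal(nefr_mrl(1e-3, p[1], p[2], p[3]) + 1e-3, mu, tolerance = 1e-6)
  # MIT is within (0, t)
  for (t in c(0.5, 1, 3)) {
    mit <- nefr_mit(t, p[1], p[2], p[3])
    expect_gt(mit, 0)
    expect_lt(mit, t)
  }
  # existence guard: beta*lambda <= 1 has no mean
  expect_error(nefr_mrl(1, 0.6, 0.2, 0.5), "beta\\*lambda")
  expect_error(nefr_conditional_moment(1, 1, 0.6, 0.2, 0.5), "exist")
})

test_that("Bonferroni and Lorenz curves are valid inequality curves", {
  p <- c(0.5, 3, 2)
  u <- seq(0.05, 0.95, by = 0.05)
  L <- nefr_lorenz(u, p[1], p[2], p[3])
  expect_true(all(L <= u + 1e-12))
  expect_true(all(L >= 0))
  expect_true(all(diff(L) > 0))
  expect_true(all(diff(diff(L)) > -1e-10))  # convexity
  expect_gt(nefr_lorenz(0.9999, p[1], p[2], p[3]), 0.99)
  expect_equal(nefr_bonferroni(0.5, p[1], p[2], p[3]),
               nefr_lorenz(0.5, p[1], p[2], p[3]) / 0.5, tolerance = 1e-12)
  # independent z-space oracle for L(1/2)
  mu <- integrate(function(z) z * dnefr(z, p[1], p[2], p[3]),
                  0, Inf, rel.tol = 1e-12)$value
  q50 <- qnefr(0.5, p[1], p[2], p[3])
  oracle <- integrate(function(z) z * dnefr(z, p[1], p[2], p[3]),
                      0, q50, rel.tol = 1e-12)$value / mu
  expect_equal(nefr_lorenz(0.5, p[1], p[2], p[3]), oracle, tolerance = 1e-5)
  expect_error(nefr_lorenz(0.5, 0.6, 0.2, 0.5), "undefined")
})

test_that("quantile summaries reproduce the published table rows", {
  # three full rows of the quantile-summary table, printed to 5 d.p.
  rows <- list(
    list(p = c(0.4, 0.4, 0.9),
         v = c(0.34770, 2.29081, 25.35068, 0.84457, 8.10270)),
    list(p = c(0.4, 0.8, 0.9),
         v = c(0.58966, 1.51354, 5.03495, 0.58433, 2.80456)),
    list(p = c(0.6, 1.2, 2.1),
         v = c(0.50439, 0.69667, 1.01599, 0.24831, 1.46775)))
  for (row in rows) {
    qs <- nefr_quantile_summary(row$p[1], row$p[2], row$p[3])
    expect_equal(unname(qs), row$v, tolerance = 2e-5)
    expect_true(qs[["Q1"]] < qs[["Q2"]] && qs[["Q2"]] < qs[["Q3"]])
    expect_true(abs(qs[["BSK"]]) < 1)
  }
  # Bowley skewness is invariant to the scale-type parameter alpha
  expect_equal(nefr_quantile_summary(0.4, 0.4, 0.9)[["BSK"]],
               nefr_quantile_summary(4.0, 0.4, 0.9)[["BSK"]],
               tolerance = 1e-12)
})

test_that("order-statistic densities specialise and normalise correctly", {
  z <- c(0.3, 1, 2.5)
  expect_equal(nefr_order_stat_pdf(z, 1, 1, 0.5, 1, 2),
               dnefr(z, 0.5, 1, 2), tolerance = 1e-12)
  total <- integrate(function(x) nefr_order_stat_pdf(x, 1, 5, 0.5, 1, 2),
                     0, Inf, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-8)
  # sample maximum: direct evaluation of the printed specialised form
  direct_max <- function(x, n, a, b, l) {
    lb <- 1 - l
    u <- exp(-2 * a * x^(-b))
    n * 2 * l^2 * a * b * x^(-b - 1) * u * (1 - u)^(l - 1) /
      (1 - lb * u)^(l + 1) *
      (1 - ((1 - u) / (1 - lb * u))^l)^(n - 1)
  }
  expect_equal(nefr_order_stat_pdf(z, 5, 5, 0.5, 1, 2),
               direct_max(z, 5, 0.5, 1, 2), tolerance = 1e-10)
  expect_error(nefr_order_stat_pdf(1, 6, 5, 0.5, 1, 2), "1 <= m <= n")
})

test_that("index of dispersion follows its definition", {
  m1 <- nefr_moment(1, 0.5, 3, 2)$value
  m2 <- nefr_moment(2, 0.5, 3, 2)$value
  expect_equal(nefr_index_of_dispersion(0.5, 3, 2), (m2 - m1^2) / m1,
               tolerance = 1e-10)
  expect_error(nefr_index_of_dispersion(0.5, 1, 1), "undefined")
})
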