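# shared helpers for the test suite

# a parameter panel spanning lambda < 1, = 1, > 1
param_panel <- list(
  c(alpha = 0.5, beta = 1.0, lambda = 0.5),
  c(alpha = 0.4, beta = 0.4, lambda = 0.9),
  c(alpha = 0.5, beta = 1.0, lambda = 1.0),
  c(alpha = 0.5, beta = 3.0, lambda = 2.0),
  c(alpha = 2.0, beta = 0.8, lambda = 5.0)
)

# generous truncation for series/quadrature agreement checks (the inner
# binomial series decays only polynomially for fractional lambda)
big_ctrl <- series_control(max_index = 2e5)

quiet_fit <- function(...) suppressWarnings(nefr_fit(...))

quiet <- function(expr) suppressWarnings(expr)

# central finite-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-6 * pmax(abs(x), 1)) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h[k]
    (f(x + e) - f(x - e)) / (2 * h[k])
  }, numeric(1))
}
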