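# Brute-force trapezoid oracle for marginal likelihoods: a fixed uniform
# grid, no adaptivity, independent of the quadrature path under test.
oracle_marginal <- function(summary, density_fn, lo = -1, hi = 1,
                            points = 1e6) {
  eps <- (hi - lo) * 1e-9
  rho <- seq(lo + eps, hi - eps, length.out = points)
  y <- r_density(summary$r, rho, summary$n) * density_fn(rho)
  sum((y[-1] + y[-length(y)]) / 2 * diff(rho))
}

oracle_bf01 <- function(summary, points = 1e6) {
  m <- oracle_marginal(summary, function(rho) rep(0.5, length(rho)),
                       points = points)
  r_density(summary$r, 0, summary$n) / m
}

# published two-decimal summaries used across the tests
fixture_summaries <- function() {
  tab <- donnellan_summaries()
  lapply(seq_len(nrow(tab)), function(i) {
    study_summary(tab$n[i], tab$r[i], tab$study[i])
  })
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
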