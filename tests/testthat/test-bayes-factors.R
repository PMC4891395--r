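test_that("marginal likelihood agrees with the brute-force trapezoid oracle", {
  s <- study_summary(20, 0.3)
  m <- marginal_likelihood(s, uniform_prior())
  expect_lt(m$rel_error, 1e-8)
  expect_rel(m$value, oracle_marginal(s, function(rho) rep(0.5, length(rho))),
             1e-7)
  # r = 0 with a symmetric prior: two-sided marginal equals the one-sided one
  s0 <- study_summary(100, 0)
  expect_rel(marginal_likelihood(s0, uniform_prior())$value,
             marginal_likelihood(s0, one_sided_prior())$value, 1e-9)
  # narrow interval prior converges to the likelihood at rho = 0
  expect_rel(marginal_likelihood(s, interval_prior(1e-5))$value,
             r_density(0.3, 0, 20), 1e-6)
})

test_that("default BF01 matches the oracle and published values within the ladder", {
  # frozen expected values from the 1e6-point trapezoid oracle
  expect_rel(bf01(study_summary(480, -0.01))$bf01,
             oracle_bf01(study_summary(480, -0.01)), 1e-6)
  # published values recomputed from printed 2-decimal (n, r): +-5%
  expect_rel(bf01(study_summary(480, -0.01))$bf01, 17.36, 0.05)
  expect_rel(bf01(study_summary(311, 0.02))$bf01, 13.21, 0.05)
  # symmetric prior and likelihood: BF is even in r
  expect_rel(bf01(study_summary(235, -0.06))$bf01,
             bf01(study_summary(235, 0.06))$bf01, 1e-8)
})

test_that("every computed BF satisfies reciprocity and records small numeric error", {
  for (s in fixture_summaries()) {
    b <- bf01(s)
    expect_equal(b$bf01 * b$bf10, 1, tolerance = 1e-12)
    expect_equal(b$bf01, exp(b$log_bf01), tolerance = 1e-15)
    expect_lt(b$numeric_error, 1e-6)
  }
})

test_that("one-sided BF obeys the two-fold bound and direction asymmetry", {
  for (s in fixture_summaries()) {
    b01 <- bf01(s)$bf01
    b0p <- bf0plus(s)$bf01
    # a sign restriction can favor the alternative at most two-fold
    expect_gte(b0p, b01 / 2 * (1 - 1e-9))
    if (s$r < 0) expect_gt(b0p, b01)
    if (s$r > 0) expect_lt(b0p, b01)
  }
  # perfectly symmetric posterior: one- and two-sided tests coincide
  s0 <- study_summary(100, 0)
  expect_rel(bf0plus(s0)$bf01, bf01(s0)$bf01, 1e-8)
  # published one-sided value for study 1 (within the +-5% ladder)
  expect_rel(bf0plus(study_summary(235, -0.06))$bf01, 22.59, 0.05)
})

test_that("sensitivity curve hits the default at gamma = 1 and 1 at gamma -> 0", {
  s <- study_summary(1153, -0.03)
  curve <- bf_sensitivity(s, gamma = c(1e-5, 2e-5, 0.25, 0.5, 1))
  expect_rel(curve$bf01[curve$gamma == 1], bf01(s)$bf01, 1e-9)
  # linear extrapolation of log BF to gamma = 0 vanishes
  extrap <- curve$log_bf01[1] -
    (curve$log_bf01[2] - curve$log_bf01[1])  # 2*lb(1e-5) - lb(2e-5)
  expect_lt(abs(extrap), 1e-3)
  # pooled studies 1-4: support for the null at every width tested
  grid <- bf_sensitivity(s, gamma = seq(0.02, 1, length.out = 50))
  expect_true(all(grid$log_bf01 > 0))
  expect_error(bf_sensitivity(s, gamma = c(0.5, 0.2)),
               class = "corbf_domain_error")
  expect_error(bf_sensitivity(s, gamma = c(0.5, 1.2)),
               class = "corbf_domain_error")
})

test_that("interval-null BF behaves at both limits of the half-width", {
  s <- study_summary(480, -0.01)
  # c -> 0: the interval null degenerates to the point null
  expect_rel(bf_interval_null(s, 1e-5)$bf01, bf01(s)$bf01, 1e-4)
  # c = 0.01: virtually identical to the point-null analysis
  expect_lt(abs(bf_interval_null(s, 0.01)$log_bf01 - bf01(s)$log_bf01), 0.05)
  # c -> 1: null and alternative coincide
  expect_lt(abs(bf_interval_null(s, 0.9999)$log_bf01), 1e-3)
})

test_that("replication BF matches the oracle, uniform base, and warns when extreme", {
  orig <- study_summary(41, 0.37)
  rep3 <- study_summary(210, 0.13)
  b <- bf_replication(orig, rep3)
  # oracle: trapezoid integration of likelihood times normalized origin posterior
  m0 <- oracle_marginal(orig, function(rho) rep(0.5, length(rho)))
  m <- oracle_marginal(rep3, function(rho) {
    r_density(orig$r, rho, orig$n) * 0.5 / m0
  })
  expect_rel(b$bf01, r_density(rep3$r, 0, rep3$n) / m, 1e-6)

  # self-replication: evidence favors Hr over H0
  orig57 <- study_summary(51, 0.57)
  expect_lt(bf_replication(orig57, orig57)$bf01, 1)

  expect_warning(bf_replication(orig57, study_summary(235, -0.06)),
                 class = "corbf_extreme_bf_warning")
})

test_that("sequential updating obeys the multiplication rule", {
  s1 <- study_summary(235, -0.06)
  s2 <- study_summary(480, -0.01)
  sq <- bf_sequential(s1, s2)
  expect_rel(sq$bf_joint$bf01,
             sq$bf_first$bf01 * sq$bf_second_given_first$bf01, 1e-6)
  # naive product of individually computed BFs overstates the joint evidence
  naive <- bf01(s1)$bf01 * bf01(s2)$bf01
  expect_gt(abs(log(naive)), abs(sq$bf_joint$log_bf01))
  expect_gt(naive, sq$bf_joint$bf01)  # both favor H0 here

  # on study pairs simulated under a shared null, the naive product again
  # overstates the evidence for H0 relative to the coherent joint analysis
  for (seed in c(11, 12, 13)) {
    g1 <- pearson_summary(simulate_bivariate(150, 0, seed = seed)[[1]])
    g2 <- pearson_summary(simulate_bivariate(180, 0, seed = seed + 50)[[1]])
    sq2 <- bf_sequential(g1, g2)
    naive2 <- bf01(g1)$bf01 * bf01(g2)$bf01
    expect_gt(naive2, sq2$bf_joint$bf01)
  }
  # under a shared true effect the update sharpens the prediction of the
  # second study, so the joint evidence against H0 exceeds the naive product
  e1 <- pearson_summary(simulate_bivariate(100, 0.35, seed = 21)[[1]])
  e2 <- pearson_summary(simulate_bivariate(140, 0.35, seed = 22)[[1]])
  sq3 <- bf_sequential(e1, e2)
  expect_lt(sq3$bf_joint$bf01, 1)
  expect_lt(sq3$bf_joint$bf01, bf01(e1)$bf01 * bf01(e2)$bf01)
})

test_that("prior odds update multiplicatively", {
  expect_equal(update_odds(1 / 9, 9), 1)
  expect_equal(update_odds(99, 1), 99)
  b <- bf01(study_summary(480, -0.01))
  expect_equal(update_odds(2, b), 2 * b$bf01)
  expect_error(update_odds(-1, 2), class = "corbf_domain_error")
  expect_error(update_odds(1, 0), class = "corbf_domain_error")
})
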