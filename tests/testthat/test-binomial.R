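test_that("decision probabilities match the worked n = 30 two-outcome rule", {
  d <- three_outcome_design(30, 17, 17)
  p0 <- decision_probs(d, 0.5)
  p1 <- decision_probs(d, 0.7)
  expect_equal(round(p0$go, 2), 0.18)     # type I error of the x = 17 rule
  expect_equal(round(p1$stop, 2), 0.08)   # type II error
  expect_equal(p0$pause, 0)               # no amber zone when x0 = x1
})

test_that("decision probabilities agree with direct pmf summation and sum to one", {
  cases <- list(c(15, 9, 9, 0.7), c(20, 8, 13, 0.45), c(7, -1, 7, 0.3),
                c(12, 3, 9, 0.999), c(25, 10, 10, 0))
  for (cs in cases) {
    d <- three_outcome_design(cs[1], cs[2], cs[3])
    p <- decision_probs(d, cs[4])
    expect_lt(abs(p$stop - pmf_region(cs[1], 0, cs[2], cs[4])), 1e-12)
    expect_lt(abs(p$pause - pmf_region(cs[1], cs[2] + 1, cs[3], cs[4])), 1e-12)
    expect_lt(abs(p$go - pmf_region(cs[1], cs[3] + 1, cs[1], cs[4])), 1e-12)
    expect_equal(p$stop + p$pause + p$go, 1)
  }
  # empty go region, full-support stop region
  p <- decision_probs(three_outcome_design(10, 10, 10), 0.42)
  expect_equal(c(p$stop, p$pause, p$go), c(1, 0, 0))
})

test_that("go probability is monotone non-decreasing (and stop non-increasing) in rho", {
  d <- three_outcome_design(23, 8, 14)
  p <- decision_probs(d, seq(0, 1, by = 0.02))
  expect_true(all(diff(p$go) >= -1e-12))
  expect_true(all(diff(p$stop) <= 1e-12))
})

test_that("classic operating characteristics match exhaustive enumeration at n = 10", {
  prob <- pilot_problem(0.4, 0.6)   # rho_m = 0.5
  oc <- oc_classic(three_outcome_design(10, 3, 6), prob)
  expect_equal(oc$alpha_a, pmf_region(10, 7, 10, 0.4), tolerance = 1e-12)
  expect_equal(oc$beta_a, pmf_region(10, 0, 3, 0.6), tolerance = 1e-12)
  expect_equal(oc$lambda, pmf_region(10, 4, 6, 0.4), tolerance = 1e-12)
  expect_equal(oc$delta, pmf_region(10, 4, 6, 0.6), tolerance = 1e-12)
  expect_equal(oc$alpha_b, pmf_region(10, 4, 10, 0.4), tolerance = 1e-12)
  expect_equal(oc$beta_b, pmf_region(10, 0, 6, 0.6), tolerance = 1e-12)
  expect_equal(oc$gamma_L, pmf_region(10, 0, 3, 0.5), tolerance = 1e-12)
  expect_equal(oc$gamma_U, pmf_region(10, 7, 10, 0.5), tolerance = 1e-12)
  expect_equal(oc$gamma, oc$gamma_L + oc$gamma_U)
})

test_that("a two-outcome design has an empty pause region in the classic OCs", {
  oc <- oc_classic(three_outcome_design(30, 17, 17), adherence_problem())
  expect_equal(oc$lambda, 0)
  expect_equal(oc$delta, 0)
  expect_equal(oc$gamma, 1)
})

test_that("reformulated rates reproduce the worked n = 30 three-outcome numbers", {
  oc <- oc_reformulated(three_outcome_design(30, 15, 20), adherence_problem())
  expect_equal(round(oc$alpha, 2), 0.22)
  expect_equal(round(oc$beta, 2), 0.21)
  expect_equal(round(oc$gamma, 2), 0.35)
})

test_that("with eta = 0 the reformulated rates reduce to the immediate-decision errors", {
  p <- adherence_problem(eta0 = 0, eta1 = 0)
  oc <- oc_reformulated(three_outcome_design(30, 12, 19), p)
  expect_equal(oc$alpha, oc$alpha_a)
  expect_equal(oc$beta, oc$beta_a)
})

test_that("adjustment-aware rates match direct pmf evaluation at the shifted parameters", {
  p <- adherence_problem(eta0 = 0.5, tau_min = 0.05, tau_max = 0.10)
  oc <- oc_reformulated(three_outcome_design(20, 9, 13), p)
  oracle <- oracle_error_rates(20, 9, 13, 0.5, 0.7, 0.5, 0.05, 0.10)
  expect_equal(oc$alpha, oracle[["alpha"]], tolerance = 1e-12)
  expect_equal(oc$beta, oracle[["beta"]], tolerance = 1e-12)
})

test_that("no-adjustment identities alpha = alpha_a + eta0*lambda and beta = beta_a + eta1*delta hold to 1e-12", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:60, 1)
    x1 <- sample(0:n, 1)
    x0 <- sample(-1:x1, 1)
    eta0 <- runif(1); eta1 <- runif(1)
    p <- pilot_problem(runif(1, 0.2, 0.5), runif(1, 0.55, 0.9),
                       eta0 = eta0, eta1 = eta1)
    oc <- oc_reformulated(three_outcome_design(n, x0, x1), p)
    expect_lt(abs(oc$alpha - (oc$alpha_a + eta0 * oc$lambda)), 1e-12)
    expect_lt(abs(oc$beta - (oc$beta_a + eta1 * oc$delta)), 1e-12)
    # pause-route error never exceeds the overall rate it feeds into
    expect_lte(eta0 * oc$lambda, oc$alpha + 1e-15)
    expect_lte(eta1 * oc$delta, oc$beta + 1e-15)
  }
})

test_that("requesting adjustment-aware rates with unequal etas is an error", {
  p <- adherence_problem()
  p$tau_min <- p$tau_max <- 0.05; p$eta1 <- 0.3   # bypass constructor on purpose
  expect_error(oc_reformulated(three_outcome_design(20, 9, 13), p), "eta0 == eta1")
})
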