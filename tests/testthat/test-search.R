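test_that("two-outcome search reproduces the exact single-stage benchmark n = 53", {
  d <- find_two_outcome(adherence_problem())
  expect_equal(d$n, 53L)
  # the returned threshold satisfies both constraints
  expect_lte(decision_probs(d, 0.5)$go, 0.05)
  expect_lte(decision_probs(d, 0.7)$stop, 0.1)
})

test_that("two-outcome search agrees with brute force and handles vacuous constraints", {
  # independent brute-force oracle over all (n, x) for beta* = 0.2
  brute <- NULL
  for (n in 1:100) {
    x <- -1:n
    ok <- pbinom(x, n, 0.5, lower.tail = FALSE) <= 0.05 & pbinom(x, n, 0.7) <= 0.2
    if (any(ok)) { brute <- n; break }
  }
  expect_equal(find_two_outcome(adherence_problem(beta_star = 0.2))$n, brute)
  expect_equal(find_two_outcome(pilot_problem(0.5, 0.7, alpha_star = 1, beta_star = 1),
                                search_settings(n_min = 1))$n, 1L)
})

test_that("infeasible searches raise a classed error carrying the best candidate", {
  err <- expect_error(
    find_two_outcome(pilot_problem(0.5, 0.55, alpha_star = 0.01, beta_star = 0.01),
                     search_settings(n_max = 30)),
    class = "stopgo_infeasible")
  expect_false(is.null(err$best))
  expect_gt(err$best$alpha + err$best$beta, 0.02)
  expect_error(
    brute_force_min_n(adherence_problem(alpha_star = 1e-4, beta_star = 1e-4),
                      search_settings(n_max = 20)),
    class = "stopgo_infeasible")
})

test_that("x0_from_alpha returns the smallest stop threshold keeping alpha within its bound", {
  p <- adherence_problem(eta0 = 0.5, eta1 = 0.5)
  # linear-scan oracle over x0 at a loose alpha constraint
  p25 <- adherence_problem(alpha_star = 0.25)
  x1 <- 20; n <- 30
  scan <- sapply(-1:x1, function(x0)
    oracle_error_rates(n, x0, x1, 0.5, 0.7, 0.5)[["alpha"]])
  oracle_x0 <- (-1:x1)[which(scan <= 0.25)[1]]
  expect_equal(x0_from_alpha(n, x1, p25), oracle_x0)
  # with eta = 0 there is no pause route to a wrong go, so the sentinel is returned
  p0 <- adherence_problem(eta0 = 0, eta1 = 0)
  x1min <- qbinom(0.95, 52, 0.5)
  expect_equal(x0_from_alpha(52, x1min, p0), -1L)
  # at the reformulated optimum the stop threshold sits just below x1
  x1 <- which(pbinom(0:52, 52, 0.5, lower.tail = FALSE) <= 0.05)[1] - 1
  x0 <- x0_from_alpha(52, x1, p)
  expect_true(x0 <= x1 && x1 - x0 <= 3)
  # precondition: direct-go error must already satisfy alpha*
  expect_error(x0_from_alpha(30, 5, p), class = "stopgo_infeasible")
})

test_that("three-outcome search with guessing post-pause decisions gives n = 52", {
  res <- find_three_outcome(adherence_problem())
  expect_equal(res$design$n, 52L)
  expect_lte(res$oc$alpha, 0.05 + 1e-12)
  expect_lte(res$oc$beta, 0.1 + 1e-12)
})

test_that("vacuous constraints are satisfied at the search floor", {
  res <- find_three_outcome(pilot_problem(0.5, 0.7, alpha_star = 1, beta_star = 1),
                            search_settings(n_min = 1))
  expect_equal(res$design$n, 1L)
})

test_that("Sargent-original search reproduces n = 42 and reduces to two-outcome when no pause is allowed", {
  p <- adherence_problem()
  res <- find_sargent_original(p, 0.05, 0.1, 0.1, 0.1)
  expect_equal(res$design$n, 42L)
  expect_lte(res$oc$alpha_a, 0.05 + 1e-12)
  expect_lte(res$oc$beta_a, 0.1 + 1e-12)
  expect_lte(res$oc$lambda, 0.1 + 1e-12)
  expect_lte(res$oc$delta, 0.1 + 1e-12)
  # forcing lambda = delta = 0 forces x0 = x1 and recovers the two-outcome n
  res0 <- find_sargent_original(p, 0.05, 0.1, 0, 0)
  expect_equal(res0$design$x0, res0$design$x1)
  expect_equal(res0$design$n, find_two_outcome(p)$n)
})

test_that("Sargent-original search agrees with exhaustive enumeration", {
  p <- pilot_problem(0.2, 0.4)
  res <- find_sargent_original(p, 0.15, 0.15, 0.15, 0.15)
  brute <- NULL
  for (n in 1:200) {
    found <- FALSE
    for (x1 in -1:n) {
      x0 <- -1:x1
      aa <- pmf_region(n, x1 + 1, n, 0.2)
      ok <- pmf_region(n, 0, x1, 0.2) - pbinom(x0, n, 0.2) <= 0.15 + 1e-12 &
        pbinom(x0, n, 0.4) <= 0.15 + 1e-12 &
        pbinom(x1, n, 0.4) - pbinom(x0, n, 0.4) <= 0.15 + 1e-12 &
        aa <= 0.15 + 1e-12
      if (any(ok)) { found <- TRUE; break }
    }
    if (found) { brute <- n; break }
  }
  expect_equal(res$design$n, brute)
})

test_that("Storer-original search respects all four constraints and near-vacuous cases hit the floor", {
  p <- adherence_problem()
  res <- find_storer_original(p, 0.3, 0.3, 0.2, 0.2)
  expect_lte(res$oc$alpha_b, 0.3 + 1e-12)
  expect_lte(res$oc$beta_b, 0.3 + 1e-12)
  expect_lte(res$oc$gamma_L, 0.2 + 1e-12)
  expect_lte(res$oc$gamma_U, 0.2 + 1e-12)
  # independent exhaustive check of minimality
  brute <- NULL
  for (n in 1:100) {
    found <- FALSE
    for (x1 in -1:n) {
      if (pbinom(x1, n, 0.7) > 0.3 + 1e-12) next
      if (1 - pbinom(x1, n, 0.6) > 0.2 + 1e-12) next
      x0 <- -1:x1
      if (any(1 - pbinom(x0, n, 0.5) <= 0.3 + 1e-12 &
              pbinom(x0, n, 0.6) <= 0.2 + 1e-12)) { found <- TRUE; break }
    }
    if (found) { brute <- n; break }
  }
  expect_equal(res$design$n, brute)
  # near-vacuous constraints are satisfied at the bottom of the search range:
  # n = 1 fails only because gamma_U and beta_b cannot both hold with one subject
  expect_equal(find_storer_original(p, 0.99, 0.99, 0.5, 0.5)$design$n, 2L)
  # a two-outcome design always reaches a conclusive decision at rho_m
  oc <- oc_classic(three_outcome_design(20, 11, 11), p)
  expect_equal(oc$gamma_L + oc$gamma_U, 1)
})

test_that("threshold-inversion search agrees with the brute-force oracle on randomized problems", {
  set.seed(11)
  n_agree <- 0
  for (i in 1:12) {
    prob <- random_problem(with_tau = i %% 3 == 0)
    fast <- tryCatch(find_three_outcome(prob, search_settings(n_max = 150)),
                     stopgo_infeasible = function(e) NULL)
    slow <- tryCatch(brute_force_min_n(prob, search_settings(n_max = 150)),
                     stopgo_infeasible = function(e) NULL)
    if (is.null(fast)) {
      expect_null(slow)
    } else {
      expect_equal(fast$design$n, slow$design$n)
      n_agree <- n_agree + 1
    }
  }
  expect_gte(n_agree, 5)   # the generator must mostly produce feasible problems
})

test_that("returned designs re-validate against their constraints (closed loop)", {
  probs <- list(adherence_problem(),
                adherence_problem(gamma_star = 0.4),
                adherence_problem(tau_min = 0.05, tau_max = 0.08),
                adherence_problem(eta0 = 0.25, eta1 = 0.25))
  for (p in probs) {
    res <- find_three_outcome(p, search_settings(n_max = 300))
    oc <- oc_reformulated(res$design, p)
    expect_lte(oc$alpha, p$alpha_star + 1e-12)
    expect_lte(oc$beta, p$beta_star + 1e-12)
    expect_lte(oc$gamma, p$gamma_star + 1e-12)
  }
})

test_that("with guessing post-pause decisions the three-outcome n never beats the two-outcome n", {
  set.seed(23)
  for (i in 1:8) {
    prob <- random_problem()
    prob <- modifyList(unclass(prob), list(eta0 = 0.5, eta1 = 0.5, gamma_star = 1,
                                           tau_min = 0, tau_max = 0))
    prob <- do.call(pilot_problem, prob)
    two <- tryCatch(find_two_outcome(prob, search_settings(n_max = 200)),
                    stopgo_infeasible = function(e) NULL)
    three <- tryCatch(find_three_outcome(prob, search_settings(n_max = 200)),
                      stopgo_infeasible = function(e) NULL)
    if (!is.null(two) && !is.null(three)) expect_lte(three$design$n, two$n)
  }
})
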