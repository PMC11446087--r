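# The running adherence example used throughout the tests: poor rate 0.5,
# promising rate 0.7, conventional error constraints.
adherence_problem <- function(...) {
  # alpha_star = 0.05 and beta_star = 0.1 are the constructor defaults
  pilot_problem(rho0 = 0.5, rho1 = 0.7, ...)
}

# independent oracle: region probabilities by direct pmf summation
pmf_region <- function(n, lo, hi, rho) {
  k <- seq.int(max(lo, 0), min(hi, n))
  if (!length(k) || lo > hi) return(0)
  sum(stats::dbinom(k, n, rho))
}

# independent oracle for the reformulated error rates (scalar, pmf sums)
oracle_error_rates <- function(n, x0, x1, rho0, rho1, eta, tau_min = 0, tau_max = 0) {
  ra <- rho0 - tau_min
  rb <- rho1 - tau_max
  alpha <- max(pmf_region(n, x1 + 1, n, rho0),
               eta * pmf_region(n, x0 + 1, x1, ra) + pmf_region(n, x1 + 1, n, ra))
  beta <- pmf_region(n, 0, x0, rb) + eta * pmf_region(n, x0 + 1, x1, rb)
  c(alpha = alpha, beta = beta)
}

# random problem generator for property suites (fixed seed at call sites)
random_problem <- function(with_tau = FALSE) {
  rho0 <- runif(1, 0.2, 0.55)
  rho1 <- rho0 + runif(1, 0.15, 0.3)
  eta <- sample(c(0, 0.25, 0.5), 1)
  tau_min <- if (with_tau) runif(1, 0, min(0.05, rho0)) else 0
  tau_max <- if (with_tau) tau_min + runif(1, 0, 0.03) else 0
  pilot_problem(rho0 = rho0, rho1 = rho1,
                alpha_star = sample(c(0.05, 0.1, 0.15), 1),
                beta_star = sample(c(0.1, 0.2), 1),
                gamma_star = sample(c(0.8, 1), 1),
                eta0 = eta, eta1 = eta,
                tau_min = tau_min, tau_max = tau_max)
}
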