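#' Decision probabilities for a continuous endpoint with known sigma
#'
#' The estimate is modelled as \eqn{\hat\rho \sim N(\rho, \sigma^2/n)}.
#' With real thresholds `x0 <= x1`: stop iff \eqn{\hat\rho \le x_0}, pause
#' iff \eqn{x_0 < \hat\rho \le x_1}, go iff \eqn{\hat\rho > x_1}.
#'
#' @param design A continuous [three_outcome_design()].
#' @param rho True mean (vectorised).
#' @param sigma Known outcome standard deviation, > 0.
#' @return A data.frame with columns `rho`, `stop`, `pause`, `go`.
#' @examples
#' d <- three_outcome_design(100, -0.1, 0.2, endpoint = "continuous")
#' decision_probs_normal(d, 0, 1)
#' @export
decision_probs_normal <- function(design, rho, sigma) {
  stopifnot(inherits(design, "stopgo_design"))
  if (design$endpoint != "continuous")
    stop("decision_probs_normal() is for continuous endpoints", call. = FALSE)
  chk_num(sigma, "sigma")
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  s <- sigma / sqrt(design$n)
  p_stop <- stats::pnorm(design$x0, rho, s)
  p_go <- stats::pnorm(design$x1, rho, s, lower.tail = FALSE)
  p_pause <- pmax(0, stats::pnorm(design$x1, rho, s) - p_stop)
  data.frame(rho = rho, stop = p_stop, pause = p_pause, go = p_go)
}

# classic OCs under the normal sampling model (sigma from the problem)
oc_classic_normal <- function(design, problem) {
  p0 <- decision_probs_normal(design, problem$rho0, problem$sigma)
  p1 <- decision_probs_normal(design, problem$rho1, problem$sigma)
  pm <- decision_probs_normal(design, problem$rho_m, problem$sigma)
  structure(list(
    alpha_a = p0$go, beta_a = p1$stop,
    lambda = p0$pause, delta = p1$pause,
    alpha_b = p0$go + p0$pause, beta_b = p1$stop + p1$pause,
    gamma_L = pm$stop, gamma_U = pm$go, gamma = pm$stop + pm$go),
    class = "stopgo_oc")
}

#' Minimum sample size for a continuous endpoint
#'
#' Continuous analogue of [find_three_outcome()]: for each `n`, the stop
#' threshold solving the type I constraint with equality is obtained in
#' closed form from the normal quantile function, the go threshold is the
#' largest real `x1` with `x0 <= x1` and type II error at most
#' `beta_star` (found by root-finding to 1e-8 on the estimate scale), and
#' the smallest `n` whose design also satisfies
#' \eqn{\gamma \le \gamma^*} is returned.
#'
#' @param problem A continuous-endpoint [pilot_problem()].
#' @param settings A [search_settings()].
#' @return A `stopgo_result` (see [find_three_outcome()]).
#' @examples
#' p <- pilot_problem(0.5, 0.7, sigma = 0.5, endpoint = "continuous")
#' find_three_outcome_normal(p)$design$n
#' @export
find_three_outcome_normal <- function(problem, settings = search_settings()) {
  stopifnot(inherits(problem, "stopgo_problem"), problem$endpoint == "continuous")
  a <- problem$alpha_star; b <- problem$beta_star; g <- problem$gamma_star
  eta0 <- problem$eta0; eta1 <- problem$eta1
  ra <- problem$rho0 - problem$tau_min
  rb <- problem$rho1 - problem$tau_max
  for (n in settings$n_min:settings$n_max) {
    s <- problem$sigma / sqrt(n)
    x0_of <- function(x1) {
      if (eta0 == 0) return(rep(-Inf, length(x1)))
      q <- 1 / eta0 + (eta0 - 1) / eta0 * stats::pnorm(x1, ra, s) - a / eta0
      out <- ifelse(q <= 0, -Inf, ifelse(q >= 1, Inf, stats::qnorm(pmin(pmax(q, 0), 1), ra, s)))
      out
    }
    beta_of <- function(x1) {
      x0 <- x0_of(x1)
      Fb0 <- stats::pnorm(x0, rb, s)
      Fb0 + eta1 * (stats::pnorm(x1, rb, s) - Fb0)
    }
    x1_lo <- stats::qnorm(1 - a, problem$rho0, s)   # direct-go constraint
    x1_hi <- max(x1_lo, rb + 10 * s, problem$rho1 + 10 * s)
    grid <- seq(x1_lo, x1_hi, length.out = 512L)
    feas <- x0_of(grid) <= grid & beta_of(grid) <= b
    if (!any(feas)) next
    # largest feasible x1: refine the boundary between the last feasible
    # grid point and its infeasible right neighbour
    i <- max(which(feas))
    x1 <- grid[i]
    if (i < length(grid)) {
      f <- function(x) {
        viol <- max(beta_of(x) - b, x0_of(x) - x)
        viol
      }
      if (f(grid[i + 1L]) > 0) {
        root <- stats::uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-8)$root
        # step back inside the feasible region to respect the constraints
        x1 <- if (f(root) <= 0) root else grid[i]
      }
    }
    x0 <- x0_of(x1)
    gamma <- stats::pnorm(x0, problem$rho_m, s) +
      stats::pnorm(x1, problem$rho_m, s, lower.tail = FALSE)
    if (gamma <= g + EPS) {
      design <- three_outcome_design(n, x0, x1, endpoint = "continuous")
      return(new_result(design, problem))
    }
  }
  infeasible_stop("no continuous-endpoint design satisfies the constraints within n_max")
}
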