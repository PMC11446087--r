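#' Exact stop/pause/go decision probabilities for a binary endpoint
#'
#' With \eqn{X \sim Bin(n, \rho)} and the rule stop iff \eqn{X \le x_0},
#' pause iff \eqn{x_0 < X \le x_1}, go iff \eqn{X > x_1}, returns the three
#' exact outcome probabilities. They sum to 1 by construction.
#'
#' @param design A binary [three_outcome_design()].
#' @param rho True success probability, in \[0, 1\] (vectorised).
#' @return A data.frame with columns `rho`, `stop`, `pause`, `go`.
#' @examples
#' d <- three_outcome_design(30, 17, 17)
#' decision_probs(d, c(0.5, 0.7))
#' @export
decision_probs <- function(design, rho) {
  stopifnot(inherits(design, "stopgo_design"))
  if (design$endpoint != "binary")
    stop("decision_probs() is for binary endpoints; see decision_probs_normal()",
         call. = FALSE)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]", call. = FALSE)
  p_stop <- stats::pbinom(design$x0, design$n, rho)
  p_go <- stats::pbinom(design$x1, design$n, rho, lower.tail = FALSE)
  p_pause <- pmax(0, stats::pbinom(design$x1, design$n, rho) - p_stop)
  data.frame(rho = rho, stop = p_stop, pause = p_pause, go = p_go)
}

#' Classic three-outcome operating characteristics
#'
#' Computes, exactly, the Sargent operating characteristics
#' (\eqn{\alpha_a}: immediate go under \eqn{\rho_0}; \eqn{\beta_a}:
#' immediate stop under \eqn{\rho_1}; \eqn{\lambda}, \eqn{\delta}: pause
#' probabilities under the two hypotheses) and the Storer ones
#' (\eqn{\alpha_b = \alpha_a + \lambda}, \eqn{\beta_b = \beta_a + \delta},
#' and the conclusive-decision errors \eqn{\gamma_L}, \eqn{\gamma_U} at
#' the borderline value \eqn{\rho_m}), plus their sum
#' \eqn{\gamma = \gamma_L + \gamma_U}.
#'
#' @param design A binary [three_outcome_design()].
#' @param problem A [pilot_problem()] supplying `rho0`, `rho1`, `rho_m`.
#' @return A list of class `stopgo_oc` with fields `alpha_a`, `beta_a`,
#'   `lambda`, `delta`, `alpha_b`, `beta_b`, `gamma_L`, `gamma_U`, `gamma`.
#' @examples
#' oc_classic(three_outcome_design(30, 15, 20), pilot_problem(0.5, 0.7))
#' @export
oc_classic <- function(design, problem) {
  stopifnot(inherits(design, "stopgo_design"), inherits(problem, "stopgo_problem"))
  p0 <- decision_probs(design, problem$rho0)
  p1 <- decision_probs(design, problem$rho1)
  pm <- decision_probs(design, problem$rho_m)
  structure(list(
    alpha_a = p0$go, beta_a = p1$stop,
    lambda = p0$pause, delta = p1$pause,
    alpha_b = p0$go + p0$pause, beta_b = p1$stop + p1$pause,
    gamma_L = pm$stop, gamma_U = pm$go, gamma = pm$stop + pm$go),
    class = "stopgo_oc")
}

#' Reformulated error rates allowing post-pause decisions and adjustment
#'
#' The overall type I error rate is the probability of any route to an
#' (eventually) wrong go decision, and the type II rate likewise for wrong
#' stop decisions. With no adjustment (`tau_min = tau_max = 0`) these are
#' \deqn{\alpha = \alpha_a + \eta_0 \lambda, \qquad
#'       \beta = \beta_a + \eta_1 \delta.}
#' With an adjustment effect \eqn{\tau \in [\tau_{min}, \tau_{max}]}
#' applied after a pause (requiring a common \eqn{\eta}),
#' \deqn{\alpha = \max[\Pr(X > x_1 \mid \rho_0),\;
#'   \eta \Pr(x_0 < X \le x_1 \mid \rho_0 - \tau_{min}) +
#'   \Pr(X > x_1 \mid \rho_0 - \tau_{min})]}
#' \deqn{\beta = \Pr(X \le x_0 \mid \rho_1 - \tau_{max}) +
#'   \eta \Pr(x_0 < X \le x_1 \mid \rho_1 - \tau_{max}),}
#' the worst cases over the parameter values consistent with an error.
#' \eqn{\gamma} is always the conclusive-decision probability at
#' \eqn{\rho_m}, unshifted and unweighted. All classic fields are attached
#' as well.
#'
#' @inheritParams oc_classic
#' @return A list of class `stopgo_oc` with fields `alpha`, `beta`,
#'   `gamma` plus all [oc_classic()] fields.
#' @examples
#' d <- three_outcome_design(30, 15, 20)
#' oc <- oc_reformulated(d, pilot_problem(0.5, 0.7))
#' round(c(oc$alpha, oc$beta, oc$gamma), 2)   # 0.22 0.21 0.35
#' @export
oc_reformulated <- function(design, problem) {
  stopifnot(inherits(design, "stopgo_design"), inherits(problem, "stopgo_problem"))
  oc <- if (design$endpoint == "binary") oc_classic(design, problem) else
    oc_classic_normal(design, problem)
  ab <- error_rates(design$n, design$x0, design$x1, problem)
  oc$alpha <- ab$alpha
  oc$beta <- ab$beta
  oc
}

# Core reformulated alpha/beta, vectorised over x0/x1. Works for both
# endpoints through the tail helpers below. eta0 != eta1 is only meaningful
# at tau = [0,0], where the formulas decouple.
error_rates <- function(n, x0, x1, problem) {
  if (problem$tau_max > 0 && problem$eta0 != problem$eta1)
    stop("adjustment-aware error rates require eta0 == eta1 when tau_max > 0",
         call. = FALSE)
  F <- tail_cdf(problem, n)
  ra <- problem$rho0 - problem$tau_min
  rb <- problem$rho1 - problem$tau_max
  alpha <- pmax(1 - F(x1, problem$rho0),
                problem$eta0 * (F(x1, ra) - F(x0, ra)) + 1 - F(x1, ra))
  beta <- F(x0, rb) + problem$eta1 * (F(x1, rb) - F(x0, rb))
  list(alpha = alpha, beta = beta,
       gamma = F(x0, problem$rho_m) + 1 - F(x1, problem$rho_m))
}

# CDF of the decision statistic at threshold x for true parameter rho:
# binomial count or normal mean with known sigma.
tail_cdf <- function(problem, n) {
  if (problem$endpoint == "binary") {
    function(x, rho) stats::pbinom(x, n, rho)
  } else {
    s <- problem$sigma / sqrt(n)
    function(x, rho) stats::pnorm(x, rho, s)
  }
}

#' @export
print.stopgo_oc <- function(x, digits = 3, ...) {
  cat("Operating characteristics\n")
  if (!is.null(x$alpha))
    cat(sprintf("  overall: alpha = %.*f, beta = %.*f, gamma = %.*f\n",
                digits, x$alpha, digits, x$beta, digits, x$gamma))
  cat(sprintf("  Sargent: alpha_a = %.*f, beta_a = %.*f, lambda = %.*f, delta = %.*f\n",
              digits, x$alpha_a, digits, x$beta_a, digits, x$lambda, digits, x$delta))
  cat(sprintf("  Storer : alpha_b = %.*f, beta_b = %.*f, gamma_L = %.*f, gamma_U = %.*f\n",
              digits, x$alpha_b, digits, x$beta_b, digits, x$gamma_L, digits, x$gamma_U))
  invisible(x)
}
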