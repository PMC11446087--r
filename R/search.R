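#' Search settings
#'
#' Bounds for the ascending sample-size searches.
#'
#' @param n_min Integer floor of the search (default 1).
#' @param n_max Integer cap (default 2000). Searches iterate `n` upwards
#'   from `n_min` and raise an infeasibility error at the cap.
#' @return A list of class `stopgo_settings`.
#' @export
search_settings <- function(n_min = 1L, n_max = 2000L) {
  chk_num(n_min, "n_min"); chk_num(n_max, "n_max")
  if (n_min < 1 || n_min > n_max) stop("need 1 <= n_min <= n_max", call. = FALSE)
  structure(list(n_min = as.integer(n_min), n_max = as.integer(n_max)),
            class = "stopgo_settings")
}

# float guard for constraint comparisons; never a substantive relaxation
EPS <- 1e-12

# Raise a classed infeasibility condition carrying the best near-feasible
# candidate, so callers can distinguish "no design exists below the cap"
# from user error and report how close the search got.
infeasible_stop <- function(msg, best = NULL) {
  cond <- structure(class = c("stopgo_infeasible", "error", "condition"),
                    list(message = paste0(
                      msg, if (!is.null(best)) paste0(
                        "; best candidate: ", format_candidate(best))),
                      call = NULL, best = best))
  stop(cond)
}

format_candidate <- function(best) {
  paste0("n = ", best$n, ", x0 = ", best$x0, ", x1 = ", best$x1,
         ", alpha = ", signif(best$alpha, 4), ", beta = ", signif(best$beta, 4),
         if (!is.null(best$gamma)) paste0(", gamma = ", signif(best$gamma, 4)))
}

#' Minimum sample size for a two-outcome (stop/go) progression criterion
#'
#' Finds the smallest `n` admitting a single threshold `x` (go iff the
#' statistic exceeds `x`) with exact type I error
#' \eqn{\Pr[X > x \mid \rho_0] \le \alpha^*} and type II error
#' \eqn{\Pr[X \le x \mid \rho_1] \le \beta^*}. For binary endpoints this
#' is the classic exact single-stage (A'Hern-type) design; among feasible
#' thresholds at the minimal `n` the smallest (power-maximising) `x` is
#' returned. For continuous endpoints the closed-form normal solution is
#' used.
#'
#' @param problem A [pilot_problem()]; only `rho0`, `rho1`, `alpha_star`,
#'   `beta_star` and the endpoint model are used.
#' @param settings A [search_settings()].
#' @return A `stopgo_design` with `x0 == x1`.
#' @examples
#' find_two_outcome(pilot_problem(0.5, 0.7))$n   # 53
#' @export
find_two_outcome <- function(problem, settings = search_settings()) {
  stopifnot(inherits(problem, "stopgo_problem"))
  a <- problem$alpha_star; b <- problem$beta_star
  if (problem$endpoint == "continuous") {
    za <- stats::qnorm(1 - a); zb <- stats::qnorm(1 - b)
    n <- max(settings$n_min,
             ceiling(problem$sigma^2 * (za + zb)^2 / (problem$rho1 - problem$rho0)^2))
    if (n > settings$n_max) infeasible_stop("no two-outcome design within n_max")
    x <- problem$rho0 + za * problem$sigma / sqrt(n)
    return(three_outcome_design(n, x, x, endpoint = "continuous"))
  }
  best <- NULL
  for (n in settings$n_min:settings$n_max) {
    x <- -1:n
    alpha <- stats::pbinom(x, n, problem$rho0, lower.tail = FALSE)
    beta <- stats::pbinom(x, n, problem$rho1)
    ok <- alpha <= a + EPS & beta <= b + EPS
    if (any(ok)) {
      x_star <- x[ok][1]
      return(three_outcome_design(n, x_star, x_star))
    }
    viol <- pmax(alpha - a, 0) + pmax(beta - b, 0)
    i <- which.min(viol)
    if (is.null(best) || viol[i] < best$viol)
      best <- list(n = n, x0 = x[i], x1 = x[i], alpha = alpha[i], beta = beta[i],
                   viol = viol[i])
  }
  infeasible_stop("no two-outcome design satisfies the error constraints within n_max",
                  best)
}

#' Lower threshold implied by the type I error constraint
#'
#' Given `n` and an upper threshold `x1` whose direct-go error satisfies
#' \eqn{\Pr[X > x_1 \mid \rho_0] \le \alpha^*}, returns the stop threshold
#' `x0` that makes the overall type I error (including wrong go decisions
#' after a pause, and any adjustment shift) as large as possible while
#' still at most `alpha_star`. For binary endpoints this is the smallest
#' integer `x0 >= -1` with \eqn{\alpha(n, x_0, x_1) \le \alpha^*}; for
#' continuous endpoints the exact real solution attaining equality (or
#' `-Inf` when even an empty stop region keeps \eqn{\alpha < \alpha^*}).
#'
#' @param n Sample size.
#' @param x1 Upper threshold (count scale for binary endpoints).
#' @param problem A [pilot_problem()].
#' @return The lower threshold `x0`.
#' @export
x0_from_alpha <- function(n, x1, problem) {
  stopifnot(inherits(problem, "stopgo_problem"))
  a <- problem$alpha_star
  F <- tail_cdf(problem, n)
  if (1 - F(x1, problem$rho0) > a + EPS)
    infeasible_stop("x1 too small for alpha_star")
  ra <- problem$rho0 - problem$tau_min
  eta <- problem$eta0
  if (problem$endpoint == "binary") {
    if (eta == 0) return(-1L)
    target <- (eta * F(x1, ra) + 1 - F(x1, ra) - a) / eta
    if (target <= 0) return(-1L)
    Fa <- stats::pbinom(-1:x1, n, ra)
    j <- findInterval(target - EPS, Fa) + 1L
    if (j > length(Fa)) infeasible_stop("x1 too small for alpha_star")
    return(as.integer(j - 2L))
  }
  if (eta == 0) return(-Inf)
  q <- 1 / eta + (eta - 1) / eta * F(x1, ra) - a / eta
  if (q <= 0) return(-Inf)
  if (q >= 1) return(Inf)
  stats::qnorm(q, ra, problem$sigma / sqrt(n))
}

#' Minimum sample size for the reformulated three-outcome design
#'
#' Implements the nested search: for each `n` ascending, consider upper
#' thresholds `x1` whose direct-go error under \eqn{\rho_0} is at most
#' `alpha_star`; set `x0` from the type I constraint via
#' [x0_from_alpha()]; among candidates with `x0 <= x1` and overall type II
#' error at most `beta_star`, keep the largest `x1`; accept the first `n`
#' whose resulting design also satisfies the conclusive-decision
#' constraint \eqn{\gamma \le \gamma^*} at `rho_m`. Dispatches to the
#' continuous-endpoint search for continuous problems.
#'
#' @inheritParams find_two_outcome
#' @return A list of class `stopgo_result` with elements `design`
#'   (a `stopgo_design`), `oc` (its [oc_reformulated()] operating
#'   characteristics) and `problem`.
#' @examples
#' res <- find_three_outcome(pilot_problem(0.5, 0.7))
#' res$design$n   # 52
#' @export
find_three_outcome <- function(problem, settings = search_settings()) {
  stopifnot(inherits(problem, "stopgo_problem"))
  if (problem$endpoint == "continuous")
    return(find_three_outcome_normal(problem, settings))
  a <- problem$alpha_star; b <- problem$beta_star; g <- problem$gamma_star
  eta <- problem$eta0
  ra <- problem$rho0 - problem$tau_min
  rb <- problem$rho1 - problem$tau_max
  best <- NULL
  for (n in settings$n_min:settings$n_max) {
    F0 <- stats::pbinom(-1:n, n, problem$rho0)  # index i <-> count i - 2
    x1 <- (-1:n)[1 - F0 <= a + EPS]
    if (!length(x1)) next
    Fa <- stats::pbinom(-1:n, n, ra)
    Fa_x1 <- Fa[x1 + 2L]
    if (eta == 0) {
      x0 <- rep(-1L, length(x1))
    } else {
      target <- (eta * Fa_x1 + 1 - Fa_x1 - a) / eta
      x0 <- findInterval(target - EPS, Fa) - 1L   # smallest count with Fa >= target
      x0[target <= 0] <- -1L
    }
    Fb <- stats::pbinom(-1:n, n, rb)
    beta <- Fb[x0 + 2L] + problem$eta1 * (Fb[x1 + 2L] - Fb[x0 + 2L])
    ok <- x0 <= x1 & beta <= b + EPS
    if (!any(ok)) {
      viol <- pmax(beta - b, 0) + ifelse(x0 <= x1, 0, Inf)
      i <- which.min(viol)
      if (is.finite(viol[i]) && (is.null(best) || viol[i] < best$viol))
        best <- list(n = n, x0 = x0[i], x1 = x1[i], alpha = a, beta = beta[i],
                     viol = viol[i])
      next
    }
    i <- max(which(ok))                           # largest feasible x1
    Fm <- stats::pbinom(c(x0[i], x1[i]), n, problem$rho_m)
    gamma <- Fm[1] + 1 - Fm[2]
    if (gamma <= g + EPS) {
      design <- three_outcome_design(n, x0[i], x1[i])
      return(new_result(design, problem))
    }
    if (is.null(best) || gamma - g < best$viol)
      best <- list(n = n, x0 = x0[i], x1 = x1[i], alpha = a, beta = beta[i],
                   gamma = gamma, viol = gamma - g)
  }
  infeasible_stop("no three-outcome design satisfies the constraints within n_max",
                  best)
}

new_result <- function(design, problem) {
  oc <- oc_reformulated(design, problem)
  structure(list(design = design, oc = oc, problem = problem,
                 slack = c(alpha = problem$alpha_star - oc$alpha,
                           beta = problem$beta_star - oc$beta,
                           gamma = problem$gamma_star - oc$gamma)),
            class = "stopgo_result")
}

#' @export
print.stopgo_result <- function(x, ...) {
  print(x$design)
  cat(sprintf("  alpha = %.4f (<= %g), beta = %.4f (<= %g), gamma = %.4f (<= %g)\n",
              x$oc$alpha, x$problem$alpha_star,
              x$oc$beta, x$problem$beta_star,
              x$oc$gamma, x$problem$gamma_star))
  invisible(x)
}

#' Original Sargent and Storer three-outcome designs
#'
#' `find_sargent_original()` minimises `n` subject to the four classic
#' Sargent constraints: immediate-go error \eqn{\alpha_a \le} `alpha_a_star`,
#' immediate-stop error \eqn{\beta_a \le} `beta_a_star`, and pause
#' probabilities \eqn{\lambda \le} `lambda_star` (under \eqn{\rho_0}) and
#' \eqn{\delta \le} `delta_star` (under \eqn{\rho_1}).
#' `find_storer_original()` instead constrains \eqn{\alpha_b} (non-stop
#' under \eqn{\rho_0}), \eqn{\beta_b} (non-go under \eqn{\rho_1}) and the
#' conclusive-decision errors \eqn{\gamma_L}, \eqn{\gamma_U} at `rho_m`.
#' Both searches are exhaustive over integer `x0 <= x1` at each `n`,
#' breaking ties by the largest `x1`, then the largest `x0`.
#'
#' @param problem A [pilot_problem()] supplying the hypotheses (binary
#'   endpoint only).
#' @param alpha_a_star,beta_a_star,lambda_star,delta_star Sargent
#'   constraints, each in (0, 1].
#' @param settings A [search_settings()].
#' @return A `stopgo_result` (see [find_three_outcome()]).
#' @examples
#' p <- pilot_problem(0.5, 0.7)
#' find_sargent_original(p, 0.05, 0.1, 0.1, 0.1)$design$n   # 42
#' @export
find_sargent_original <- function(problem, alpha_a_star, beta_a_star,
                                  lambda_star, delta_star,
                                  settings = search_settings()) {
  stopifnot(inherits(problem, "stopgo_problem"), problem$endpoint == "binary")
  for (n in settings$n_min:settings$n_max) {
    F0 <- stats::pbinom(-1:n, n, problem$rho0)
    F1 <- stats::pbinom(-1:n, n, problem$rho1)
    for (x1 in n:(-1)) {
      if (1 - F0[x1 + 2L] > alpha_a_star + EPS) break  # alpha_a grows as x1 falls
      x0 <- -1:x1
      ok <- F1[x0 + 2L] <= beta_a_star + EPS &
        F0[x1 + 2L] - F0[x0 + 2L] <= lambda_star + EPS &
        F1[x1 + 2L] - F1[x0 + 2L] <= delta_star + EPS
      if (any(ok))
        return(new_result(three_outcome_design(n, max(x0[ok]), x1), problem))
    }
  }
  infeasible_stop("no design satisfies the Sargent constraints within n_max")
}

#' @rdname find_sargent_original
#' @param alpha_b_star,beta_b_star,gamma_L_star,gamma_U_star Storer
#'   constraints, each in (0, 1].
#' @examples
#' find_storer_original(p, 0.3, 0.3, 0.2, 0.2)$design$n
#' @export
find_storer_original <- function(problem, alpha_b_star, beta_b_star,
                                 gamma_L_star, gamma_U_star,
                                 settings = search_settings()) {
  stopifnot(inherits(problem, "stopgo_problem"), problem$endpoint == "binary")
  for (n in settings$n_min:settings$n_max) {
    F0 <- stats::pbinom(-1:n, n, problem$rho0)
    F1 <- stats::pbinom(-1:n, n, problem$rho1)
    Fm <- stats::pbinom(-1:n, n, problem$rho_m)
    for (x1 in n:(-1)) {
      if (1 - Fm[x1 + 2L] > gamma_U_star + EPS) break  # gamma_U grows as x1 falls
      if (F1[x1 + 2L] > beta_b_star + EPS) next
      x0 <- -1:x1
      ok <- 1 - F0[x0 + 2L] <= alpha_b_star + EPS &
        Fm[x0 + 2L] <= gamma_L_star + EPS
      if (any(ok))
        return(new_result(three_outcome_design(n, max(x0[ok]), x1), problem))
    }
  }
  infeasible_stop("no design satisfies the Storer constraints within n_max")
}

#' Brute-force verification oracle for the minimum sample size
#'
#' Exhaustively enumerates every design `-1 <= x0 <= x1 <= n` for each `n`
#' ascending, evaluating the reformulated error rates exactly, and returns
#' the smallest feasible `n` (thresholds tie-broken as in
#' [find_three_outcome()]: largest `x1`, then the type-I-maximising, i.e.
#' smallest, feasible `x0`). Intended as an independent check on the
#' threshold-inversion search; the two must agree on `n`.
#'
#' @inheritParams find_two_outcome
#' @return A `stopgo_result`.
#' @export
brute_force_min_n <- function(problem, settings = search_settings(n_max = 1000L)) {
  stopifnot(inherits(problem, "stopgo_problem"), problem$endpoint == "binary")
  a <- problem$alpha_star; b <- problem$beta_star; g <- problem$gamma_star
  for (n in settings$n_min:settings$n_max) {
    for (x1 in n:(-1)) {
      x0 <- -1:x1
      rates <- error_rates(n, x0, x1, problem)
      ok <- rates$alpha <= a + EPS & rates$beta <= b + EPS & rates$gamma <= g + EPS
      if (any(ok))
        return(new_result(three_outcome_design(n, min(x0[ok]), x1), problem))
    }
  }
  infeasible_stop("no design found by exhaustive enumeration within n_max")
}
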