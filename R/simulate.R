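#' Monte Carlo validation of analytic operating characteristics
#'
#' Simulates the full decision process: a pilot outcome is drawn from the
#' sampling model at `rho_true` and classified as stop/pause/go; a pause
#' is resolved by a final decision that is wrong with the problem's
#' post-pause error probabilities. When an adjustment interval is set, a
#' pause draws an adjustment effect \eqn{\tau \sim U[\tau_{min},
#' \tau_{max}]} and correctness of the final decision is judged against
#' the adjusted parameter \eqn{\rho' = \rho + \tau}: if
#' \eqn{\rho' \le \rho_0} a final go is wrong (probability `eta0`), if
#' \eqn{\rho' \ge \rho_1} a final stop is wrong (probability `eta1`), and
#' in the indeterminate zone between the hypotheses the final decision is
#' a coin flip.
#'
#' @param design A [three_outcome_design()].
#' @param problem A [pilot_problem()] (supplies the hypotheses, etas, the
#'   adjustment interval, and `sigma` for continuous endpoints).
#' @param rho_true True parameter value to simulate under.
#' @param n_reps Number of replicates (default 1e5).
#' @param seed Integer seed; the generator state is scoped to this call
#'   and the result is reproducible for a fixed seed.
#' @return A list of class `stopgo_sim`: empirical `stop`, `pause`, `go`
#'   frequencies, overall `go_overall` / `stop_overall` rates (after
#'   post-pause resolution), their Wald standard errors, and the analytic
#'   values from the exact engine for comparison.
#' @examples
#' sim <- simulate_oc(three_outcome_design(30, 15, 20),
#'                    pilot_problem(0.5, 0.7), rho_true = 0.5,
#'                    n_reps = 1e4, seed = 1)
#' sim$go_overall          # close to the analytic alpha 0.22
#' @export
simulate_oc <- function(design, problem, rho_true, n_reps = 1e5, seed = 1L) {
  stopifnot(inherits(design, "stopgo_design"), inherits(problem, "stopgo_problem"))
  chk_num(rho_true, "rho_true"); chk_num(n_reps, "n_reps"); chk_num(seed, "seed")
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    est <- if (design$endpoint == "binary") {
      stats::rbinom(n_reps, design$n, rho_true)
    } else {
      stats::rnorm(n_reps, rho_true, problem$sigma / sqrt(design$n))
    }
    outcome <- ifelse(est > design$x1, "go",
                      ifelse(est > design$x0, "pause", "stop"))
    is_pause <- outcome == "pause"
    n_pause <- sum(is_pause)
    go_final <- outcome == "go"
    if (n_pause > 0) {
      tau <- stats::runif(n_pause, problem$tau_min, problem$tau_max)
      rho_adj <- rho_true + tau
      u <- stats::runif(n_pause)
      # wrong final decision with probability eta; coin flip when the
      # adjusted parameter falls strictly between the hypotheses
      p_go <- ifelse(rho_adj <= problem$rho0, problem$eta0,
                     ifelse(rho_adj >= problem$rho1, 1 - problem$eta1, 0.5))
      go_final[is_pause] <- u < p_go
    }
  })
  emp <- c(stop = mean(outcome == "stop"), pause = mean(outcome == "pause"),
           go = mean(outcome == "go"))
  go_overall <- mean(go_final)
  se <- function(p) sqrt(p * (1 - p) / n_reps)
  ana <- if (design$endpoint == "binary") {
    decision_probs(design, rho_true)
  } else {
    decision_probs_normal(design, rho_true, problem$sigma)
  }
  structure(list(
    n_reps = n_reps, seed = as.integer(seed), rho_true = rho_true,
    stop = emp[["stop"]], pause = emp[["pause"]], go = emp[["go"]],
    go_overall = go_overall, stop_overall = 1 - go_overall,
    se = c(stop = se(emp[["stop"]]), pause = se(emp[["pause"]]),
           go = se(emp[["go"]]), go_overall = se(go_overall),
           stop_overall = se(go_overall)),
    analytic = list(stop = ana$stop, pause = ana$pause, go = ana$go)),
    class = "stopgo_sim")
}

#' @export
print.stopgo_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo operating characteristics (%d replicates, seed %d)\n",
              x$n_reps, x$seed))
  cat(sprintf("  rho_true = %g\n", x$rho_true))
  cat(sprintf("  stop %.4f (analytic %.4f)  pause %.4f (%.4f)  go %.4f (%.4f)\n",
              x$stop, x$analytic$stop, x$pause, x$analytic$pause,
              x$go, x$analytic$go))
  cat(sprintf("  overall go %.4f, overall stop %.4f\n",
              x$go_overall, x$stop_overall))
  invisible(x)
}

#' Write a simulation report as JSON
#'
#' @param sim A `stopgo_sim` from [simulate_oc()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_simulation_json <- function(sim, path) {
  stopifnot(inherits(sim, "stopgo_sim"))
  jsonlite::write_json(unclass(sim), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
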