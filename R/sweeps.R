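#' Sensitivity sweeps of the optimal design
#'
#' Each sweep re-solves the minimum-sample-size problem over a grid of one
#' design parameter, holding the rest of the problem fixed, and returns a
#' tidy table of the optimal design and its realised operating
#' characteristics at each grid point. Grid points where no design exists
#' below the search cap are recorded with `feasible = FALSE` rather than
#' failing the whole sweep.
#'
#' * `sweep_eta()`: post-pause error probability \eqn{\eta} (common to
#'   both hypotheses), grid restricted to \[0, 0.5\] — values above 0.5
#'   mean worse-than-random post-pause decisions, under which the
#'   two-outcome design is optimal anyway.
#' * `sweep_gamma()`: conclusive-decision constraint \eqn{\gamma^*}; at
#'   \eqn{\gamma^* = 1} the optimum reduces to the two-outcome design.
#' * `sweep_tau()`: Cartesian sweep over the adjustment-interval lower
#'   bound `tau_min` and width `tau_max - tau_min`; the width-0 rows trace
#'   the known-adjustment-effect curve.
#'
#' @param problem A [pilot_problem()] giving the fixed part of the design
#'   problem.
#' @param eta_grid,gamma_grid Numeric grids for the swept parameter.
#' @param tau_min_grid,width_grid Numeric grids for the adjustment sweep.
#' @param settings A [search_settings()].
#' @return A data.frame of class `stopgo_sweep`: one row per grid point
#'   with the swept parameter(s), `n`, `x0`, `x1`, realised `alpha`,
#'   `beta`, `gamma`, the intermediate-zone width `width = x1 - x0`, and
#'   `feasible`.
#' @examples
#' \donttest{
#' sweep_eta(pilot_problem(0.5, 0.7), eta_grid = c(0.3, 0.4, 0.5))
#' }
#' @export
sweep_eta <- function(problem, eta_grid = seq(0, 0.5, by = 0.05),
                      settings = search_settings()) {
  stopifnot(all(eta_grid >= 0 & eta_grid <= 0.5))
  rows <- lapply(sort(eta_grid), function(eta) {
    p <- modify_problem(problem, eta0 = eta, eta1 = eta)
    sweep_row(list(eta = eta), p, settings)
  })
  as_sweep(rows)
}

#' @rdname sweep_eta
#' @export
sweep_gamma <- function(problem, gamma_grid = seq(0.3, 1, by = 0.05),
                        settings = search_settings()) {
  rows <- lapply(sort(gamma_grid), function(gs) {
    p <- modify_problem(problem, gamma_star = gs)
    sweep_row(list(gamma_star = gs), p, settings)
  })
  as_sweep(rows)
}

#' @rdname sweep_eta
#' @export
sweep_tau <- function(problem, tau_min_grid = seq(0, 0.1, by = 0.01),
                      width_grid = seq(0, 0.05, by = 0.01),
                      settings = search_settings()) {
  grid <- expand.grid(tau_width = sort(width_grid), tau_min = sort(tau_min_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tmin <- grid$tau_min[i]; w <- grid$tau_width[i]
    p <- modify_problem(problem, tau_min = tmin, tau_max = tmin + w)
    sweep_row(list(tau_min = tmin, tau_width = w), p, settings)
  })
  as_sweep(rows)
}

# re-validate a problem with some fields replaced
modify_problem <- function(problem, ...) {
  new <- utils::modifyList(unclass(problem), list(...))
  do.call(pilot_problem, new)
}

sweep_row <- function(id, problem, settings) {
  res <- tryCatch(find_three_outcome(problem, settings),
                  stopgo_infeasible = function(e) NULL)
  if (is.null(res)) {
    c(id, list(n = NA_integer_, x0 = NA_real_, x1 = NA_real_,
               alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
               width = NA_real_, feasible = FALSE))
  } else {
    c(id, list(n = res$design$n, x0 = res$design$x0, x1 = res$design$x1,
               alpha = res$oc$alpha, beta = res$oc$beta, gamma = res$oc$gamma,
               width = res$design$x1 - res$design$x0, feasible = TRUE))
  }
}

as_sweep <- function(rows) {
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  class(out) <- c("stopgo_sweep", "data.frame")
  out
}

#' Error-rate inflation under a misspecified post-pause error probability
#'
#' For each assumed \eqn{\eta} in the grid, finds the optimal design under
#' that assumption and then re-evaluates its type I and II error rates
#' under the true \eqn{\eta}. Optimising under an optimistically small
#' \eqn{\eta} buys sample size at the cost of inflated realised error
#' rates when post-pause decisions are in fact no better than guessing.
#'
#' @inheritParams sweep_eta
#' @param eta_assumed_grid Assumed values of \eqn{\eta} used to optimise.
#' @param eta_true The true common \eqn{\eta} used to re-evaluate.
#' @return A data.frame with one row per assumed \eqn{\eta}: the optimal
#'   design under the assumption and the realised `alpha`, `beta` under
#'   `eta_true`.
#' @export
misspecified_eta_curve <- function(problem,
                                   eta_assumed_grid = seq(0, 0.5, by = 0.05),
                                   eta_true = 0.5,
                                   settings = search_settings()) {
  rows <- lapply(sort(eta_assumed_grid), function(eta) {
    p <- modify_problem(problem, eta0 = eta, eta1 = eta)
    res <- tryCatch(find_three_outcome(p, settings),
                    stopgo_infeasible = function(e) NULL)
    if (is.null(res))
      return(data.frame(eta_assumed = eta, n = NA_integer_, x0 = NA_real_,
                        x1 = NA_real_, alpha = NA_real_, beta = NA_real_,
                        feasible = FALSE))
    p_true <- modify_problem(problem, eta0 = eta_true, eta1 = eta_true)
    oc <- oc_reformulated(res$design, p_true)
    data.frame(eta_assumed = eta, n = res$design$n, x0 = res$design$x0,
               x1 = res$design$x1, alpha = oc$alpha, beta = oc$beta,
               feasible = TRUE)
  })
  do.call(rbind, rows)
}

#' Operating-characteristic trade-offs at a fixed pilot sample size
#'
#' Rather than minimising `n` under error constraints, fixes `n` and
#' tabulates the reformulated and classic operating characteristics of a
#' set of candidate threshold pairs, showing what widening the amber zone
#' costs in overall error rates.
#'
#' @param n Fixed sample size.
#' @param problem A [pilot_problem()].
#' @param designs A list of `c(x0, x1)` pairs (count scale), or
#'   `stopgo_design` objects with this `n`.
#' @return A data.frame with one row per design: thresholds, `alpha`,
#'   `beta`, `gamma`, and the Sargent fields.
#' @examples
#' fixed_n_tradeoff(30, pilot_problem(0.5, 0.7),
#'                  designs = list(c(17, 17), c(15, 20)))
#' @export
fixed_n_tradeoff <- function(n, problem, designs) {
  rows <- lapply(designs, function(d) {
    if (!inherits(d, "stopgo_design"))
      d <- three_outcome_design(n, d[1], d[2], endpoint = problem$endpoint)
    if (d$n != n) stop("all designs must have sample size n = ", n, call. = FALSE)
    oc <- oc_reformulated(d, problem)
    data.frame(n = n, x0 = d$x0, x1 = d$x1,
               alpha = oc$alpha, beta = oc$beta, gamma = oc$gamma,
               alpha_a = oc$alpha_a, beta_a = oc$beta_a,
               lambda = oc$lambda, delta = oc$delta)
  })
  do.call(rbind, rows)
}

#' Write a sweep table as RFC 4180 CSV
#'
#' @param sweep A data.frame from one of the sweep functions.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
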