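#' Run a design, evaluation, sweep or simulation from a configuration
#'
#' These are the orchestration entry points behind the command-line
#' interface (`inst/cli/stopgo.R`); they take a flat configuration list
#' (the parsed form of a JSON/YAML config file, possibly overridden by
#' CLI flags), run the corresponding engine, optionally write the result
#' to `config$output` in `config$format`, and return the result object.
#'
#' `run_design()` solves the minimum-sample-size problem
#' ([find_three_outcome()], or [find_sargent_original()] when the four
#' Sargent constraints are supplied as `sargent = c(alpha_a, beta_a,
#' lambda, delta)`), and renders a traffic-light report. `run_evaluate()`
#' computes the operating characteristics of a user-supplied design
#' (`n`, `x0`, `x1` in the config). `run_sweep()` dispatches on
#' `config$sweep` (`"eta"`, `"gamma"`, `"tau"`, `"misspecified_eta"`).
#' `run_simulate()` runs [simulate_oc()].
#'
#' @param config A named list; problem fields as in [pilot_problem()],
#'   plus optional `n_min`, `n_max`, `output`, `format`
#'   (`"json"`, `"csv"` or `"text"`), and the operation-specific fields
#'   described above.
#' @return The underlying result object, invisibly when written to file.
#' @export
run_design <- function(config) {
  problem <- problem_from_config(config)
  settings <- settings_from_config(config)
  res <- if (!is.null(config$sargent)) {
    s <- as.numeric(config$sargent)
    if (length(s) != 4) stop("sargent must supply four constraints", call. = FALSE)
    find_sargent_original(problem, s[1], s[2], s[3], s[4], settings)
  } else {
    find_three_outcome(problem, settings)
  }
  emit(result_record(res), config, text = function() print_traffic_light(res))
}

#' @rdname run_design
#' @export
run_evaluate <- function(config) {
  problem <- problem_from_config(config)
  for (nm in c("n", "x0", "x1"))
    if (is.null(config[[nm]])) stop("evaluate needs field: ", nm, call. = FALSE)
  design <- three_outcome_design(config$n, config$x0, config$x1,
                                 endpoint = problem$endpoint)
  res <- new_result(design, problem)
  emit(result_record(res), config, text = function() print_traffic_light(res))
}

#' @rdname run_design
#' @export
run_sweep <- function(config) {
  problem <- problem_from_config(config)
  settings <- settings_from_config(config)
  kind <- if (is.null(config$sweep)) "eta" else config$sweep
  grid <- function(nm, default) if (is.null(config[[nm]])) default else as.numeric(config[[nm]])
  tab <- switch(kind,
    eta = sweep_eta(problem, grid("eta_grid", seq(0, 0.5, 0.05)), settings),
    gamma = sweep_gamma(problem, grid("gamma_grid", seq(0.3, 1, 0.05)), settings),
    tau = sweep_tau(problem, grid("tau_min_grid", seq(0, 0.1, 0.01)),
                    grid("width_grid", seq(0, 0.05, 0.01)), settings),
    misspecified_eta = misspecified_eta_curve(
      problem, grid("eta_grid", seq(0, 0.5, 0.05)),
      eta_true = if (is.null(config$eta_true)) 0.5 else config$eta_true,
      settings),
    stop("unknown sweep kind: ", kind, call. = FALSE))
  if (!is.null(config$output)) {
    write_sweep_csv(tab, config$output)
    return(invisible(tab))
  }
  tab
}

#' @rdname run_design
#' @export
run_simulate <- function(config) {
  problem <- problem_from_config(config)
  for (nm in c("n", "x0", "x1"))
    if (is.null(config[[nm]])) stop("simulate needs field: ", nm, call. = FALSE)
  design <- three_outcome_design(config$n, config$x0, config$x1,
                                 endpoint = problem$endpoint)
  sim <- simulate_oc(design, problem,
                     rho_true = if (is.null(config$rho_true)) problem$rho0 else config$rho_true,
                     n_reps = if (is.null(config$n_reps)) 1e5 else config$n_reps,
                     seed = if (is.null(config$seed)) 1L else config$seed)
  if (!is.null(config$output)) {
    write_simulation_json(sim, config$output)
    return(invisible(sim))
  }
  sim
}

settings_from_config <- function(config) {
  search_settings(
    n_min = if (is.null(config$n_min)) 1L else config$n_min,
    n_max = if (is.null(config$n_max)) 2000L else config$n_max)
}

# full-precision flat record of a design result, serialisable to JSON/CSV
result_record <- function(res) {
  oc <- res$oc
  c(list(n = res$design$n, x0 = res$design$x0, x1 = res$design$x1,
         endpoint = res$design$endpoint),
    oc[c("alpha", "beta", "gamma", "alpha_a", "beta_a", "lambda", "delta",
         "alpha_b", "beta_b", "gamma_L", "gamma_U")],
    list(slack_alpha = res$slack[["alpha"]], slack_beta = res$slack[["beta"]],
         slack_gamma = res$slack[["gamma"]]))
}

emit <- function(record, config, text) {
  fmt <- if (is.null(config$format)) {
    if (is.null(config$output)) "text" else "json"
  } else config$format
  if (is.null(config$output)) {
    if (fmt == "text") text() else
      cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n")
    return(invisible(record))
  }
  switch(fmt,
    json = jsonlite::write_json(record, config$output, auto_unbox = TRUE, digits = NA),
    csv = utils::write.csv(as.data.frame(record), config$output, row.names = FALSE),
    text = {
      con <- file(config$output, "w"); on.exit(close(con))
      sink(con); on.exit(sink(), add = TRUE, after = FALSE)
      text()
    },
    stop("unknown format: ", fmt, call. = FALSE))
  invisible(record)
}

# human-readable traffic-light interpretation of a design result
print_traffic_light <- function(res) {
  print(res$design)
  print(res$oc)
  cat(sprintf("  constraint slack: alpha %+.4f, beta %+.4f, gamma %+.4f\n",
              res$slack[["alpha"]], res$slack[["beta"]], res$slack[["gamma"]]))
  invisible(res)
}
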