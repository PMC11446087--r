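#' Specify a pilot-trial progression design problem
#'
#' Bundles and validates everything needed to design or evaluate a
#' stop/pause/go progression rule: the hypotheses on the feasibility
#' parameter, the error-rate constraints, the post-pause decision model,
#' the adjustment-effect interval, and the endpoint model.
#'
#' The feasibility parameter \eqn{\rho} (for example an adherence
#' probability) is tested against a null ("poor") value \eqn{\rho_0} and an
#' alternative ("promising") value \eqn{\rho_1}. The midpoint
#' \eqn{\rho_m \in (\rho_0, \rho_1)} is the borderline value at which a
#' conclusive stop or go decision counts as an error of probability
#' \eqn{\gamma = \gamma_L + \gamma_U}; it defaults to
#' \eqn{(\rho_0 + \rho_1)/2}.
#'
#' A *pause* outcome is resolved later (by other data, stakeholders, or
#' after adjusting the intervention). `eta0` is the probability that this
#' later decision is a wrong *go* when in truth \eqn{\rho' \le \rho_0};
#' `eta1` the probability of a wrong *stop* when \eqn{\rho' \ge \rho_1}.
#' The conservative default is 0.5 (guessing). Adjustment-aware error
#' rates are only derived for a common `eta0 == eta1`, so a positive
#' `tau_max` requires equal etas.
#'
#' The adjustment applied after a pause shifts the main-trial parameter to
#' \eqn{\rho' = \rho + \tau} with \eqn{\tau} known up to the interval
#' `[tau_min, tau_max]`; `tau_min = tau_max = 0` recovers the
#' no-adjustment case.
#'
#' @param rho0 Null ("poor") parameter value. For binary endpoints a
#'   probability in (0, 1); for continuous endpoints any real.
#' @param rho1 Alternative ("promising") value; must exceed `rho0`.
#' @param rho_m Borderline value in `(rho0, rho1)`; default the midpoint.
#' @param alpha_star Constraint on the overall type I error rate, in (0, 1].
#' @param beta_star Constraint on the overall type II error rate, in (0, 1].
#' @param gamma_star Constraint on the conclusive-decision probability at
#'   `rho_m`, in (0, 1]. The default 1 is the trivial constraint that
#'   recovers the Sargent-style reformulation.
#' @param eta0,eta1 Post-pause wrong-decision probabilities in \[0, 1\];
#'   default 0.5 each.
#' @param tau_min,tau_max Bounds of the adjustment-effect interval,
#'   `0 <= tau_min <= tau_max`; defaults 0 (no adjustment). For binary
#'   endpoints `rho0 - tau_min` and `rho1 - tau_max` must stay in \[0, 1\].
#' @param endpoint `"binary"` (number of successes in `n`, exact binomial)
#'   or `"continuous"` (estimate normal with known `sigma`).
#' @param sigma Known outcome standard deviation; required iff
#'   `endpoint = "continuous"`.
#'
#' @return An object of class `stopgo_problem`: a validated list with the
#'   fields named as above.
#'
#' @examples
#' pilot_problem(rho0 = 0.5, rho1 = 0.7)                   # rho_m = 0.6
#' pilot_problem(0.5, 0.7, gamma_star = 0.4)               # Storer-style
#' pilot_problem(0.5, 0.7, tau_min = 0.05, tau_max = 0.1)  # with adjustment
#' @export
pilot_problem <- function(rho0, rho1, rho_m = NULL,
                          alpha_star = 0.05, beta_star = 0.1, gamma_star = 1,
                          eta0 = 0.5, eta1 = eta0,
                          tau_min = 0, tau_max = tau_min,
                          endpoint = c("binary", "continuous"),
                          sigma = NULL) {
  endpoint <- match.arg(endpoint)
  chk_num(rho0, "rho0"); chk_num(rho1, "rho1")
  if (endpoint == "binary") {
    if (rho0 <= 0 || rho0 >= 1) stop("rho0 must lie in (0, 1) for a binary endpoint", call. = FALSE)
    if (rho1 <= 0 || rho1 >= 1) stop("rho1 must lie in (0, 1) for a binary endpoint", call. = FALSE)
  }
  if (rho0 >= rho1) stop("rho0 < rho1 required", call. = FALSE)
  if (is.null(rho_m)) rho_m <- (rho0 + rho1) / 2
  chk_num(rho_m, "rho_m")
  if (rho_m <= rho0 || rho_m >= rho1)
    stop("rho_m must lie strictly between rho0 and rho1", call. = FALSE)

  chk_prob01 <- function(x, nm) {
    chk_num(x, nm)
    if (x <= 0 || x > 1) stop(nm, " must lie in (0, 1]", call. = FALSE)
  }
  chk_prob01(alpha_star, "alpha_star")
  chk_prob01(beta_star, "beta_star")
  chk_prob01(gamma_star, "gamma_star")

  for (nm in c("eta0", "eta1")) {
    v <- get(nm)
    chk_num(v, nm)
    if (v < 0 || v > 1) stop(nm, " must lie in [0, 1]", call. = FALSE)
  }

  chk_num(tau_min, "tau_min"); chk_num(tau_max, "tau_max")
  if (tau_min < 0) stop("tau_min must be >= 0", call. = FALSE)
  if (tau_min > tau_max) stop("tau_min <= tau_max required", call. = FALSE)
  if (endpoint == "binary") {
    if (rho0 - tau_min < 0)
      stop("rho0 - tau_min must be a valid probability (>= 0)", call. = FALSE)
    if (rho1 - tau_max < 0)
      stop("rho1 - tau_max must be a valid probability (>= 0)", call. = FALSE)
  }
  if (tau_max > 0 && eta0 != eta1)
    stop("adjustment-aware error rates require eta0 == eta1 when tau_max > 0",
         call. = FALSE)

  if (endpoint == "continuous") {
    if (is.null(sigma)) stop("sigma is required for a continuous endpoint", call. = FALSE)
    chk_num(sigma, "sigma")
    if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  } else if (!is.null(sigma)) {
    stop("sigma applies only to continuous endpoints", call. = FALSE)
  }

  structure(
    list(rho0 = rho0, rho1 = rho1, rho_m = rho_m,
         alpha_star = alpha_star, beta_star = beta_star,
         gamma_star = gamma_star,
         eta0 = eta0, eta1 = eta1,
         tau_min = tau_min, tau_max = tau_max,
         endpoint = endpoint, sigma = sigma),
    class = "stopgo_problem")
}

chk_num <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(nm, " must be a single non-missing number", call. = FALSE)
  invisible(x)
}

#' @export
print.stopgo_problem <- function(x, ...) {
  cat("Three-outcome progression design problem\n")
  cat(sprintf("  hypotheses : rho0 = %g, rho1 = %g, rho_m = %g\n",
              x$rho0, x$rho1, x$rho_m))
  cat(sprintf("  constraints: alpha* = %g, beta* = %g, gamma* = %g\n",
              x$alpha_star, x$beta_star, x$gamma_star))
  cat(sprintf("  post-pause : eta0 = %g, eta1 = %g\n", x$eta0, x$eta1))
  cat(sprintf("  adjustment : tau in [%g, %g]\n", x$tau_min, x$tau_max))
  cat(sprintf("  endpoint   : %s%s\n", x$endpoint,
              if (x$endpoint == "continuous") sprintf(" (sigma = %g)", x$sigma) else ""))
  invisible(x)
}

#' State a lower-is-better problem in the engines' orientation
#'
#' All engines assume that larger parameter values are better (go when the
#' estimate is high). For criteria where smaller is better (for example a
#' dropout rate), state the problem on its natural scale here — null
#' (poor) value *above* the promising one — and it is reflected into the
#' standard orientation: binary parameters map to \eqn{1 - \rho},
#' continuous ones to \eqn{-\rho}. Reflect observed estimates the same
#' way with [reflect_estimate()] before evaluating them against the
#' resulting design. An adjustment after a pause is still an improvement
#' (it lowers the parameter), so `tau_min`/`tau_max` keep their meaning.
#'
#' @inheritParams pilot_problem
#' @param rho0 Null ("poor") value, the *higher* of the two.
#' @param rho1 Alternative ("promising") value, below `rho0`.
#' @return A `stopgo_problem` in the standard orientation.
#' @examples
#' # dropout: 40% is poor, 20% promising
#' reflect_problem(rho0 = 0.4, rho1 = 0.2)
#' @export
reflect_problem <- function(rho0, rho1, rho_m = NULL,
                            alpha_star = 0.05, beta_star = 0.1, gamma_star = 1,
                            eta0 = 0.5, eta1 = eta0,
                            tau_min = 0, tau_max = tau_min,
                            endpoint = c("binary", "continuous"),
                            sigma = NULL) {
  endpoint <- match.arg(endpoint)
  if (rho0 <= rho1)
    stop("lower-is-better problems need rho0 > rho1 (null is the poor, high value)",
         call. = FALSE)
  f <- if (endpoint == "binary") function(r) 1 - r else function(r) -r
  pilot_problem(rho0 = f(rho0), rho1 = f(rho1),
                rho_m = if (is.null(rho_m)) NULL else f(rho_m),
                alpha_star = alpha_star, beta_star = beta_star,
                gamma_star = gamma_star, eta0 = eta0, eta1 = eta1,
                tau_min = tau_min, tau_max = tau_max,
                endpoint = endpoint, sigma = sigma)
}

#' @rdname reflect_problem
#' @param estimate Observed estimate (count scale for binary problems with
#'   `n` supplied, otherwise the raw estimate).
#' @param n Sample size (binary endpoints, count-scale reflection `n - x`).
#' @export
reflect_estimate <- function(estimate, n = NULL) {
  if (!is.null(n)) n - estimate else -estimate
}

#' Read or write a design problem as a flat configuration file
#'
#' The configuration is a flat key/value mapping (JSON or YAML, chosen by
#' file extension) whose keys are exactly the field names of
#' [pilot_problem()]. Writing then reading a problem returns an identical
#' bundle.
#'
#' @param path File path; `.json` uses JSON, anything else is parsed as YAML.
#' @return `read_problem()` returns a validated `stopgo_problem`;
#'   `write_problem()` invisibly returns `path`.
#' @examples
#' p <- pilot_problem(0.5, 0.7)
#' f <- tempfile(fileext = ".json")
#' write_problem(p, f)
#' identical(read_problem(f), p)
#' @export
read_problem <- function(path) {
  cfg <- read_config(path)
  problem_from_config(cfg)
}

#' @rdname read_problem
#' @param problem A `stopgo_problem`.
#' @export
write_problem <- function(problem, path) {
  stopifnot(inherits(problem, "stopgo_problem"))
  fields <- problem[!vapply(problem, is.null, logical(1))]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path)
  }
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

# Build a validated problem from a flat named list, applying defaults for
# anything absent. Unknown keys that are not problem fields are ignored so
# the same config can carry run options (subcommand, seed, ...).
problem_from_config <- function(cfg) {
  need <- function(nm) {
    if (is.null(cfg[[nm]])) stop("config is missing required field: ", nm, call. = FALSE)
    cfg[[nm]]
  }
  grab <- function(nm, default) if (is.null(cfg[[nm]])) default else cfg[[nm]]
  tau_min <- grab("tau_min", 0)
  pilot_problem(rho0 = need("rho0"), rho1 = need("rho1"),
                rho_m = grab("rho_m", NULL),
                alpha_star = grab("alpha_star", 0.05),
                beta_star = grab("beta_star", 0.1),
                gamma_star = grab("gamma_star", 1),
                eta0 = grab("eta0", 0.5),
                eta1 = grab("eta1", grab("eta0", 0.5)),
                tau_min = tau_min,
                tau_max = grab("tau_max", tau_min),
                endpoint = grab("endpoint", "binary"),
                sigma = grab("sigma", NULL))
}
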