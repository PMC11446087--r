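#' Construct a stop/pause/go design
#'
#' A single-stage three-outcome design is a sample size `n` and two
#' thresholds `x0 <= x1` on the decision scale. The decision rule is:
#' stop (red) if the statistic is `<= x0`, pause (amber) if it lies in
#' `(x0, x1]`, go (green) if it is `> x1`.
#'
#' For binary endpoints the statistic is the success count
#' \eqn{X \sim Bin(n, \rho)} and the thresholds are integers with
#' `-1 <= x0 <= x1 <= n`; `x0 = -1` means the stop region is empty and
#' `x1 = n` that the direct-go region is empty. `x0 == x1` is a
#' two-outcome (stop/go) design. Thresholds may also be given as
#' proportion-scale fractions such as `"9/15"`, converted to the count
#' scale with an exactness check.
#'
#' For continuous endpoints the statistic is the sample mean and the
#' thresholds are reals on the same scale as \eqn{\rho} (`-Inf`/`Inf`
#' allowed for empty regions).
#'
#' @param n Positive integer sample size.
#' @param x0 Lower (stop) threshold.
#' @param x1 Upper (go) threshold; defaults to `x0` (two-outcome design).
#' @param endpoint `"binary"` or `"continuous"`.
#' @return An object of class `stopgo_design` with fields `n`, `x0`, `x1`,
#'   `endpoint`.
#' @examples
#' three_outcome_design(30, 15, 20)
#' three_outcome_design(15, "9/15")        # count 9 out of 15
#' three_outcome_design(40, 0.55, 0.62, endpoint = "continuous")
#' @export
three_outcome_design <- function(n, x0, x1 = x0,
                                 endpoint = c("binary", "continuous")) {
  endpoint <- match.arg(endpoint)
  chk_num(n, "n")
  if (n < 1 || n != as.integer(n)) stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (endpoint == "binary") {
    x0 <- as_count(x0, n, "x0")
    x1 <- as_count(x1, n, "x1")
    if (x0 < -1L || x1 > n) stop("need -1 <= x0 and x1 <= n", call. = FALSE)
  } else {
    chk_num(x0, "x0"); chk_num(x1, "x1")
  }
  if (x0 > x1) stop("x0 <= x1 required", call. = FALSE)
  structure(list(n = n, x0 = x0, x1 = x1, endpoint = endpoint),
            class = "stopgo_design")
}

# Parse a binary threshold: integer count, or fraction string "a/b" on the
# proportion scale, converted by x = n * a/b and required to be integral to
# within 1e-9.
as_count <- function(x, n, nm) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop(nm, ": fractions must look like \"9/15\"", call. = FALSE)
    x <- n * as.numeric(parts[1]) / as.numeric(parts[2])
  }
  chk_num(x, nm)
  if (abs(x - round(x)) > 1e-9)
    stop(nm, " must be an integer on the count scale (got ", format(x), ")",
         call. = FALSE)
  as.integer(round(x))
}

#' @export
print.stopgo_design <- function(x, ...) {
  two <- isTRUE(x$x0 == x$x1)
  cat(sprintf("%s %s design: n = %d\n",
              if (two) "Two-outcome" else "Three-outcome", x$endpoint, x$n))
  fmt <- if (x$endpoint == "binary") "%d" else "%g"
  cat(sprintf(paste0("  stop  (red)  : estimate <= ", fmt, "\n"), x$x0))
  if (!two)
    cat(sprintf(paste0("  pause (amber): ", fmt, " < estimate <= ", fmt, "\n"),
                x$x0, x$x1))
  cat(sprintf(paste0("  go    (green): estimate > ", fmt, "\n"), x$x1))
  invisible(x)
}
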