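#' Bimodal payoff scheme for competing risk strategies
#'
#' A payoff scheme describes one round of the evolutionary game: risk-averse
#' individuals receive a constant payoff per decision event, while risk-prone
#' individuals receive either a high or a low payoff, drawn independently for
#' every event. All schemes studied in practice are *mean-matched*: the
#' expected per-event payoff of the risk-prone strategy equals the risk-averse
#' payoff, so the two strategies differ only in variance (and, for asymmetric
#' schemes, in the shape of the payoff distribution).
#'
#' @param low Risk-prone low outcome, in payoff units. Must satisfy
#'   `low <= high`.
#' @param high Risk-prone high outcome.
#' @param risk_averse Constant per-event payoff of the risk-averse strategy
#'   (10 in all standard scenarios).
#' @param p_high Probability of the high outcome per event, in `[0, 1]`. If
#'   `NULL` (the default), it is solved from the equal-mean constraint as
#'   `(risk_averse - low) / (high - low)`, so the scheme is mean-matched by
#'   construction.
#' @param events Number of decision events per lifetime, a positive integer.
#'   Accumulated lifetime payoff is the sum over events.
#' @param mean_match_tol Tolerance used to decide whether the scheme is
#'   mean-matched; a scheme that is not triggers a warning (not an error).
#'
#' @return An object of class `payoff_scheme`: a list with elements `low`,
#'   `high`, `risk_averse`, `p_high` and `events`.
#'
#' @examples
#' s <- payoff_scheme(5, 15)           # the symmetric 5-10-15 scheme
#' mean(s)                             # 10, matched to the risk-averse payoff
#' scheme_variance(s)                  # 25
#' payoff_scheme(5, 500, risk_averse = 10)$p_high  # 5/495, solved from the mean
#' @seealso [scheme_from_moments()], [parse_scheme_string()]
#' @export
payoff_scheme <- function(low, high, risk_averse = 10, p_high = NULL,
                          events = 1L, mean_match_tol = 1e-6) {
  stopifnot(is.numeric(low), is.numeric(high), is.numeric(risk_averse),
            length(low) == 1L, length(high) == 1L, length(risk_averse) == 1L,
            is.finite(low), is.finite(high), is.finite(risk_averse))
  if (low > high)
    stop("'low' must not exceed 'high'")
  if (is.null(p_high)) {
    if (high == low) {
      p_high <- 0.5
      if (abs(low - risk_averse) >= mean_match_tol)
        warning("degenerate scheme (low == high) cannot be mean-matched; p_high set to 0.5")
    } else {
      p_high <- (risk_averse - low) / (high - low)
      if (p_high < 0 || p_high > 1)
        stop("risk-averse payoff outside [low, high]; cannot solve a mean-matching p_high")
    }
  }
  stopifnot(length(p_high) == 1L, is.finite(p_high))
  if (p_high < 0 || p_high > 1)
    stop("'p_high' must lie in [0, 1]")
  events <- as.integer(events)
  if (is.na(events) || events < 1L)
    stop("'events' must be a positive integer")
  s <- structure(list(low = as.double(low), high = as.double(high),
                      risk_averse = as.double(risk_averse),
                      p_high = as.double(p_high), events = events),
                 class = "payoff_scheme")
  if (abs(mean(s) - risk_averse) >= mean_match_tol)
    warning(sprintf(
      "scheme is not mean-matched: risk-prone mean %.6g != risk-averse payoff %.6g",
      mean(s), risk_averse))
  s
}

#' Expected per-event payoff of the risk-prone strategy
#'
#' @param x A [payoff_scheme()].
#' @param ... Unused.
#' @return `p_high * high + (1 - p_high) * low`.
#' @export
mean.payoff_scheme <- function(x, ...) {
  x$p_high * x$high + (1 - x$p_high) * x$low
}

#' Per-event payoff variance of the risk-prone strategy
#'
#' @param scheme A [payoff_scheme()].
#' @return The variance of the two-point per-event payoff distribution. The
#'   accumulated lifetime payoff over `E` independent events has variance
#'   `E * scheme_variance(scheme)`.
#' @export
scheme_variance <- function(scheme) {
  stopifnot(inherits(scheme, "payoff_scheme"))
  m <- mean(scheme)
  scheme$p_high * (scheme$high - m)^2 + (1 - scheme$p_high) * (scheme$low - m)^2
}

#' Is a scheme mean-matched to the risk-averse payoff?
#'
#' @param scheme A [payoff_scheme()].
#' @param tol Absolute tolerance on the difference of means.
#' @return `TRUE` if the risk-prone mean equals the risk-averse payoff to
#'   within `tol`.
#' @export
is_mean_matched <- function(scheme, tol = 1e-6) {
  stopifnot(inherits(scheme, "payoff_scheme"))
  abs(mean(scheme) - scheme$risk_averse) < tol
}

#' Construct a payoff scheme from its first two moments
#'
#' Solves for the two-point risk-prone distribution with a given high-outcome
#' probability, mean and variance. This is how the asymmetric
#' constant-variance schemes are built: for every `p_high` in
#' `{0.1, ..., 0.8}` the payoffs are adjusted so that the mean stays at the
#' risk-averse payoff and the variance stays at its baseline value. The closed
#' form is
#' `high = mean + sqrt(variance * (1 - p_high) / p_high)` and
#' `low  = mean - sqrt(variance * p_high / (1 - p_high))`,
#' which reproduces the input moments exactly.
#'
#' @param p_high Probability of the high outcome, strictly inside `(0, 1)`
#'   unless `variance` is zero.
#' @param mean Target mean of the per-event risk-prone payoff.
#' @param variance Target variance (nonnegative).
#' @param risk_averse Constant risk-averse payoff; defaults to `mean`, i.e., a
#'   mean-matched scheme.
#' @param events Number of decision events per lifetime.
#' @return A [payoff_scheme()].
#' @examples
#' scheme_from_moments(0.5, 10, 25)   # the 5-10-15 scheme
#' scheme_from_moments(0.1, 10, 25)   # the 8.333-10-25 scheme
#' @export
scheme_from_moments <- function(p_high, mean, variance, risk_averse = mean,
                                events = 1L) {
  stopifnot(length(p_high) == 1L, length(mean) == 1L, length(variance) == 1L,
            is.finite(p_high), is.finite(mean), is.finite(variance))
  if (variance < 0)
    stop("'variance' must be nonnegative")
  if (p_high <= 0 || p_high >= 1) {
    if (variance > 0)
      stop("degenerate distribution: p_high in {0, 1} is incompatible with positive variance")
    return(payoff_scheme(mean, mean, risk_averse, p_high = 0.5, events = events))
  }
  high <- mean + sqrt(variance * (1 - p_high) / p_high)
  low <- mean - sqrt(variance * p_high / (1 - p_high))
  # snap rounding residue to an exact zero payoff (e.g. p_high = 0.8 with
  # mean 10, variance 25 has low = 0 analytically)
  tol0 <- 1e-9 * max(1, abs(mean))
  if (abs(low) < tol0) low <- 0
  if (abs(high) < tol0) high <- 0
  payoff_scheme(low, high, risk_averse, p_high = p_high, events = events)
}

#' Parse a "low-riskaverse-high" shorthand scheme string
#'
#' Schemes are conventionally written as `"L-M-H"`: risk-prone low payoff `L`,
#' risk-averse constant payoff `M`, risk-prone high payoff `H`. Unless given
#' explicitly, `p_high` is solved from the equal-mean constraint, so
#' `"5-10-15"` yields `p_high = 0.5` and `"5-10-500"` yields `p_high = 5/495`.
#'
#' @param x A string such as `"5-10-15"`.
#' @param p_high Optional explicit high-outcome probability; default solves
#'   the mean-matching value.
#' @param events Number of decision events per lifetime.
#' @return A [payoff_scheme()].
#' @export
parse_scheme_string <- function(x, p_high = NULL, events = 1L) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- suppressWarnings(as.numeric(strsplit(trimws(x), "-", fixed = TRUE)[[1L]]))
  if (length(parts) != 3L || anyNA(parts))
    stop("scheme string must have the form \"low-riskaverse-high\", e.g. \"5-10-15\"")
  payoff_scheme(parts[1L], parts[3L], risk_averse = parts[2L],
                p_high = p_high, events = events)
}

#' @export
print.payoff_scheme <- function(x, ...) {
  cat(sprintf("Payoff scheme %g-%g-%g (low-riskaverse-high)\n",
              x$low, x$risk_averse, x$high))
  cat(sprintf("  P(high) = %.6g, events per lifetime = %d\n", x$p_high, x$events))
  cat(sprintf("  risk-prone mean = %.6g, variance = %.6g%s\n",
              mean(x), scheme_variance(x),
              if (is_mean_matched(x)) " (mean-matched)" else " (NOT mean-matched)"))
  invisible(x)
}
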