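#' Sample one individual's accumulated lifetime payoff
#'
#' A risk-averse individual deterministically accumulates
#' `events * risk_averse`; a risk-prone individual accumulates the sum of
#' `events` independent draws, each equal to `high` with probability `p_high`
#' and `low` otherwise. Randomness comes from R's global random number
#' stream, so results are reproducible under [set.seed()].
#'
#' @param strategy `"risk_averse"` or `"risk_prone"`.
#' @param scheme A [payoff_scheme()].
#' @return A single accumulated payoff.
#' @examples
#' set.seed(1)
#' sample_lifetime_payoff("risk_averse", payoff_scheme(5, 15))  # always 10
#' sample_lifetime_payoff("risk_prone", payoff_scheme(5, 15))   # 5 or 15
#' @export
sample_lifetime_payoff <- function(strategy = c("risk_averse", "risk_prone"),
                                   scheme) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(scheme, "payoff_scheme"))
  if (strategy == "risk_averse")
    return(scheme$events * scheme$risk_averse)
  h <- stats::rbinom(1L, scheme$events, scheme$p_high)
  h * scheme$high + (scheme$events - h) * scheme$low
}

#' Sample accumulated payoffs for a whole generation
#'
#' Draws the lifetime payoff of every individual in the current population
#' state: the `k_risk_prone` risk-prone individuals get iid lifetime sums and
#' the remaining individuals get the deterministic risk-averse total.
#' Individuals within a strategy are exchangeable, so risk-prone individuals
#' are listed first by convention.
#'
#' @param state A [population_state()].
#' @param scheme A [payoff_scheme()].
#' @return A data frame with one row per individual and columns `strategy`
#'   (`"risk_prone"` or `"risk_averse"`) and `payoff`.
#' @export
sample_population_payoffs <- function(state, scheme) {
  stopifnot(inherits(state, "population_state"),
            inherits(scheme, "payoff_scheme"))
  k <- state$k_risk_prone
  n_ra <- state$N - k
  h <- if (k > 0L) stats::rbinom(k, scheme$events, scheme$p_high) else integer()
  rp <- h * scheme$high + (scheme$events - h) * scheme$low
  data.frame(
    strategy = rep(c("risk_prone", "risk_averse"), c(k, n_ra)),
    payoff = c(rp, rep(scheme$events * scheme$risk_averse, n_ra))
  )
}
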