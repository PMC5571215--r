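#' Reproduction weights under proportional selection
#'
#' Each individual's probability of parenting a given offspring is its
#' accumulated payoff divided by the population total, so with payoffs
#' `(10, 5)` the first individual parents each offspring with probability
#' `10 / (10 + 5)`.
#'
#' @param payoffs Vector of accumulated payoffs, nonnegative with a positive
#'   total (a zero payoff simply means no chance of parenthood; the low
#'   payoff of the mean-10/variance-25 scheme at `p_high = 0.8` is exactly 0).
#' @return A weight vector: nonnegative, summing to 1.
#' @export
proportional_weights <- function(payoffs) {
  .check_payoffs(payoffs)
  if (any(payoffs < 0) || sum(payoffs) <= 0)
    stop("proportional selection requires nonnegative payoffs with a positive total")
  payoffs / sum(payoffs)
}

#' Reproduction weights under power-weighted selection
#'
#' Weight proportional to `payoff^z`. `z = 1` is identical to
#' [proportional_weights()]; `z = 0` gives uniform weights; `z > 1` makes the
#' payoff-to-fitness mapping convex, `z < 1` concave.
#'
#' @param payoffs Vector of accumulated payoffs, nonnegative with a positive
#'   total.
#' @param z Nonnegative exponent.
#' @inherit proportional_weights return
#' @export
power_weights <- function(payoffs, z) {
  .check_payoffs(payoffs)
  stopifnot(length(z) == 1L, is.finite(z), z >= 0)
  if (z == 1) return(proportional_weights(payoffs))
  if (z == 0) return(rep(1 / length(payoffs), length(payoffs)))
  if (any(payoffs < 0) || sum(payoffs) <= 0)
    stop("power-weighted selection requires nonnegative payoffs with a positive total")
  w <- payoffs^z
  w / sum(w)
}

#' Reproduction weights under rank-based truncation selection
#'
#' Exactly `k = max(1, round(threshold * N))` individuals — those with the
#' highest accumulated payoffs — are eligible to reproduce, each with weight
#' `1/k`; everyone else gets weight 0. Eligibility depends only on payoff
#' rank, not on the payoff value, so all eligible individuals are weighted
#' equally. Ties spanning the cutoff rank are resolved uniformly at random
#' among the tied individuals (via an iid uniform jitter key), which keeps the
#' eligibility distribution permutation-equivariant and unbiased.
#'
#' @param payoffs Vector of accumulated payoffs.
#' @param threshold Top fraction allowed to reproduce, in `(0, 1]`.
#' @inherit proportional_weights return
#' @export
truncation_rank_weights <- function(payoffs, threshold) {
  .check_payoffs(payoffs)
  stopifnot(length(threshold) == 1L, is.finite(threshold))
  if (threshold <= 0 || threshold > 1)
    stop("'threshold' must lie in (0, 1]")
  n <- length(payoffs)
  k <- max(1L, as.integer(floor(threshold * n + 0.5)))  # round half up
  o <- order(-payoffs, stats::runif(n))
  w <- numeric(n)
  w[o[seq_len(k)]] <- 1 / k
  w
}

#' Reproduction weights under absolute-threshold truncation selection
#'
#' All individuals whose accumulated payoff reaches the fixed cutoff
#' reproduce with equal weight; the rest get weight 0. Unlike rank-based
#' truncation, the number of parents varies from generation to generation and
#' can be zero, in which case an error of class `empty_parent_set` is
#' signalled (the engine exposes a policy for this case, see
#' [experiment_config()]).
#'
#' @param payoffs Vector of accumulated payoffs.
#' @param cutoff Finite payoff cutoff.
#' @inherit proportional_weights return
#' @export
truncation_absolute_weights <- function(payoffs, cutoff) {
  .check_payoffs(payoffs)
  stopifnot(length(cutoff) == 1L, is.finite(cutoff))
  ok <- payoffs >= cutoff
  m <- sum(ok)
  if (m == 0L)
    stop(errorCondition(
      "no individual reaches the absolute truncation cutoff: empty parent set",
      class = "empty_parent_set"))
  w <- numeric(length(payoffs))
  w[ok] <- 1 / m
  w
}

#' Reproduction weights under sigmoid-weighted selection
#'
#' Payoffs are first normalized by the generation's maximum, so the
#' best-scoring individual has normalized payoff `p_n = 1` (the normalization
#' is recomputed every generation from the realized maximum). Each individual
#' is then weighted by the logistic transform
#' `1 / (1 + exp(-steepness * (p_n - inflection)))`, normalized to sum to 1.
#' Unlike rank-based truncation, the weight depends only on the payoff value,
#' not on the individual's rank.
#'
#' @param payoffs Vector of accumulated payoffs; the maximum must be positive.
#' @param steepness Positive logistic steepness.
#' @param inflection Inflection point on the normalized payoff scale.
#' @inherit proportional_weights return
#' @export
sigmoid_weights <- function(payoffs, steepness, inflection) {
  .check_payoffs(payoffs)
  stopifnot(length(steepness) == 1L, steepness > 0,
            length(inflection) == 1L, is.finite(inflection))
  m <- max(payoffs)
  if (m <= 0)
    stop("sigmoid-weighted selection requires a positive maximum payoff")
  tr <- stats::plogis(steepness * (payoffs / m - inflection))
  tr / sum(tr)
}

#' Reproduction weights for any selection scheme
#'
#' Dispatches on the scheme kind to the corresponding weight function.
#'
#' @param payoffs Vector of accumulated payoffs.
#' @param selection A [selection_scheme].
#' @inherit proportional_weights return
#' @export
reproduction_weights <- function(payoffs, selection) {
  stopifnot(inherits(selection, "selection_scheme"))
  switch(selection$kind,
    proportional = proportional_weights(payoffs),
    truncation_rank = truncation_rank_weights(payoffs, selection$threshold),
    truncation_absolute = truncation_absolute_weights(payoffs, selection$cutoff),
    power = power_weights(payoffs, selection$z),
    sigmoid = sigmoid_weights(payoffs, selection$steepness,
                              selection$inflection),
    stop("unknown selection scheme kind: ", selection$kind))
}

.check_payoffs <- function(payoffs) {
  if (!is.numeric(payoffs) || length(payoffs) == 0L || anyNA(payoffs) ||
      any(!is.finite(payoffs)))
    stop("'payoffs' must be a nonempty numeric vector of finite values")
  invisible(TRUE)
}
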