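#' Exact transition matrix of the fixation Markov chain (small populations)
#'
#' For small `N` and a single decision event per lifetime, the generational
#' dynamics can be enumerated exactly: given `k` risk-prone individuals, the
#' number receiving the high payoff is `Binomial(k, p_high)`; for each
#' realization the weight vector is computed from an explicit payoff vector
#' via the same weight functions the simulator exposes (rank-based truncation
#' ties are averaged analytically by hypergeometric allocation of the
#' boundary slots, so the oracle is free of Monte Carlo noise); and the next
#' risk-prone count is `Binomial(N, total risk-prone weight)`. Transition
#' rows are the mixture over payoff realizations (and tie-breaks). States
#' `k = 0` and `k = N` are absorbing.
#'
#' The oracle serves as a brute-force verification target for the stochastic
#' engine: simulated fixation proportions must agree with
#' [fixation_probability()] within binomial sampling error.
#'
#' @param N Population size, at most `max_N` (enumeration bound).
#' @param scheme A [payoff_scheme()] with `events = 1`.
#' @param selection A [selection_scheme].
#' @param empty_parent_policy For absolute-threshold truncation only:
#'   `"error"` aborts when a payoff realization leaves no eligible parent;
#'   `"uniform"` assigns uniform parenthood in that realization.
#' @param max_N Enumeration bound on `N` (default 12).
#' @return An object of class `transition_model` with elements `N`, `scheme`,
#'   `selection`, and the `(N+1) x (N+1)` row-stochastic matrix `P` over
#'   states `k = 0, ..., N`.
#' @examples
#' tm <- transition_matrix(2, payoff_scheme(5, 15), selection_proportional())
#' tm$P[2, ]  # mixture over the two payoff realizations of the risk-prone player
#' @export
transition_matrix <- function(N, scheme, selection,
                              empty_parent_policy = c("error", "uniform"),
                              max_N = 12L) {
  stopifnot(inherits(scheme, "payoff_scheme"),
            inherits(selection, "selection_scheme"))
  empty_parent_policy <- match.arg(empty_parent_policy)
  N <- as.integer(N)
  if (is.na(N) || N < 2L) stop("'N' must be an integer >= 2")
  if (N > max_N)
    stop(sprintf("exact enumeration supports N <= %d; use simulation for larger N", max_N))
  if (scheme$events != 1L)
    stop("exact enumeration requires a single event per lifetime (events = 1)")
  P <- matrix(0, N + 1L, N + 1L,
              dimnames = list(paste0("k", 0:N), paste0("k", 0:N)))
  P[1L, 1L] <- 1
  P[N + 1L, N + 1L] <- 1
  js <- 0:N
  for (k in seq_len(N - 1L)) {
    row <- numeric(N + 1L)
    for (h in 0:k) {
      p_h <- stats::dbinom(h, k, scheme$p_high)
      if (p_h == 0) next
      Wd <- .exact_rp_weight_dist(N, k, h, scheme, selection,
                                  empty_parent_policy)
      for (i in seq_len(nrow(Wd)))
        row <- row + p_h * Wd$prob[i] * stats::dbinom(js, N, Wd$W[i])
    }
    P[k + 1L, ] <- row
  }
  structure(list(N = N, scheme = scheme, selection = selection, P = P),
            class = "transition_model")
}

# Distribution of the total risk-prone reproduction weight for a fixed payoff
# realization (h of the k risk-prone individuals drew the high payoff).
# Deterministic schemes give a single atom; rank-based truncation can give
# several when the eligibility cutoff falls inside a tied group.
.exact_rp_weight_dist <- function(N, k, h, scheme, selection,
                                  empty_parent_policy) {
  low <- scheme$low; high <- scheme$high; ra <- scheme$risk_averse
  payoffs <- c(rep(high, h), rep(low, k - h), rep(ra, N - k))
  is_rp <- c(rep(TRUE, k), rep(FALSE, N - k))
  kind <- selection$kind
  if (kind == "truncation_rank") {
    k_el <- max(1L, as.integer(floor(selection$threshold * N + 0.5)))
    # group individuals by payoff value, descending
    vv <- sort(unique(payoffs), decreasing = TRUE)
    crp <- vapply(vv, function(v) sum(is_rp & payoffs == v), 1)
    cra <- vapply(vv, function(v) sum(!is_rp & payoffs == v), 1)
    tot <- crp + cra
    cum <- cumsum(tot)
    g <- which(cum >= k_el)[1L]
    prev <- if (g > 1L) cum[g - 1L] else 0
    slots <- k_el - prev
    strict_rp <- if (g > 1L) sum(crp[seq_len(g - 1L)]) else 0
    if (slots == tot[g] || crp[g] == 0 || cra[g] == 0) {
      m <- if (slots == tot[g]) crp[g] else if (cra[g] == 0) slots else 0
      return(data.frame(W = (strict_rp + m) / k_el, prob = 1))
    }
    m <- 0:min(slots, crp[g])
    return(data.frame(W = (strict_rp + m) / k_el,
                      prob = stats::dhyper(m, crp[g], cra[g], slots)))
  }
  if (kind == "truncation_absolute") {
    w <- tryCatch(truncation_absolute_weights(payoffs, selection$cutoff),
                  empty_parent_set = function(e) {
                    if (empty_parent_policy == "uniform") rep(1 / N, N)
                    else stop(e)
                  })
    return(data.frame(W = sum(w[is_rp]), prob = 1))
  }
  w <- switch(kind,
    proportional = proportional_weights(payoffs),
    power = power_weights(payoffs, selection$z),
    sigmoid = sigmoid_weights(payoffs, selection$steepness,
                              selection$inflection),
    stop("unknown selection scheme kind: ", kind))
  data.frame(W = sum(w[is_rp]), prob = 1)
}

#' Exact fixation probability of the risk-prone strategy
#'
#' Solves the absorbing-chain linear system for absorption at `k = N`: with
#' `u(k)` the probability that risk-prone fixes from `k` risk-prone
#' individuals, `u(0) = 0`, `u(N) = 1`, and for interior states
#' `(I - Q) u = b`, where `Q` is the interior block of the transition matrix
#' and `b` the one-step absorption probabilities into `k = N`.
#'
#' @param model A [transition_matrix()] result.
#' @param initial_k Initial number of risk-prone individuals (may be a
#'   vector).
#' @return Probability (or vector of probabilities) that the risk-prone
#'   strategy fixes.
#' @examples
#' tm <- transition_matrix(2, payoff_scheme(5, 15), selection_proportional())
#' fixation_probability(tm, 1)  # 53/121: risk-averse is favored
#' @export
fixation_probability <- function(model, initial_k) {
  stopifnot(inherits(model, "transition_model"))
  N <- model$N
  initial_k <- as.integer(initial_k)
  stopifnot(all(initial_k >= 0L), all(initial_k <= N))
  interior <- 2:N  # matrix rows for k = 1 .. N-1
  Q <- model$P[interior, interior, drop = FALSE]
  b <- model$P[interior, N + 1L]
  u_int <- solve(diag(N - 1L) - Q, b)
  u <- c(0, u_int, 1)
  unname(u[initial_k + 1L])
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Exact transition model: N = %d, selection = %s\n",
              x$N, x$selection$kind))
  cat(sprintf("  scheme %g-%g-%g, P(high) = %.4g\n", x$scheme$low,
              x$scheme$risk_averse, x$scheme$high, x$scheme$p_high))
  cat(sprintf("  risk-prone fixation from k = %d: %.6f\n", x$N %/% 2L,
              fixation_probability(x, x$N %/% 2L)))
  invisible(x)
}
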