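# Shared fixtures: standard schemes and a naive per-individual reference
# engine used to verify the grouped fast core.

scheme_515 <- function(events = 1L) payoff_scheme(5, 15, events = events)

all_selection_schemes <- function() {
  list(
    proportional = selection_proportional(),
    truncation_rank = selection_truncation(0.5),
    truncation_absolute = selection_truncation_absolute(10),
    power = selection_power(1.26),
    sigmoid = selection_sigmoid(10, 2 / 3)
  )
}

# Naive reference dynamics: explicit per-individual payoffs, explicit parent
# draws from the full weight vector. Distributionally equivalent to the
# exchangeability-based core in run_to_fixation, but shares none of its code
# path beyond the exported weight functions.
naive_run_to_fixation <- function(scheme, selection, N, initial_k, seed,
                                  max_generations = 1e5) {
  set.seed(seed)
  strategy <- rep(c("risk_prone", "risk_averse"), c(initial_k, N - initial_k))
  gen <- 0L
  while (any(strategy == "risk_prone") && any(strategy == "risk_averse")) {
    if (gen >= max_generations) stop("naive reference did not fix")
    payoffs <- vapply(strategy, function(s) sample_lifetime_payoff(s, scheme),
                      numeric(1))
    w <- reproduction_weights(payoffs, selection)
    parents <- sample.int(N, N, replace = TRUE, prob = w)
    strategy <- strategy[parents]
    gen <- gen + 1L
  }
  list(fixed_strategy = strategy[1L], generations = gen)
}

naive_fixation_proportion <- function(scheme, selection, N, initial_k,
                                      replicates, base_seed) {
  fixed <- vapply(seq_len(replicates), function(r) {
    naive_run_to_fixation(scheme, selection, N, initial_k,
                          spawn_seed(base_seed, r))$fixed_strategy
  }, character(1))
  mean(fixed == "risk_prone")
}

# Risk-prone fixation proportion from the package engine.
engine_fixation_proportion <- function(scheme, selection, N, replicates,
                                       base_seed, initial_k = NULL) {
  cfg <- experiment_config(scheme, selection, N, initial_k = initial_k,
                           replicates = replicates, base_seed = base_seed)
  res <- run_replicates(cfg)
  mean(res$fixed_strategy == "risk_prone")
}

# Three-binomial-SE band around a target proportion.
band3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
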