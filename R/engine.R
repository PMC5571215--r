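#' Population state of the two-strategy competition
#'
#' The population is haploid, of constant size `N`, with non-overlapping
#' generations and no mutation or migration: offspring inherit the parental
#' strategy exactly, so the state of the process is fully summarized by the
#' number of risk-prone individuals `k` (individuals are exchangeable within
#' a strategy).
#'
#' @param N Population size, a positive integer.
#' @param k_risk_prone Number of risk-prone individuals, in `[0, N]`.
#' @param generation Nonnegative generation index.
#' @return An object of class `population_state`.
#' @export
population_state <- function(N, k_risk_prone, generation = 0L) {
  N <- as.integer(N); k <- as.integer(k_risk_prone)
  generation <- as.integer(generation)
  stopifnot(!is.na(N), N >= 1L, !is.na(k), k >= 0L, k <= N,
            !is.na(generation), generation >= 0L)
  structure(list(N = N, k_risk_prone = k, generation = generation),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population: N = %d, risk-prone = %d, risk-averse = %d (generation %d)\n",
              x$N, x$k_risk_prone, x$N - x$k_risk_prone, x$generation))
  invisible(x)
}

#' Configuration of a fixation experiment
#'
#' Bundles a payoff scheme, a selection scheme, the population size and
#' initial composition, and replicate/seed bookkeeping. Runs start from a
#' 50/50 population by default (`floor(N/2)` risk-prone individuals when `N`
#' is odd) and continue until one strategy fixes.
#'
#' @param scheme A [payoff_scheme()].
#' @param selection A [selection_scheme].
#' @param N Population size.
#' @param initial_k Initial number of risk-prone individuals; default
#'   `floor(N/2)`.
#' @param replicates Number of independent replicate runs for
#'   [run_replicates()].
#' @param base_seed Integer seed from which each replicate's seed is derived
#'   deterministically.
#' @param max_generations Guard on run length; fixation is almost sure under
#'   every valid scheme, so exceeding the guard signals a configuration error.
#' @param empty_parent_policy What to do when absolute-threshold truncation
#'   leaves no eligible parent: `"error"` (abort the run) or `"uniform"`
#'   (fall back to uniform parenthood for that generation).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scheme, selection, N, initial_k = NULL,
                              replicates = 2000L, base_seed = 1L,
                              max_generations = 1e6,
                              empty_parent_policy = c("error", "uniform")) {
  stopifnot(inherits(scheme, "payoff_scheme"),
            inherits(selection, "selection_scheme"))
  N <- as.integer(N)
  stopifnot(!is.na(N), N >= 2L)
  if (is.null(initial_k)) initial_k <- N %/% 2L
  initial_k <- as.integer(initial_k)
  stopifnot(!is.na(initial_k), initial_k >= 0L, initial_k <= N)
  replicates <- as.integer(replicates)
  stopifnot(!is.na(replicates), replicates >= 1L)
  structure(list(scheme = scheme, selection = selection, N = N,
                 initial_k = initial_k, replicates = replicates,
                 base_seed = as.integer(base_seed),
                 max_generations = as.double(max_generations),
                 empty_parent_policy = match.arg(empty_parent_policy)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("Experiment: N = %d, initial risk-prone = %d, replicates = %d, base seed = %d\n",
              x$N, x$initial_k, x$replicates, x$base_seed))
  print(x$scheme); print(x$selection)
  invisible(x)
}

#' Advance the population by one generation
#'
#' One generation consists of (i) sampling every individual's accumulated
#' lifetime payoff, (ii) mapping payoffs to reproduction weights under the
#' selection scheme, and (iii) replacing the whole population with `N` new
#' individuals whose parents are drawn independently from the weight vector
#' (a single parent may produce multiple offspring). Offspring inherit the
#' parental strategy exactly. Uses R's global random number stream.
#'
#' @param state A non-absorbed [population_state()] (`0 < k < N`).
#' @param scheme A [payoff_scheme()].
#' @param selection A [selection_scheme].
#' @param empty_parent_policy See [experiment_config()].
#' @return The next [population_state()].
#' @export
step_generation <- function(state, scheme, selection,
                            empty_parent_policy = c("error", "uniform")) {
  stopifnot(inherits(state, "population_state"))
  empty_parent_policy <- match.arg(empty_parent_policy)
  k <- state$k_risk_prone; N <- state$N
  if (k <= 0L || k >= N)
    stop("population is already fixed; step_generation requires 0 < k < N")
  pp <- sample_population_payoffs(state, scheme)
  w <- tryCatch(reproduction_weights(pp$payoff, selection),
                empty_parent_set = function(e) {
                  if (empty_parent_policy == "uniform") rep(1 / N, N)
                  else stop(e)
                })
  parents <- sample.int(N, N, replace = TRUE, prob = w)
  k_next <- sum(pp$strategy[parents] == "risk_prone")
  population_state(N, k_next, state$generation + 1L)
}

#' Run a single replicate to fixation
#'
#' Iterates generations from the configured initial composition until the
#' population is absorbed at all-risk-prone (`k = N`) or all-risk-averse
#' (`k = 0`). The run is seeded explicitly, so identical `(config, seed)`
#' pairs give bit-identical results; the caller's random number stream is
#' left untouched.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed for this run.
#' @return An object of class `run_result`: a list with `fixed_strategy`
#'   (`"risk_prone"` or `"risk_averse"`), `generations_to_fixation`, and
#'   `seed`.
#' @export
run_to_fixation <- function(config, seed) {
  stopifnot(inherits(config, "experiment_config"))
  seed <- as.integer(seed)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  res <- .run_core(config$N, config$initial_k, config$scheme,
                   config$selection, config$max_generations,
                   config$empty_parent_policy)
  structure(list(
    fixed_strategy = if (res$k == config$N) "risk_prone" else "risk_averse",
    generations_to_fixation = res$generations,
    seed = seed), class = "run_result")
}

#' Run independent replicates to fixation
#'
#' Replicate `r` is run with seed `spawn_seed(base_seed, r)`, so the full set
#' of results is a deterministic function of the configuration and
#' `base_seed`, independent of execution order.
#'
#' @param config An [experiment_config()].
#' @return A data frame with one row per replicate and columns `replicate`,
#'   `seed`, `fixed_strategy`, `generations`.
#' @examples
#' cfg <- experiment_config(payoff_scheme(5, 15), selection_proportional(),
#'                          N = 10, replicates = 50, base_seed = 42)
#' res <- run_replicates(cfg)
#' table(res$fixed_strategy)
#' @export
run_replicates <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  R <- config$replicates
  seeds <- vapply(seq_len(R), function(r) spawn_seed(config$base_seed, r), 1L)
  fixed <- character(R)
  gens <- integer(R)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  N <- config$N
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    res <- .run_core(N, config$initial_k, config$scheme, config$selection,
                     config$max_generations, config$empty_parent_policy)
    fixed[r] <- if (res$k == N) "risk_prone" else "risk_averse"
    gens[r] <- res$generations
  }
  data.frame(replicate = seq_len(R), seed = seeds, fixed_strategy = fixed,
             generations = gens)
}

#' Derive a child seed from a base seed and an index
#'
#' A small Lehmer-style integer scramble that maps `(base_seed, index)` to a
#' seed in `[0, 2^31 - 2]`, used to give every replicate (and every cell of a
#' scenario grid) its own deterministic, decorrelated stream.
#'
#' @param base_seed Integer base seed.
#' @param index Nonnegative integer index.
#' @return An integer seed.
#' @export
spawn_seed <- function(base_seed, index) {
  m <- 2147483647
  x <- (abs(as.double(base_seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + abs(as.double(index))) %% m
  x <- (x * 69621) %% m
  as.integer(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.stop_nonfix <- function(gen) {
  stop(sprintf(
    "no fixation after %g generations; check the configuration (max_generations guard)",
    gen))
}

# Fast generational core. Individuals within a strategy are exchangeable, so
# a generation's payoffs are summarized by counts over the at most E + 2
# distinct accumulated-payoff values (j high draws out of E for risk-prone
# individuals, plus the deterministic risk-averse total). Under multinomial
# parenthood the next risk-prone count is Binomial(N, total risk-prone
# weight), so each generation costs O(E) regardless of N. Equivalence to the
# naive per-individual dynamics is checked in the test suite.
.run_core <- function(N, k, scheme, selection, max_generations,
                      empty_parent_policy = "error") {
  E <- scheme$events
  low <- scheme$low; high <- scheme$high; ph <- scheme$p_high
  raE <- scheme$risk_averse * E
  gen <- 0L
  kind <- selection$kind

  if (kind == "proportional") {
    if (low < 0 || raE <= 0)
      stop("proportional selection requires nonnegative payoffs with a positive total")
    # total risk-prone payoff is linear in the total number of high draws
    while (k > 0L && k < N) {
      if (gen >= max_generations) .stop_nonfix(gen)
      nh <- stats::rbinom(1L, k * E, ph)
      s_rp <- nh * high + (k * E - nh) * low
      k <- stats::rbinom(1L, N, s_rp / (s_rp + (N - k) * raE))
      gen <- gen + 1L
    }
  } else if (kind == "power") {
    z <- selection$z
    if (z == 1)
      return(.run_core(N, k, scheme, selection_proportional(),
                       max_generations, empty_parent_policy))
    if (z > 0 && (low < 0 || raE <= 0))
      stop("power-weighted selection requires nonnegative payoffs with a positive total")
    if (E == 1L) {
      lo_z <- low^z; hi_z <- high^z; ra_z <- raE^z
      while (k > 0L && k < N) {
        if (gen >= max_generations) .stop_nonfix(gen)
        h <- stats::rbinom(1L, k, ph)
        s_rp <- h * hi_z + (k - h) * lo_z
        k <- stats::rbinom(1L, N, s_rp / (s_rp + (N - k) * ra_z))
        gen <- gen + 1L
      }
    } else {
      v_z <- (low * E + (high - low) * (0:E))^z
      ra_z <- raE^z
      while (k > 0L && k < N) {
        if (gen >= max_generations) .stop_nonfix(gen)
        cnt <- tabulate(stats::rbinom(k, E, ph) + 1L, E + 1L)
        s_rp <- sum(cnt * v_z)
        k <- stats::rbinom(1L, N, s_rp / (s_rp + (N - k) * ra_z))
        gen <- gen + 1L
      }
    }
  } else if (kind == "sigmoid") {
    xi <- selection$steepness; beta <- selection$inflection
    if (E == 1L) {
      while (k > 0L && k < N) {
        if (gen >= max_generations) .stop_nonfix(gen)
        h <- stats::rbinom(1L, k, ph)
        m <- if (h > 0L) max(high, raE) else max(low, raE)
        t_lo <- 1 / (1 + exp(-xi * (low / m - beta)))
        t_hi <- 1 / (1 + exp(-xi * (high / m - beta)))
        t_ra <- 1 / (1 + exp(-xi * (raE / m - beta)))
        s_rp <- (k - h) * t_lo + h * t_hi
        k <- stats::rbinom(1L, N, s_rp / (s_rp + (N - k) * t_ra))
        gen <- gen + 1L
      }
    } else {
      vals <- low * E + (high - low) * (0:E)
      while (k > 0L && k < N) {
        if (gen >= max_generations) .stop_nonfix(gen)
        cnt <- tabulate(stats::rbinom(k, E, ph) + 1L, E + 1L)
        m <- max(vals[cnt > 0L], raE)
        tr <- 1 / (1 + exp(-xi * (vals / m - beta)))
        t_ra <- 1 / (1 + exp(-xi * (raE / m - beta)))
        s_rp <- sum(cnt * tr)
        k <- stats::rbinom(1L, N, s_rp / (s_rp + (N - k) * t_ra))
        gen <- gen + 1L
      }
    }
  } else if (kind == "truncation_rank") {
    k_el <- max(1L, as.integer(floor(selection$threshold * N + 0.5)))
    vals <- if (E == 1L) c(low, high) else low * E + (high - low) * (0:E)
    while (k > 0L && k < N) {
      if (gen >= max_generations) .stop_nonfix(gen)
      cnt <- if (E == 1L) {
        h <- stats::rbinom(1L, k, ph)
        c(k - h, h)
      } else {
        tabulate(stats::rbinom(k, E, ph) + 1L, E + 1L)
      }
      W <- .trunc_rank_rp_weight(vals, cnt, raE, N - k, k_el)
      k <- stats::rbinom(1L, N, W)
      gen <- gen + 1L
    }
  } else if (kind == "truncation_absolute") {
    cutoff <- selection$cutoff
    ra_ok <- raE >= cutoff
    vals <- if (E == 1L) c(low, high) else low * E + (high - low) * (0:E)
    ok <- vals >= cutoff
    while (k > 0L && k < N) {
      if (gen >= max_generations) .stop_nonfix(gen)
      cnt <- if (E == 1L) {
        h <- stats::rbinom(1L, k, ph)
        c(k - h, h)
      } else {
        tabulate(stats::rbinom(k, E, ph) + 1L, E + 1L)
      }
      n_rp <- sum(cnt[ok])
      n_ra <- if (ra_ok) N - k else 0L
      tot <- n_rp + n_ra
      if (tot == 0L) {
        if (empty_parent_policy == "uniform") {
          W <- k / N
        } else {
          stop(errorCondition(
            "no individual reaches the absolute truncation cutoff: empty parent set",
            class = "empty_parent_set"))
        }
      } else {
        W <- n_rp / tot
      }
      k <- stats::rbinom(1L, N, W)
      gen <- gen + 1L
    }
  } else {
    stop("unknown selection scheme kind: ", kind)
  }
  list(k = k, generations = gen)
}

# Total reproduction weight of the risk-prone strategy under rank-based
# truncation, for a generation summarized by payoff-value counts. Groups with
# equal payoff values across the two strategies are merged; if the eligibility
# cutoff falls inside a tied group, the number of risk-prone individuals among
# the remaining slots is drawn hypergeometrically (uniform tie-breaking).
.trunc_rank_rp_weight <- function(vals_rp, cnt_rp, ra_val, n_ra, k_el) {
  keep <- cnt_rp > 0L
  v <- vals_rp[keep]; crp <- as.double(cnt_rp[keep])
  if (anyDuplicated(v)) {  # zero-variance schemes collapse low and high
    uv <- unique(v)
    crp <- vapply(uv, function(x) sum(crp[v == x]), numeric(1))
    v <- uv
  }
  cra <- numeric(length(v))
  j <- which(v == ra_val)
  if (length(j)) {
    cra[j[1L]] <- n_ra
  } else {
    v <- c(v, ra_val); crp <- c(crp, 0); cra <- c(cra, n_ra)
  }
  o <- order(v, decreasing = TRUE)
  crp <- crp[o]; cra <- cra[o]
  tot <- crp + cra
  cum <- cumsum(tot)
  g <- which(cum >= k_el)[1L]
  prev <- if (g > 1L) cum[g - 1L] else 0
  slots <- k_el - prev
  strict_rp <- if (g > 1L) sum(crp[seq_len(g - 1L)]) else 0
  m <- if (slots == tot[g]) {
    crp[g]
  } else if (cra[g] == 0) {
    slots
  } else if (crp[g] == 0) {
    0
  } else {
    stats::rhyper(1L, crp[g], cra[g], slots)
  }
  (strict_rp + m) / k_el
}
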