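#' Predefined experimental scenarios
#'
#' The scenario registry bundles the standard study conditions: a payoff
#' scheme, a selection scheme, a population size and (for sweeps) a grid of
#' parameter values. Each registry cell is simulated with [run_replicates()]
#' and summarized with [summarize_fixation()].
#'
#' @return `list_scenarios()` returns a data frame with one row per scenario
#'   (name, description, default replicate count, number of grid cells).
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  reg <- .scenario_registry()
  data.frame(
    scenario = names(reg),
    description = vapply(reg, function(s) s$description, ""),
    default_replicates = vapply(reg, function(s) s$replicates, 1L),
    cells = vapply(reg, function(s) nrow(s$grid), 1L),
    row.names = NULL
  )
}

# Registry of study conditions. Replicate defaults: 5000 where that count is
# the stated convention for the scenario, otherwise 2000.
.scenario_registry <- function() {
  p_grid <- seq(0.1, 0.8, by = 0.1)
  base <- function(descr, reps, grid, build) {
    list(description = descr, replicates = as.integer(reps), grid = grid,
         build = build)
  }
  list(
    "proportional-one-decision" = base(
      "Proportional selection, scheme 5-10-15, one event, across population sizes",
      5000L,
      data.frame(N = c(10L, 50L, 100L, 250L, 500L, 1000L)),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15), selection_proportional(),
                          N = row$N, replicates = reps, base_seed = seed)
      }),
    "proportional-multiple-events" = base(
      "Proportional selection, scheme 5-10-15, N = 100, across events per lifetime",
      5000L,
      data.frame(events = c(1L, 2L, 5L, 10L, 20L)),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15, events = row$events),
                          selection_proportional(), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "proportional-asymmetric-constant-variance" = base(
      "Proportional selection, N = 100, mean 10 / variance 25 schemes across P(high)",
      5000L,
      data.frame(p_high = p_grid),
      function(row, reps, seed) {
        experiment_config(scheme_from_moments(row$p_high, 10, 25),
                          selection_proportional(), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "proportional-asymmetric-free-variance" = base(
      "Proportional selection, N = 100, mean-matched schemes with low = 5 fixed (variance varies with P(high))",
      2000L,
      data.frame(p_high = p_grid),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 5 + 5 / row$p_high,
                                        p_high = row$p_high),
                          selection_proportional(), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "truncation-threshold-sweep" = base(
      "Rank-based truncation, scheme 5-10-15, N = 100, across thresholds",
      2000L,
      data.frame(threshold = seq(0.1, 0.9, by = 0.1)),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15),
                          selection_truncation(row$threshold), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "truncation-50-symmetric" = base(
      "Rank-based truncation at 50%, symmetric scheme 5-10-15, N = 100 (neutral case)",
      2000L,
      data.frame(threshold = 0.5),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15), selection_truncation(0.5),
                          N = 100L, replicates = reps, base_seed = seed)
      }),
    "truncation-50-payoff-schemes" = base(
      "Rank-based truncation at 50%, mean 10 / variance 25 schemes across P(high)",
      2000L,
      data.frame(p_high = p_grid),
      function(row, reps, seed) {
        experiment_config(scheme_from_moments(row$p_high, 10, 25),
                          selection_truncation(0.5), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "truncation-20-payoff-schemes" = base(
      "Rank-based truncation at 20%, mean 10 / variance 25 schemes across P(high) (includes 8.333-10-25)",
      2000L,
      data.frame(p_high = p_grid),
      function(row, reps, seed) {
        experiment_config(scheme_from_moments(row$p_high, 10, 25),
                          selection_truncation(0.2), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "power-exponent-sweep" = base(
      "Power-weighted selection, scheme 5-10-15, across exponents and population sizes",
      2000L,
      expand.grid(z = c(0.75, 0.9, 1, 1.1, 1.26, 1.5),
                  N = c(10L, 100L, 1000L)),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15), selection_power(row$z),
                          N = row$N, replicates = reps, base_seed = seed)
      }),
    "power-z1.26-N100" = base(
      "Power-weighted selection, z = 1.26, scheme 5-10-15, N = 100",
      2000L,
      data.frame(z = 1.26, N = 100L),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15), selection_power(1.26),
                          N = 100L, replicates = reps, base_seed = seed)
      }),
    "power-z1.26-N10" = base(
      "Power-weighted selection, z = 1.26, scheme 5-10-15, N = 10",
      5000L,
      data.frame(z = 1.26, N = 10L),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15), selection_power(1.26),
                          N = 10L, replicates = reps, base_seed = seed)
      }),
    "power-z1.5-5-10-500-N50" = base(
      "Power-weighted selection, z = 1.5, extreme scheme 5-10-500, N = 50",
      2000L,
      data.frame(z = 1.5, N = 50L),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 500), selection_power(1.5),
                          N = 50L, replicates = reps, base_seed = seed)
      }),
    "sigmoid-inflection-sweep" = base(
      "Sigmoid-weighted selection, steepness 10, scheme 5-10-15, N = 100, across inflection points",
      2000L,
      data.frame(inflection = seq(0.55, 0.80, by = 0.025)),
      function(row, reps, seed) {
        experiment_config(payoff_scheme(5, 15),
                          selection_sigmoid(10, row$inflection), N = 100L,
                          replicates = reps, base_seed = seed)
      }),
    "sigmoid-high15-family" = base(
      "Sigmoid-weighted selection (steepness 10, inflection 2/3), high payoff fixed at 15, across P(high)",
      2000L,
      data.frame(p_high = c(0.40, 0.45, 0.50, 0.55, 0.60)),
      function(row, reps, seed) {
        low <- (10 - row$p_high * 15) / (1 - row$p_high)  # mean-matched, high fixed
        experiment_config(payoff_scheme(low, 15, p_high = row$p_high),
                          selection_sigmoid(10, 2 / 3), N = 100L,
                          replicates = reps, base_seed = seed)
      })
  )
}

#' Run a registered scenario
#'
#' Simulates every cell of the scenario's parameter grid to fixation and
#' returns one summary row per cell. Cell `i` of the grid uses base seed
#' `spawn_seed(seed, i)`, so a scenario is fully reproducible from
#' `(name, replicates, seed)`.
#'
#' @param name Scenario name; see [list_scenarios()].
#' @param replicates Replicates per grid cell; `NULL` uses the scenario
#'   default.
#' @param seed Integer seed.
#' @return A data frame: the scenario's grid columns followed by the fields
#'   of [summarize_fixation()] (proportions are risk-averse fixation).
#' @examples
#' \donttest{
#' run_scenario("truncation-50-symmetric", replicates = 200, seed = 1)
#' }
#' @export
run_scenario <- function(name, replicates = NULL, seed = 1L) {
  reg <- .scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  sc <- reg[[name]]
  reps <- if (is.null(replicates)) sc$replicates else as.integer(replicates)
  out <- vector("list", nrow(sc$grid))
  for (i in seq_len(nrow(sc$grid))) {
    row <- sc$grid[i, , drop = FALSE]
    cfg <- sc$build(row, reps, spawn_seed(seed, i))
    est <- summarize_fixation(run_replicates(cfg))
    out[[i]] <- cbind(scenario = name, row, as.data.frame(est),
                      seed = cfg$base_seed)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locate the tipping point of a selection-parameter sweep
#'
#' Simulates fixation proportions over a grid of a selection parameter
#' (sigmoid inflection, power exponent, or truncation threshold) and locates
#' the parameter value at which the risk-prone fixation probability crosses
#' 0.5, i.e. where neither strategy is favored. The crossing is interpolated
#' linearly on the logit of the risk-prone fixation proportion between the
#' bracketing grid points; when sampling noise produces multiple sign
#' changes, the proportions are first made monotone by isotonic regression.
#' Uncertainty is assessed by a parametric bootstrap of the per-cell binomial
#' counts.
#'
#' @param family `"sigmoid"` (vary the inflection), `"power"` (vary the
#'   exponent) or `"truncation"` (vary the threshold).
#' @param grid Increasing vector of parameter values to simulate.
#' @param scheme A [payoff_scheme()] (default the 5-10-15 scheme).
#' @param N Population size.
#' @param replicates Replicates per grid point.
#' @param seed Integer seed.
#' @param steepness Sigmoid steepness (used when `family = "sigmoid"`).
#' @param n_boot Bootstrap resamples for the uncertainty estimate.
#' @return A list with `estimate` (the interpolated crossing), `ci_low`,
#'   `ci_high` (2.5% and 97.5% bootstrap quantiles), `table` (per-grid-point
#'   fixation proportions) and `family`.
#' @examples
#' \donttest{
#' tp <- locate_tipping_point("power", grid = seq(0.9, 1.3, by = 0.1),
#'                            N = 50, replicates = 300, seed = 1)
#' tp$estimate
#' }
#' @export
locate_tipping_point <- function(family = c("sigmoid", "power", "truncation"),
                                 grid, scheme = payoff_scheme(5, 15),
                                 N = 100L, replicates = 1000L, seed = 1L,
                                 steepness = 10, n_boot = 200L) {
  family <- match.arg(family)
  stopifnot(is.numeric(grid), length(grid) >= 2L, !is.unsorted(grid))
  build <- switch(family,
    sigmoid = function(v) selection_sigmoid(steepness, v),
    power = function(v) selection_power(v),
    truncation = function(v) selection_truncation(v))
  p_rp <- numeric(length(grid))
  for (i in seq_along(grid)) {
    cfg <- experiment_config(scheme, build(grid[i]), N = N,
                             replicates = replicates,
                             base_seed = spawn_seed(seed, i))
    res <- run_replicates(cfg)
    p_rp[i] <- mean(res$fixed_strategy == "risk_prone")
  }
  est <- .interp_crossing(grid, p_rp)
  if (is.na(est))
    stop("risk-prone fixation proportion does not cross 0.5 over the grid; ",
         "widen the parameter range")
  boot <- numeric(n_boot)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(spawn_seed(seed, 0L))
  for (b in seq_len(n_boot)) {
    pb <- stats::rbinom(length(grid), replicates, p_rp) / replicates
    boot[b] <- .interp_crossing(grid, pb)
  }
  boot <- boot[!is.na(boot)]
  list(estimate = est,
       ci_low = if (length(boot)) unname(stats::quantile(boot, 0.025)) else NA_real_,
       ci_high = if (length(boot)) unname(stats::quantile(boot, 0.975)) else NA_real_,
       table = data.frame(parameter = grid, proportion_risk_prone = p_rp,
                          n = replicates),
       family = family)
}

# Logit-linear interpolation of the 0.5 crossing; isotonic regression is
# applied first if noise produces multiple sign changes. Returns NA when the
# proportions never cross 0.5.
.interp_crossing <- function(x, p) {
  s <- sign(p - 0.5)
  flips <- which(s[-1] * s[-length(s)] < 0 |
                   (s[-length(s)] != 0 & s[-1] == 0))
  exact <- which(s == 0)
  if (length(exact) && length(flips) == 0L) return(x[exact[1L]])
  if (length(flips) == 0L) return(NA_real_)
  if (length(flips) > 1L) {
    direction <- sign(stats::cor(x, p, method = "spearman"))
    if (is.na(direction) || direction == 0) direction <- 1
    iso <- stats::isoreg(x, direction * p)
    p <- direction * iso$yf
    s <- sign(p - 0.5)
    flips <- which(s[-1] * s[-length(s)] < 0 |
                     (s[-length(s)] != 0 & s[-1] == 0))
    exact <- which(s == 0)
    if (length(exact) && length(flips) == 0L) return(x[exact[1L]])
    if (length(flips) == 0L) return(NA_real_)
  }
  i <- flips[1L]
  eps <- 1e-6
  l1 <- stats::qlogis(min(max(p[i], eps), 1 - eps))
  l2 <- stats::qlogis(min(max(p[i + 1L], eps), 1 - eps))
  if (l1 == l2) return((x[i] + x[i + 1L]) / 2)
  x[i] + (0 - l1) * (x[i + 1L] - x[i]) / (l2 - l1)
}
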