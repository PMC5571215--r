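test_that("step_generation enforces preconditions and conserves population size", {
  s <- scheme_515()
  sel <- selection_proportional()
  expect_error(step_generation(population_state(10, 0), s, sel), "fixed")
  expect_error(step_generation(population_state(10, 10), s, sel), "fixed")
  set.seed(1)
  st <- step_generation(population_state(10, 5), s, sel)
  expect_equal(st$N, 10L)
  expect_gte(st$k_risk_prone, 0L)
  expect_lte(st$k_risk_prone, 10L)
  expect_equal(st$generation, 1L)
})

test_that("equal payoffs give neutral Wright-Fisher resampling in one step", {
  sv0 <- scheme_from_moments(0.5, 10, 0)
  set.seed(21)
  ks <- replicate(4000, step_generation(population_state(10, 3), sv0,
                                        selection_proportional())$k_risk_prone)
  # k' ~ Binomial(10, 0.3)
  expect_lt(abs(mean(ks) - 3), 3 * sqrt(10 * 0.3 * 0.7 / 4000))
  expect_equal(stats::var(ks), 10 * 0.3 * 0.7, tolerance = 0.15)
})

test_that("two-player proportional transition matches the enumerated mixture", {
  # k = 1, N = 2, 5-10-15: the risk-prone player draws 15 or 5 with equal
  # probability, then both offspring come from the same realized weights, so
  # P(k'=2) = (0.6^2 + (1/3)^2)/2 = 53/225 and P(k'=0) = 68/225
  s <- scheme_515()
  set.seed(31)
  ks <- replicate(20000, step_generation(population_state(2, 1), s,
                                         selection_proportional())$k_risk_prone)
  expect_lt(abs(mean(ks == 2) - 53 / 225), band3(53 / 225, 20000))
  expect_lt(abs(mean(ks == 0) - 68 / 225), band3(68 / 225, 20000))
})

test_that("runs absorbed at the start return immediately", {
  s <- scheme_515()
  cfg0 <- experiment_config(s, selection_proportional(), 10, initial_k = 0)
  r <- run_to_fixation(cfg0, 1)
  expect_equal(r$fixed_strategy, "risk_averse")
  expect_equal(r$generations_to_fixation, 0L)
  cfgN <- experiment_config(s, selection_proportional(), 10, initial_k = 10)
  expect_equal(run_to_fixation(cfgN, 1)$fixed_strategy, "risk_prone")
})

test_that("replicates are deterministic in (config, base_seed) and all reach fixation", {
  cfg <- experiment_config(scheme_515(), selection_power(1.26), 20,
                           replicates = 60, base_seed = 77)
  a <- run_replicates(cfg)
  b <- run_replicates(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 60L)
  expect_true(all(a$fixed_strategy %in% c("risk_averse", "risk_prone")))
  expect_true(all(a$generations >= 1))

  cfg2 <- experiment_config(scheme_515(), selection_power(1.26), 20,
                            replicates = 60, base_seed = 78)
  expect_false(identical(run_replicates(cfg2)$seed, a$seed))
})

test_that("the max_generations guard signals non-fixation", {
  cfg <- experiment_config(scheme_515(), selection_proportional(), 50,
                           max_generations = 0)
  expect_error(run_to_fixation(cfg, 1), "no fixation")
})

test_that("run_to_fixation leaves the caller's random stream untouched", {
  set.seed(123)
  before <- .Random.seed
  cfg <- experiment_config(scheme_515(), selection_proportional(), 10,
                           replicates = 5, base_seed = 9)
  invisible(run_replicates(cfg))
  expect_identical(.Random.seed, before)
})

test_that("zero-variance schemes give the neutral fixation probability k/N", {
  sv0 <- scheme_from_moments(0.5, 10, 0)
  for (sel in list(selection_proportional(), selection_power(1.26),
                   selection_sigmoid(10, 2 / 3), selection_truncation(0.5))) {
    p <- engine_fixation_proportion(sv0, sel, 10, replicates = 10000,
                                    base_seed = 5, initial_k = 3)
    expect_lt(abs(p - 0.3), band3(0.3, 10000))
  }
})

test_that("the grouped core matches the naive per-individual dynamics", {
  # identical fixation proportions (within binomial error) for every scheme;
  # the naive reference resamples payoffs per individual and draws parents
  # explicitly from the full weight vector
  cases <- list(
    list(sel = selection_proportional(), events = 1L),
    list(sel = selection_proportional(), events = 3L),
    list(sel = selection_truncation(0.5), events = 1L),
    list(sel = selection_truncation(0.5), events = 3L),
    list(sel = selection_truncation_absolute(10), events = 1L),
    list(sel = selection_power(1.26), events = 1L),
    list(sel = selection_sigmoid(10, 2 / 3), events = 1L)
  )
  N <- 6L
  reps <- 1200L
  for (cs in cases) {
    sch <- scheme_515(events = cs$events)
    p_fast <- engine_fixation_proportion(sch, cs$sel, N, reps, base_seed = 61)
    p_naive <- naive_fixation_proportion(sch, cs$sel, N, N %/% 2L, reps,
                                         base_seed = 62)
    se <- sqrt(p_naive * (1 - p_naive) * 2 / reps) + 1e-9
    expect_lt(abs(p_fast - p_naive), 3 * se + 0.01)
  }
})

test_that("absolute truncation surfaces the empty-parent policy", {
  # cutoff above every possible payoff: no parent can ever qualify
  s <- scheme_515()
  cfg_err <- experiment_config(s, selection_truncation_absolute(100), 10,
                               empty_parent_policy = "error")
  expect_error(run_to_fixation(cfg_err, 3), class = "empty_parent_set")
  cfg_uni <- experiment_config(s, selection_truncation_absolute(100), 10,
                               empty_parent_policy = "uniform",
                               replicates = 200)
  res <- run_replicates(cfg_uni)
  p <- mean(res$fixed_strategy == "risk_prone")
  expect_lt(abs(p - 0.5), band3(0.5, 200))  # uniform fallback is neutral
})

test_that("spawn_seed is deterministic, bounded, and index-sensitive", {
  s1 <- spawn_seed(42, 1)
  expect_identical(s1, spawn_seed(42, 1))
  expect_false(s1 == spawn_seed(42, 2))
  expect_false(s1 == spawn_seed(43, 1))
  seeds <- vapply(1:5000, function(r) spawn_seed(1, r), 1L)
  expect_true(all(seeds >= 0 & seeds < 2^31 - 1))
  expect_equal(anyDuplicated(seeds), 0L)
})
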