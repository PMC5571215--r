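test_that("the scenario registry lists scenarios and rejects unknown names", {
  sc <- list_scenarios()
  expect_true(all(c("proportional-one-decision", "truncation-50-symmetric",
                    "power-z1.26-N100", "sigmoid-inflection-sweep")
                  %in% sc$scenario))
  expect_true(all(sc$default_replicates %in% c(2000L, 5000L)))
  expect_error(run_scenario("no-such-scenario"), "proportional-one-decision")
})

test_that("scenario runs return one summary row per grid cell, reproducibly", {
  r1 <- run_scenario("truncation-50-symmetric", replicates = 400, seed = 8)
  r2 <- run_scenario("truncation-50-symmetric", replicates = 400, seed = 8)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 1L)
  # symmetric scheme at a 50% rank threshold: neither strategy is favored
  expect_lt(abs(r1$proportion_risk_averse - 0.5), band3(0.5, 400))

  r <- run_scenario("proportional-multiple-events", replicates = 30, seed = 8)
  expect_equal(r$events, c(1L, 2L, 5L, 10L, 20L))
  expect_equal(r$n, rep(30L, 5))
})

test_that("asymmetric schemes flip the favored strategy under 50% truncation", {
  # high payoff more likely than low -> risk-prone fixes in the vast
  # majority of runs; the mirror case favors risk-averse
  p_hi <- engine_fixation_proportion(scheme_from_moments(0.7, 10, 25),
                                     selection_truncation(0.5), 100, 400, 301)
  p_lo <- engine_fixation_proportion(scheme_from_moments(0.3, 10, 25),
                                     selection_truncation(0.5), 100, 400, 302)
  expect_gt(p_hi, 0.9)
  expect_lt(p_lo, 0.1)
})

test_that("a 20% truncation threshold usually favors risk-prone, but not for 8.333-10-25", {
  p_sym <- engine_fixation_proportion(scheme_from_moments(0.5, 10, 25),
                                      selection_truncation(0.2), 100, 400, 311)
  p_asym <- engine_fixation_proportion(scheme_from_moments(0.1, 10, 25),
                                       selection_truncation(0.2), 100, 400, 312)
  expect_gt(p_sym, 0.9)   # symmetric variance-25 scheme: risk-prone fixes
  expect_lt(p_asym, 0.1)  # rare-high scheme: risk-averse fixes nearly always
})

test_that("with the inflection at the risk-averse payoff, the commoner risk-prone outcome decides", {
  # high payoff fixed at 15 so the risk-averse normalized payoff sits at the
  # 2/3 inflection; P(high) above vs below 1/2 flips the favored strategy
  mk <- function(p) payoff_scheme((10 - p * 15) / (1 - p), 15, p_high = p)
  p_60 <- engine_fixation_proportion(mk(0.60), selection_sigmoid(10, 2 / 3),
                                     100, 400, 321)
  p_40 <- engine_fixation_proportion(mk(0.40), selection_sigmoid(10, 2 / 3),
                                     100, 400, 322)
  expect_gt(p_60, 0.9)
  expect_lt(p_40, 0.1)
})

test_that("the strategy difference shrinks as lifetime events accumulate", {
  s1 <- 1 - engine_fixation_proportion(scheme_515(1L),
                                       selection_proportional(), 100, 2000, 331)
  s20 <- 1 - engine_fixation_proportion(scheme_515(20L),
                                        selection_proportional(), 100, 2000, 332)
  expect_lt(abs(s1 - 0.555), band3(0.555, 2000))  # single event: clear advantage
  expect_lt(abs(s20 - 0.5), band3(0.5, 2000))     # many events: neutral
})

test_that("tipping-point location interpolates the 0.5 crossing and detects its absence", {
  # power-weighted family at N = 10: the oracle puts the crossing between
  # z = 1 (risk-averse favored) and z = 1.4 (risk-prone favored)
  tp <- locate_tipping_point("power", grid = seq(0.8, 1.6, by = 0.2),
                             N = 10, replicates = 600, seed = 15)
  expect_gt(tp$estimate, 1.0)
  expect_lt(tp$estimate, 1.5)
  expect_lte(tp$ci_low, tp$estimate)
  expect_gte(tp$ci_high, tp$estimate)
  expect_equal(nrow(tp$table), 5L)

  # a range where risk-prone always fixes has no crossing
  expect_error(
    locate_tipping_point("power", grid = c(1.8, 2.0), N = 100,
                         replicates = 150, seed = 16),
    "does not cross")
})

test_that("configurations round-trip through YAML with strict scheme validation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scheme: 5-10-15",
    "events: 2",
    "selection: {kind: power, z: 1.26}",
    "N: 50",
    "replicates: 10",
    "base_seed: 99"), path)
  cfg <- read_config(path)
  expect_equal(cfg$scheme$low, 5)
  expect_equal(cfg$scheme$events, 2L)
  expect_equal(cfg$selection$z, 1.26)
  expect_equal(cfg$N, 50L)
  expect_equal(cfg$base_seed, 99L)

  path2 <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scheme: {p_high: 0.1, mean: 10, variance: 25}",
    "selection: {kind: truncation_rank, threshold: 0.2}",
    "N: 100"), path2)
  cfg2 <- read_config(path2)
  expect_equal(cfg2$scheme$high, 25)
  expect_equal(cfg2$scheme$low, 10 - 5 / 3, tolerance = 1e-9)

  path3 <- tempfile(fileext = ".yaml")
  writeLines(c(
    "scheme: 5-10-15",
    "selection: {kind: proportional, z: 2}",
    "N: 10"), path3)
  expect_error(read_config(path3), "does not accept")

  out <- tempfile(fileext = ".csv")
  res <- run_replicates(experiment_config(scheme_515(),
                                          selection_proportional(), 10,
                                          replicates = 5, base_seed = 1))
  write_results(res, out)
  back <- utils::read.csv(out)
  expect_equal(back$fixed_strategy, res$fixed_strategy)
})
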