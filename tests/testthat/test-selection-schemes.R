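test_that("proportional weights match the two-player worked examples", {
  expect_equal(proportional_weights(c(10, 5)), c(2 / 3, 1 / 3))
  expect_equal(proportional_weights(c(10, 15)), c(0.4, 0.6))
  expect_equal(proportional_weights(rep(7, 5)), rep(1 / 5, 5))
  expect_equal(proportional_weights(c(10, 0)), c(1, 0))  # zero payoff allowed
  expect_error(proportional_weights(c(10, -1)), "nonnegative")
  expect_error(proportional_weights(c(0, 0)), "positive total")
})

test_that("power weights follow payoff^z and collapse to the limiting cases", {
  expect_equal(power_weights(c(5, 15), 2), c(0.1, 0.9))
  expect_equal(power_weights(c(5, 15, 10), 0), rep(1 / 3, 3))
  set.seed(5)
  for (i in 1:20) {
    p <- stats::runif(8, 0.5, 30)
    expect_identical(power_weights(p, 1), proportional_weights(p))
  }
  expect_error(power_weights(c(5, -1), 1.5), "positive")
})

test_that("rank truncation gives exactly k parents equal weight, ties randomized", {
  set.seed(2)
  expect_equal(truncation_rank_weights(c(15, 15, 10, 5), 0.5),
               c(0.5, 0.5, 0, 0))
  expect_equal(truncation_rank_weights(c(5, 10, 15), 1.0), rep(1 / 3, 3))

  # tie at the cutoff rank: the strictly-best individual is always eligible,
  # each tied individual roughly half the time
  n_calls <- 4000
  elig <- matrix(0, n_calls, 4)
  for (i in seq_len(n_calls))
    elig[i, ] <- truncation_rank_weights(c(15, 10, 10, 5), 0.5) > 0
  expect_true(all(elig[, 1] == 1))
  expect_true(all(elig[, 4] == 0))
  expect_lt(abs(mean(elig[, 2]) - 0.5), band3(0.5, n_calls))
  expect_lt(abs(mean(elig[, 3]) - 0.5), band3(0.5, n_calls))

  # exactly k nonzero entries of exactly 1/k, k rounded half-up
  for (i in 1:20) {
    n <- sample(3:40, 1)
    thr <- stats::runif(1, 0.05, 1)
    w <- truncation_rank_weights(stats::runif(n, 0, 30), thr)
    k <- max(1, floor(thr * n + 0.5))
    expect_identical(sum(w > 0), as.integer(k))
    expect_equal(unique(w[w > 0]), 1 / k)
  }
  expect_error(truncation_rank_weights(c(1, 2), 0), "threshold")
})

test_that("absolute truncation weights are equal above the cutoff and error on empty sets", {
  expect_equal(truncation_absolute_weights(c(5, 10, 15), 10), c(0, 0.5, 0.5))
  expect_equal(truncation_absolute_weights(c(5, 10, 15), 0), rep(1 / 3, 3))
  err <- tryCatch(truncation_absolute_weights(c(5, 5, 5), 10), error = identity)
  expect_s3_class(err, "empty_parent_set")
})

test_that("sigmoid weights apply the logistic to max-normalized payoffs", {
  # an individual sitting at the inflection point has transformed value 1/2
  beta <- 10 / 15
  t1 <- stats::plogis(10 * (1 - beta))
  w <- sigmoid_weights(c(15, 10), 10, beta)
  expect_equal(w, c(t1, 0.5) / (t1 + 0.5))

  # full evaluation with three payoff levels
  tr <- stats::plogis(10 * (c(1, 2 / 3, 1 / 3) - 2 / 3))
  expect_equal(sigmoid_weights(c(15, 10, 5), 10, 2 / 3), tr / sum(tr))

  # steepness -> Inf approaches a step function over {p_n > beta}
  w <- sigmoid_weights(c(15, 12, 5), 500, 2 / 3)
  expect_equal(w, c(0.5, 0.5, 0), tolerance = 1e-12)

  # invariance to global payoff rescaling
  set.seed(9)
  for (i in 1:20) {
    p <- stats::runif(6, 1, 20)
    expect_equal(sigmoid_weights(3.7 * p, 10, 2 / 3),
                 sigmoid_weights(p, 10, 2 / 3), tolerance = 1e-12)
  }
  expect_error(sigmoid_weights(c(0, 0), 10, 0.5), "positive")
})

test_that("all schemes return probability distributions, equivariant to permutation", {
  set.seed(31)
  sels <- all_selection_schemes()
  for (i in 1:25) {
    payoffs <- stats::runif(sample(2:30, 1), 0.5, 40)
    for (sel in sels) {
      w <- reproduction_weights(payoffs, sel)
      expect_equal(sum(w), 1, tolerance = 1e-12)
      expect_true(all(w >= 0))
      # with distinct payoffs, permuting payoffs permutes weights
      perm <- sample(length(payoffs))
      if (sel$kind != "truncation_rank" ||
          !anyDuplicated(payoffs)) {
        wp <- reproduction_weights(payoffs[perm], sel)
        expect_equal(wp, w[perm], tolerance = 1e-12)
      }
    }
  }
})

test_that("selection constructors validate parameters and tagged lists strictly", {
  expect_error(selection_truncation(1.2), "threshold")
  expect_error(selection_power(-1), "nonnegative")
  expect_error(selection_sigmoid(-1, 0.5), "positive")
  expect_error(selection_sigmoid(10, 1.5), "inflection")
  expect_error(as_selection_scheme(list(kind = "proportional", z = 2)),
               "does not accept")
  expect_error(as_selection_scheme(list(kind = "power")), "requires")
  sel <- as_selection_scheme(list(kind = "sigmoid", steepness = 10,
                                  inflection = 0.5))
  expect_s3_class(sel, "selection_scheme")
  expect_equal(sel$kind, "sigmoid")
})
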