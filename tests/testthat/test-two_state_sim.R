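test_that("propensities follow the mass-action rates", {
  expect_equal(propensities(0, two_state_params(0.9, 0.4)),
               c(division = 0, transition = 0))
  expect_equal(propensities(10, two_state_params(0.65, 0.3)),
               c(division = 6.5, transition = 3.0))
  # capacity saturates division but not transition
  p <- two_state_params(1, 0.2, K = 8)
  expect_equal(propensities(4, p, y = 4),
               c(division = 0, transition = 0.8))
  expect_error(propensities(-1, two_state_params(1, 0)), "nonnegative")
})

test_that("parameter validation rejects invalid rates", {
  expect_error(two_state_params(-0.1, 0), "nonnegative")
  expect_error(two_state_params(0.5, -1), "nonnegative")
  expect_error(two_state_params(0.5, 0.1, K = 0), "positive")
})

test_that("degenerate clones behave as the reaction network dictates", {
  # no reactions possible, yet not absorbed
  tr <- simulate_clone(two_state_params(0, 0), t_max = 8, seed = 1)
  expect_equal(tr$x_counts, 1)
  expect_equal(tr$y_counts, 0)
  expect_equal(tr$terminated_reason, "t_max")
  # only the transition can fire, exactly once
  tr <- simulate_clone(two_state_params(0, 5), t_max = 8, seed = 1)
  expect_equal(tail(tr$x_counts, 1), 0)
  expect_equal(tail(tr$y_counts, 1), 1)
  expect_equal(tr$terminated_reason, "absorbed")
  expect_error(simulate_clone(two_state_params(1, 0), t_max = 0, seed = 1),
               "positive")
})

test_that("trajectories obey conservation and single-reaction stoichiometry", {
  for (seed in 1:5) {
    tr <- simulate_clone(two_state_params(0.8, 0.5), t_max = 6, seed = seed)
    expect_true(!is.unsorted(tr$times))
    expect_equal(tr$x_counts[1], 1)
    expect_equal(tr$y_counts[1], 0)
    total <- tr$x_counts + tr$y_counts
    expect_true(all(diff(total) >= 0))          # no cell loss
    expect_true(all(diff(tr$y_counts) >= 0))    # arrest is irreversible
    if (length(tr$times) > 1) {
      dx <- diff(tr$x_counts); dy <- diff(tr$y_counts)
      division <- dx == 1 & dy == 0
      transition <- dx == -1 & dy == 1
      expect_true(all(division | transition))
    }
  }
})

test_that("identical seeds reproduce identical event sequences", {
  p <- two_state_params(0.7, 0.2)
  a <- simulate_clone(p, t_max = 8, seed = 99)
  b <- simulate_clone(p, t_max = 8, seed = 99)
  expect_identical(a, b)
  ea <- simulate_ensemble(p, 100, 8, seed = 42)
  eb <- simulate_ensemble(p, 100, 8, seed = 42)
  expect_identical(ea$sizes, eb$sizes)
})

test_that("pure-birth ensembles match the Yule process law", {
  g <- 0.5; t <- 2; n <- 10000
  s <- simulate_ensemble(two_state_params(g, 0), n, t, seed = 7)
  # mean within 3 Monte-Carlo standard errors of e^{gt}
  se <- sd(s$sizes) / sqrt(n)
  expect_lt(abs(mean(s$sizes) - exp(g * t)), 3 * se)
  # full distribution: geometric on {1, 2, ...} with success p = e^{-gt}
  p_succ <- exp(-g * t)
  counts <- tabulate(pmin(s$sizes, 16), nbins = 16)
  probs <- p_succ * (1 - p_succ)^(0:14)
  probs <- c(probs, 1 - sum(probs)) # tail bin >= 16
  gof <- suppressWarnings(chisq.test(counts, p = probs))
  expect_gt(gof$p.value, 1e-3)
})

test_that("subcritical clones are absorbed in finite time", {
  s <- simulate_ensemble(two_state_params(0.2, 0.5), 1000, 60, seed = 3)
  expect_true(all(attr(s, "absorbed")))
  expect_true(all(s$sizes >= 1))
})

test_that("lineage extinction fraction matches the branching-process formula", {
  # q = min(1, k/g); moderate scale here, the large-n check is the
  # acceptance suite's job
  s <- simulate_ensemble(two_state_params(0.65, 0.3), 2000, 25, seed = 13)
  q_hat <- mean(attr(s, "absorbed"))
  q <- 0.3 / 0.65
  expect_lt(abs(q_hat - q), 3 * sqrt(q * (1 - q) / 2000))
})

test_that("ensemble input contracts hold", {
  p <- two_state_params(0.5, 0)
  expect_error(simulate_ensemble(p, 0, 8, seed = 1), ">= 1")
  s <- simulate_ensemble(two_state_params(0, 0), 100, 5, seed = 1)
  expect_true(all(s$sizes == 1))
  # capacity clamps growth at K
  sK <- simulate_ensemble(two_state_params(2, 0, K = 20), 50, 10, seed = 2)
  expect_true(all(sK$sizes <= 20))
})
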