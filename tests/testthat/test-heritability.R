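test_that("top-decile overlap handles identity, options and errors", {
  expect_equal(top_decile_overlap(1:20, 1:20), 1)
  expect_equal(top_decile_overlap(1:20, 20:1), 0)
  expect_error(top_decile_overlap(1:20, 1:10), "universe")
  expect_error(top_decile_overlap(1:5, 1:5), "at least 10")
  a <- setNames(1:10, letters[1:10])
  b <- setNames(1:10, letters[c(1:9, 11)])
  expect_error(top_decile_overlap(a, b), "names differ")
  # Jaccard denominator never exceeds the per-sample fraction
  set.seed(1)
  x <- runif(50); y <- runif(50)
  expect_lte(top_decile_overlap(x, y, denominator = "union"),
             top_decile_overlap(x, y))
})

test_that("independent rankings overlap at the decile fraction", {
  set.seed(2)
  ov <- replicate(300, top_decile_overlap(runif(1000), runif(1000)))
  expect_lt(abs(mean(ov) - 0.10), 0.01)
})

test_that("abundance correlation matches the product-moment formula", {
  expect_equal(abundance_correlation(1:10, 1:10)$pearson_r, 1)
  expect_equal(abundance_correlation(1:10, -(1:10) + 5)$pearson_r, -1)
  r <- abundance_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$pearson_r, 0.6)
  expect_error(abundance_correlation(rep(2, 5), 1:5), "zero variance")
  # rpm normalisation removes depth differences entirely
  a <- c(10, 20, 30, 40)
  r_rpm <- abundance_correlation(a, a * 7, normalize = "rpm")
  expect_equal(r_rpm$pearson_r, 1)
})

test_that("the binomial split conserves pre-split copies exactly", {
  ex <- simulate_split_experiment(500, pre_doublings = 4, seed = 11)
  expect_true(all(ex$counts$init_a + ex$counts$init_b == 16))
  ex3 <- simulate_split_experiment(100, pre_doublings = 3, seed = 1)
  expect_true(all(ex3$counts$init_a + ex3$counts$init_b == 8))
  expect_identical(ex, simulate_split_experiment(500, 4, seed = 11))
  expect_error(simulate_split_experiment(5, seed = 1), ">= 10")
})

test_that("heritable growth couples the split samples, non-heritable does not", {
  set.seed(3)
  ref <- c(rnorm(200, 2, 1), rnorm(100, 8, 1)) # spread of division counts
  dist <- growth_rate_dist("stochastic", reference = ref)
  exH <- simulate_split_experiment(1000, 4, dist, heritable = TRUE, seed = 5)
  expect_identical(exH$growth_a, exH$growth_b)
  rH <- cor(log1p(exH$counts$cells_a), log1p(exH$counts$cells_b))
  expect_gt(rH, 0.9)
  exN <- simulate_split_experiment(5000, 4, dist, heritable = FALSE,
                                   seed = 6)
  expect_false(identical(exN$growth_a, exN$growth_b))
  expect_lt(abs(cor(exN$counts$cells_a, exN$counts$cells_b)), 0.1)
})

test_that("growth-rate distributions draw from the requested law", {
  ref <- c(1, 2, 3, 9, 10)
  set.seed(7)
  expect_true(all(draw_growth_rates(growth_rate_dist("stochastic", ref),
                                    1000) %in% ref))
  u <- draw_growth_rates(growth_rate_dist("unimodal", ref), 5000)
  expect_equal(mean(u), mean(ref), tolerance = 0.2)
  expect_equal(sd(u), sd(ref), tolerance = 0.2)
  b <- draw_growth_rates(growth_rate_dist("bimodal", ref), 5000)
  expect_equal(mean(b), mean(ref), tolerance = 0.3)
  un <- draw_growth_rates(growth_rate_dist("uniform", range = c(0, 5)), 1000)
  expect_true(all(un >= 0 & un <= 5))
  expect_error(growth_rate_dist("unimodal"), "required")
})

test_that("the non-heritable null is centred near zero with add-one p-values", {
  set.seed(8)
  ref <- c(rnorm(200, 2, 1.5), rnorm(100, 8, 1))
  nd <- null_distribution(reference = ref, kind = "unimodal",
                          n_replicates = 300, n_barcodes = 500, seed = 21)
  expect_equal(length(nd$null_r), 300)
  expect_lt(abs(mean(nd$null_r, na.rm = TRUE)), 0.05)
  expect_lt(abs(mean(nd$null_overlap) - 0.10), 0.04)
  # strongly heritable observation: nothing in the null reaches it
  exH <- simulate_split_experiment(500, 4,
                                   growth_rate_dist("stochastic", ref),
                                   heritable = TRUE, seed = 22)
  ndH <- null_distribution(exH$counts$cells_a, exH$counts$cells_b,
                           reference = ref, kind = "stochastic",
                           n_replicates = 200, seed = 23)
  expect_equal(ndH$empirical_p_r, 1 / 201)
  expect_gt(ndH$pearson_r,
            quantile(ndH$null_r, 0.99, na.rm = TRUE))
  expect_warning(null_distribution(reference = ref, n_replicates = 50,
                                   n_barcodes = 100, seed = 1),
                 "unstable")
})
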