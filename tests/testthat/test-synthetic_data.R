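test_that("synthetic config validates its fields and demands a seed", {
  expect_error(synthetic_config(), "mandatory")
  expect_error(synthetic_config(frac_highly_proliferative = 1.4, seed = 1))
  cfg <- synthetic_config(seed = 1)
  expect_equal(cfg$frac_highly_proliferative, 0.10)
  expect_equal(cfg$days, c(2, 5, 8, 11))
  expect_equal(cfg$hp_params$g, 0.75)
  expect_equal(cfg$lp_params$k, 0.3)
  expect_equal(cfg$pre_doublings, 4)
})

test_that("single-class tables delegate exactly to simulate_ensemble", {
  cfg <- synthetic_config(n_clones = 80, days = 8,
                          frac_highly_proliferative = 1, seed = 77)
  tab <- gen_clone_size_table(cfg)
  direct <- simulate_ensemble(cfg$hp_params, 80, 8, seed = 77)
  expect_equal(tab$n_cells, direct$sizes)
  expect_true(all(tab$condition == "highly_proliferative"))
  # frac = 0: everything from the less-proliferative parameters
  cfg0 <- synthetic_config(n_clones = 80, days = 8,
                           frac_highly_proliferative = 0, seed = 77)
  tab0 <- gen_clone_size_table(cfg0)
  expect_true(all(tab0$condition == "less_proliferative"))
  expect_gt(mean(tab0$n_cells <= 4), 0.1) # mass at small sizes
})

test_that("clone tables are deterministic and study-shaped", {
  cfg <- synthetic_config(n_clones = 60, seed = 5)
  t1 <- gen_clone_size_table(cfg)
  t2 <- gen_clone_size_table(cfg)
  expect_identical(t1, t2)
  expect_named(t1, c("clone_id", "replicate", "condition", "day", "n_cells"))
  expect_equal(nrow(t1), 60 * 4)
  expect_equal(sum(t1$condition == "highly_proliferative"), 6 * 4)
  # different days are independent realisations, larger with time
  means <- tapply(t1$n_cells, t1$day, mean)
  expect_true(means[["2"]] < means[["11"]])
})

test_that("default day-8 tables are detectably not unimodal", {
  over_third <- sapply(1:10, function(i) {
    tab <- gen_clone_size_table(synthetic_config(seed = 400 + i), days = 8)
    div <- quiet(log2_divisions(tab$n_cells, drop_singletons = TRUE))
    bimodality_coefficient(div)$coefficient > 1 / 3
  })
  expect_gte(sum(over_third), 8)
})

test_that("barcode experiments round-trip reads, spike-ins and ground truth", {
  cfg <- synthetic_config(n_barcodes = 200, read_noise_sd = 0,
                          heritable = TRUE, seed = 9)
  bc <- gen_barcode_experiment(cfg)
  tab_a <- bc$table[bc$table$sample == "A", ]
  expect_equal(nrow(tab_a), 200 + 6) # 3 spike-in levels x 2 replicates
  cal <- calibrate_spikeins(tab_a)
  expect_equal(cal$reads_per_cell, cfg$reads_per_cell, tolerance = 1e-9)
  expect_equal(cal$fit_r, 1)
  # noiseless reads back-calculate to the true cell numbers
  est <- estimate_cells(cal, tab_a$reads[!tab_a$is_spikein])
  expect_equal(cor(est, bc$truth$cells_a), 1)
  expect_identical(bc$truth$growth_a, bc$truth$growth_b)
})

test_that("non-heritable barcode experiments overlap at chance level", {
  ov <- sapply(1:8, function(i) {
    cfg <- synthetic_config(n_barcodes = 500, heritable = FALSE,
                            seed = 300 + i)
    bc <- gen_barcode_experiment(cfg)
    top_decile_overlap(bc$truth$cells_a, bc$truth$cells_b)
  })
  expect_lt(abs(mean(ov) - 0.10), 0.05)
})

test_that("density series respond monotonically to growth-rate shifts", {
  cfg <- synthetic_config(n_clones = 200, seed = 21)
  dens <- c(100, 1000, 10000)
  eff <- setNames(c(0, 0.1, 0.2), dens)
  tab <- gen_density_series(cfg, densities = dens, density_effect = eff)
  med <- tapply(log2(tab$n_cells[tab$n_cells > 1]),
                tab$density[tab$n_cells > 1], median)
  expect_true(all(diff(med) > 0))
  # zero effect: distributions are statistically indistinguishable
  tab0 <- gen_density_series(cfg, densities = c(100, 1000))
  a <- tab0$n_cells[tab0$density == 100]
  b <- tab0$n_cells[tab0$density == 1000]
  expect_gt(ks_compare(a[a > 1], b[b > 1])$p_value, 0.001)
  expect_error(gen_density_series(cfg, densities = c(100, 500),
                                  density_effect = c("100" = 0)),
               "500")
})

test_that("a capacity at the highest density produces the saturation dip", {
  cfg <- synthetic_config(n_clones = 200, seed = 21)
  dens <- c(100, 1000, 10000)
  eff <- setNames(c(0, 0.1, 0.2), dens)
  tab <- gen_density_series(cfg, densities = dens, density_effect = eff,
                            cap_highest = 30)
  med <- tapply(log2(tab$n_cells[tab$n_cells > 1]),
                tab$density[tab$n_cells > 1], median)
  expect_lt(med[["10000"]], med[["1000"]])
  expect_true(all(tab$n_cells[tab$density == 10000] <= 30))
})
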