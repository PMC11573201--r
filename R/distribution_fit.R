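#' Two-sample Kolmogorov-Smirnov comparison of clone-size distributions
#'
#' Compares a simulated and an observed clone-size sample with the two-sample
#' KS test on log2-transformed sizes (the "number of cell divisions" axis).
#' The statistic — the supremum absolute difference of the two empirical
#' CDFs — is invariant to this monotone transform; the transform is kept for
#' consistency with the division-count convention used throughout.
#'
#' @param sim,obs [clone_size_sample()] objects or bare numeric size vectors.
#' @return List with `statistic` and `p_value` (asymptotic two-sample KS).
#' @examples
#' ks_compare(c(1, 2, 4), c(2, 4, 8)) # statistic 1/3
#' @export
ks_compare <- function(sim, obs) {
  a <- .sizes_of(sim, "sim")
  b <- .sizes_of(obs, "obs")
  kt <- suppressWarnings(stats::ks.test(log2(a), log2(b), exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

.sizes_of <- function(x, what) {
  s <- if (inherits(x, "clone_size_sample")) x$sizes else as.numeric(x)
  if (length(s) == 0L)
    stop("`", what, "` sample must be nonempty", call. = FALSE)
  if (any(!is.finite(s)) || any(s < 1))
    stop("`", what, "` sizes must be finite and >= 1", call. = FALSE)
  s
}

#' Infer two-state model parameters by a KS parameter sweep
#'
#' For every `(g, k)` grid point, simulates an ensemble of clones to the
#' observation day and scores the simulated clone-size distribution against
#' the observed one with [ks_compare()]. The best fit is the grid point with
#' the lowest KS statistic; ties are broken by the highest p-value, then the
#' smallest `k`, then the smallest `g` (the KS surface typically has a
#' plateau along compensating `(g, k)` directions, so the tie-break order is
#' part of the contract).
#'
#' Each grid point uses its own seed derived deterministically from the
#' master seed, so ensembles are independent across the grid;
#' `common_random_numbers = TRUE` reuses the master seed at every point,
#' which smooths the sweep surface.
#'
#' @param obs Observed [clone_size_sample()] (or numeric sizes).
#' @param g_grid,k_grid Rate grids, 1/day. Defaults span 0-1 in steps of
#'   0.05.
#' @param n_sim_clones Clones simulated per grid point (>= 50; default 500,
#'   a typical observed clone count per replicate).
#' @param t_obs Observation day for the simulations; defaults to `obs$day`.
#' @param seed Master seed.
#' @param common_random_numbers Reuse one seed across grid points.
#' @param drop_sim_singletons Remove size-1 clones from each simulated
#'   ensemble before scoring. Use this when the observed sample was loaded
#'   with the one-cell filter, so both sides of the comparison follow the
#'   same convention; leaving it `FALSE` against filtered data biases the
#'   fit towards low transition rates (arrested singletons are missing from
#'   the observed side only).
#' @param max_cells Per-clone cell cap passed to the simulator.
#' @return A `sweep_result`: grids, `ks_stat` and `ks_pvalue` matrices
#'   (rows = `g_grid`, columns = `k_grid`), the selected `best`
#'   [two_state_params()], `best_stat`, `best_pvalue`, `n_sim_clones`,
#'   `seed`. `as.data.frame()` gives the long heatmap-ready table.
#' @examples
#' obs <- simulate_ensemble(two_state_params(0.7, 0.3), 200, 8, seed = 42)
#' sw <- parameter_sweep(obs, g_grid = seq(0.5, 0.9, 0.1),
#'                       k_grid = seq(0, 0.5, 0.1), n_sim_clones = 100,
#'                       seed = 1)
#' sw$best
#' @export
parameter_sweep <- function(obs, g_grid = seq(0, 1, by = 0.05),
                            k_grid = seq(0, 1, by = 0.05),
                            n_sim_clones = 500, t_obs = NULL, seed = 1,
                            common_random_numbers = FALSE,
                            drop_sim_singletons = FALSE,
                            max_cells = 1e6) {
  obs_sizes <- .sizes_of(obs, "obs")
  if (length(g_grid) == 0L || length(k_grid) == 0L)
    stop("parameter grids must be nonempty", call. = FALSE)
  if (n_sim_clones < 50)
    stop("`n_sim_clones` must be >= 50", call. = FALSE)
  obs_day <- if (inherits(obs, "clone_size_sample")) obs$day else NA_real_
  if (is.null(t_obs)) {
    if (is.na(obs_day))
      stop("`t_obs` must be given when the sample carries no day",
           call. = FALSE)
    t_obs <- obs_day
  } else if (!is.na(obs_day) && t_obs != obs_day) {
    warning("`t_obs` (", t_obs, ") differs from the sample's day (",
            obs_day, ")", call. = FALSE)
  }
  seed <- as.integer(seed)
  n_g <- length(g_grid); n_k <- length(k_grid)
  set.seed(seed)
  point_seeds <- if (common_random_numbers) {
    matrix(seed, n_g, n_k)
  } else {
    matrix(sample.int(.Machine$integer.max, n_g * n_k), n_g, n_k)
  }
  ks_stat <- matrix(NA_real_, n_g, n_k)
  ks_pval <- matrix(NA_real_, n_g, n_k)
  for (i in seq_len(n_g)) {
    for (j in seq_len(n_k)) {
      sim <- simulate_ensemble(two_state_params(g_grid[i], k_grid[j]),
                               n_sim_clones, t_obs,
                               seed = point_seeds[i, j],
                               max_cells = max_cells)
      sim_sizes <- sim$sizes
      if (drop_sim_singletons) sim_sizes <- sim_sizes[sim_sizes > 1]
      if (length(sim_sizes) == 0L) {
        # every simulated clone stayed a singleton: worst possible fit
        ks_stat[i, j] <- 1
        ks_pval[i, j] <- 0
        next
      }
      ks <- ks_compare(sim_sizes, obs_sizes)
      ks_stat[i, j] <- ks$statistic
      ks_pval[i, j] <- ks$p_value
    }
  }
  # argmin statistic; ties -> max p-value -> smallest k -> smallest g
  ord <- order(rep(ks_stat, 1), -rep(ks_pval, 1),
               rep(k_grid, each = n_g), rep(g_grid, times = n_k))
  best_idx <- ord[1L]
  bi <- (best_idx - 1L) %% n_g + 1L
  bj <- (best_idx - 1L) %/% n_g + 1L
  structure(list(g_grid = g_grid, k_grid = k_grid, ks_stat = ks_stat,
                 ks_pvalue = ks_pval,
                 best = two_state_params(g_grid[bi], k_grid[bj]),
                 best_stat = ks_stat[bi, bj], best_pvalue = ks_pval[bi, bj],
                 n_sim_clones = n_sim_clones, t_obs = t_obs, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("KS parameter sweep over", length(x$g_grid), "x", length(x$k_grid),
      "grid (", x$n_sim_clones, "clones/point, day", x$t_obs, ")\n")
  cat("  best fit: g =", x$best$g, ", k =", x$best$k,
      "| KS =", signif(x$best_stat, 3),
      ", p =", signif(x$best_pvalue, 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.sweep_result <- function(x, ...) {
  data.frame(g = rep(x$g_grid, times = length(x$k_grid)),
             k = rep(x$k_grid, each = length(x$g_grid)),
             ks_stat = as.vector(x$ks_stat),
             p_value = as.vector(x$ks_pvalue))
}
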