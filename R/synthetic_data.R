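#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the study-shaped generators with the defaults the
#' analyses assume: clones are a mixture of ~10% highly proliferative
#' (exponential, g = 0.75/day, k = 0) and ~90% less proliferative
#' (g = 0.7/day, k = 0.3/day) clones observed on fixed plates at days 2, 5,
#' 8 and 11; barcode experiments expand each barcode through four doublings
#' before a binomial split; spike-in ladders carry 50, 500 and 1000 cells at
#' a known reads-per-cell scale with multiplicative lognormal read noise.
#'
#' @param n_clones Clones per day per table (default 500, a typical
#'   per-replicate clone count).
#' @param days Observation days (default `c(2, 5, 8, 11)`).
#' @param frac_highly_proliferative Mixture fraction (default 0.10).
#' @param hp_params,lp_params [two_state_params()] for the two clone
#'   classes.
#' @param n_barcodes Barcodes in the split experiment (default 1000).
#' @param pre_doublings Doublings before the split (default 4).
#' @param heritable Do split samples share growth rates (default TRUE)?
#' @param growth_dist Optional [growth_rate_dist()] for barcode growth;
#'   `NULL` means uniform 0-5 divisions.
#' @param spikein_levels Known spike-in cell numbers.
#' @param spikein_replicates Spike-in barcodes per level (default 2).
#' @param reads_per_cell Sequencing scale (default 20 reads/cell).
#' @param read_noise_sd Lognormal sdlog of the multiplicative read noise
#'   (default 0.2; 0 disables noise).
#' @param seed Mandatory integer master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_clones = 500, days = c(2, 5, 8, 11),
                             frac_highly_proliferative = 0.10,
                             hp_params = two_state_params(0.75, 0),
                             lp_params = two_state_params(0.7, 0.3),
                             n_barcodes = 1000, pre_doublings = 4,
                             heritable = TRUE, growth_dist = NULL,
                             spikein_levels = c(50, 500, 1000),
                             spikein_replicates = 2, reads_per_cell = 20,
                             read_noise_sd = 0.2, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(inherits(hp_params, "two_state_params"),
            inherits(lp_params, "two_state_params"),
            n_clones >= 1, n_barcodes >= 10,
            frac_highly_proliferative >= 0, frac_highly_proliferative <= 1,
            reads_per_cell > 0, read_noise_sd >= 0,
            length(days) >= 1, all(days > 0))
  structure(list(n_clones = as.integer(n_clones), days = days,
                 frac_highly_proliferative = frac_highly_proliferative,
                 hp_params = hp_params, lp_params = lp_params,
                 n_barcodes = as.integer(n_barcodes),
                 pre_doublings = pre_doublings, heritable = heritable,
                 growth_dist = growth_dist,
                 spikein_levels = spikein_levels,
                 spikein_replicates = as.integer(spikein_replicates),
                 reads_per_cell = reads_per_cell,
                 read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Deterministic per-(day, class) seed derivation; the first day's
# highly-proliferative block reuses the master seed, so a single-day,
# single-class table is identical to a direct simulate_ensemble() call.
.derive_seed <- function(seed, day_index, class_index) {
  as.integer((as.double(seed) + 7919 * (day_index - 1) +
                104729 * class_index) %% .Machine$integer.max)
}

#' Generate a study-shaped multi-day clone-size table
#'
#' For each requested day an independent plate of clones is simulated (the
#' fixed-plate design images and discards a plate per time point, so days
#' are independent realisations, not longitudinal tracks). Each plate holds
#' `round(frac * n_clones)` highly proliferative and the remaining less
#' proliferative clones, each simulated with the two-state Gillespie model
#' at that day.
#'
#' @param config A [synthetic_config()].
#' @param days Override of `config$days`.
#' @return data.frame with columns `clone_id`, `replicate`, `condition`
#'   (the generating class, i.e. the ground-truth label), `day`, `n_cells`.
#' @examples
#' cfg <- synthetic_config(n_clones = 50, days = 8, seed = 1)
#' head(gen_clone_size_table(cfg))
#' @export
gen_clone_size_table <- function(config, days = config$days) {
  stopifnot(inherits(config, "synthetic_config"))
  n_hp <- round(config$frac_highly_proliferative * config$n_clones)
  n_lp <- config$n_clones - n_hp
  out <- list()
  for (di in seq_along(days)) {
    day <- days[di]
    blocks <- list()
    if (n_hp > 0) {
      s <- simulate_ensemble(config$hp_params, n_hp, day,
                             seed = .derive_seed(config$seed, di, 0L),
                             label = "highly_proliferative")
      blocks$hp <- data.frame(condition = "highly_proliferative",
                              n_cells = s$sizes)
    }
    if (n_lp > 0) {
      s <- simulate_ensemble(config$lp_params, n_lp, day,
                             seed = .derive_seed(config$seed, di, 1L),
                             label = "less_proliferative")
      blocks$lp <- data.frame(condition = "less_proliferative",
                              n_cells = s$sizes)
    }
    block <- do.call(rbind, blocks)
    block$clone_id <- sprintf("d%g_c%04d", day, seq_len(nrow(block)))
    block$replicate <- "r1"
    block$day <- day
    out[[di]] <- block[, c("clone_id", "replicate", "condition", "day",
                           "n_cells")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a paired barcode-split experiment with spike-ins
#'
#' Wraps [simulate_split_experiment()] and converts cell numbers to
#' sequencing reads at `reads_per_cell` with mean-one multiplicative
#' lognormal noise, then appends spike-in barcodes at the configured known
#' cell levels (the 50/500/1000 ladder by default, two barcodes per level).
#' Ground-truth growth rates and cell numbers are returned for recovery
#' tests.
#'
#' @param config A [synthetic_config()].
#' @return List with `table` (long data.frame: `barcode`, `sample`,
#'   `reads`, `is_spikein`, `true_cells`), `experiment` (the underlying
#'   `split_experiment`) and `truth` (per-barcode growth rates and cell
#'   numbers, plus `reads_per_cell`).
#' @export
gen_barcode_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  ex <- simulate_split_experiment(config$n_barcodes, config$pre_doublings,
                                  config$growth_dist,
                                  heritable = config$heritable,
                                  seed = config$seed)
  noisy_reads <- function(cells, n) {
    noise <- if (config$read_noise_sd > 0)
      rlnorm(n, -config$read_noise_sd^2 / 2, config$read_noise_sd)
    else rep(1, n)
    round(cells * config$reads_per_cell * noise)
  }
  nb <- config$n_barcodes
  sp_cells <- rep(config$spikein_levels, each = config$spikein_replicates)
  sp_ids <- sprintf("spike%d_%d",
                    rep(config$spikein_levels,
                        each = config$spikein_replicates),
                    rep(seq_len(config$spikein_replicates),
                        times = length(config$spikein_levels)))
  one_sample <- function(cells, sample_name) {
    data.frame(barcode = c(ex$counts$barcode_id, sp_ids),
               sample = sample_name,
               reads = c(noisy_reads(cells, nb),
                         noisy_reads(sp_cells, length(sp_cells))),
               is_spikein = c(rep(FALSE, nb), rep(TRUE, length(sp_cells))),
               true_cells = c(rep(NA_real_, nb), sp_cells))
  }
  tab <- rbind(one_sample(ex$counts$cells_a, "A"),
               one_sample(ex$counts$cells_b, "B"))
  rownames(tab) <- NULL
  list(table = tab, experiment = ex,
       truth = list(growth_a = ex$growth_a, growth_b = ex$growth_b,
                    cells_a = ex$counts$cells_a,
                    cells_b = ex$counts$cells_b,
                    reads_per_cell = config$reads_per_cell))
}

#' Generate a plating-density series of clone tables
#'
#' Emulates the density experiment: tracked clones are seeded at a constant
#' low number while the surrounding (untracked) cell density varies; higher
#' densities shift clone growth. `density_effect` gives the additive shift
#' on the division rate `g` of both clone classes at each density;
#' `cap_highest` optionally imposes a carrying capacity at the highest
#' density to emulate saturation (a dip of the largest clones).
#'
#' @param config A [synthetic_config()].
#' @param densities Seeded background densities, cells/plate.
#' @param density_effect Named numeric (names = densities) of additive
#'   shifts on `g`, 1/day. Defaults to zero everywhere. Every density must
#'   be present.
#' @param cap_highest Optional carrying capacity (cells) applied at the
#'   highest density only.
#' @param day Observation day (default 8).
#' @param n_clones_per_density Clones per density (default
#'   `config$n_clones`).
#' @return Clone table as in [gen_clone_size_table()] with an extra
#'   `density` column.
#' @export
gen_density_series <- function(config,
                               densities = c(100, 500, 1000, 5000, 10000),
                               density_effect = NULL, cap_highest = NULL,
                               day = 8,
                               n_clones_per_density = config$n_clones) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(densities) == 0L)
    stop("`densities` must be nonempty", call. = FALSE)
  if (is.null(density_effect))
    density_effect <- setNames(rep(0, length(densities)),
                               as.character(densities))
  missing_d <- setdiff(as.character(densities), names(density_effect))
  if (length(missing_d) > 0)
    stop("no density_effect entry for density: ",
         paste(missing_d, collapse = ", "), call. = FALSE)
  shift_params <- function(p, shift, K) {
    two_state_params(max(p$g + shift, 0), p$k, K = K)
  }
  out <- list()
  for (di in seq_along(densities)) {
    d <- densities[di]
    shift <- density_effect[[as.character(d)]]
    K <- if (!is.null(cap_highest) && d == max(densities)) cap_highest
         else NULL
    cfg_d <- config
    cfg_d$n_clones <- as.integer(n_clones_per_density)
    cfg_d$hp_params <- shift_params(config$hp_params, shift, K)
    cfg_d$lp_params <- shift_params(config$lp_params, shift, K)
    cfg_d$seed <- .derive_seed(config$seed, di, 2L)
    tab <- gen_clone_size_table(cfg_d, days = day)
    tab$density <- d
    tab$clone_id <- sprintf("dens%g_%s", d, tab$clone_id)
    out[[di]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
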