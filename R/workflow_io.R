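#' Read and validate a clone-size table
#'
#' Clone tables are tab-delimited UTF-8 with a header and columns
#' `clone_id`, `replicate`, `condition`, `day`, `n_cells`. Rows with
#' missing, non-numeric or sub-1 cell counts are rejected with their line
#' numbers. By default single-cell clones are filtered out (the imaging
#' analysis convention); barcode-derived tables should load with
#' `drop_singletons = FALSE`.
#'
#' @param path File path.
#' @param drop_singletons Filter size-1 clones (default TRUE).
#' @return Validated data.frame of clone records.
#' @export
read_clone_table <- function(path, drop_singletons = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("clone_id", "replicate", "condition", "day", "n_cells")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  n_cells <- suppressWarnings(as.numeric(tab$n_cells))
  bad <- which(!is.finite(n_cells) | n_cells < 1 |
                 n_cells != floor(n_cells))
  if (length(bad) > 0)
    stop("invalid n_cells (must be integer >= 1) on data line(s): ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  tab$n_cells <- n_cells
  if (drop_singletons) {
    n_drop <- sum(tab$n_cells == 1)
    if (n_drop > 0)
      message(n_drop, " singleton clone(s) filtered out")
    tab <- tab[tab$n_cells > 1, , drop = FALSE]
  }
  if (nrow(tab) == 0L)
    stop("no clone records remain after filtering", call. = FALSE)
  rownames(tab) <- NULL
  tab
}

#' Write a clone-size table
#'
#' @param records Clone records data.frame.
#' @param path Output path (tab-delimited, header, no quotes).
#' @export
write_clone_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode-count table
#'
#' Long layout expects columns `barcode`, `sample`, `reads`; wide layout
#' expects a `barcode` column followed by one numeric column per sample.
#' Duplicate (barcode, sample) rows are an error; a barcode absent from a
#' sample is treated as zero reads with a warning. Optional spike-in
#' annotations (columns `barcode`, `true_cells`) are joined on barcode.
#'
#' @param path File path (tab-delimited, header).
#' @param layout `"long"` or `"wide"`.
#' @param spikeins Optional path to a spike-in annotation table.
#' @return Wide data.frame: `barcode`, one read-count column per sample,
#'   `is_spikein`, `true_cells`.
#' @export
read_barcode_table <- function(path, layout = c("long", "wide"),
                               spikeins = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (layout == "long") {
    required <- c("barcode", "sample", "reads")
    missing_cols <- setdiff(required, names(tab))
    if (length(missing_cols) > 0)
      stop("missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (anyDuplicated(tab[c("barcode", "sample")]) > 0)
      stop("duplicate (barcode, sample) rows", call. = FALSE)
    reads <- suppressWarnings(as.numeric(tab$reads))
    if (any(!is.finite(reads)) || any(reads < 0))
      stop("reads must be nonnegative numbers", call. = FALSE)
    barcodes <- unique(tab$barcode)
    samples <- unique(tab$sample)
    wide <- data.frame(barcode = barcodes, stringsAsFactors = FALSE)
    n_missing <- 0L
    for (s in samples) {
      sub <- tab[tab$sample == s, ]
      m <- match(barcodes, sub$barcode)
      n_missing <- n_missing + sum(is.na(m))
      wide[[s]] <- ifelse(is.na(m), 0, reads[tab$sample == s][m])
    }
    if (n_missing > 0)
      warning(n_missing, " missing (barcode, sample) combination(s) ",
              "treated as 0 reads", call. = FALSE)
  } else {
    if (names(tab)[1] != "barcode")
      stop("wide layout requires the first column to be `barcode`",
           call. = FALSE)
    if (anyDuplicated(tab$barcode) > 0)
      stop("duplicate barcode rows", call. = FALSE)
    wide <- tab
  }
  wide$is_spikein <- FALSE
  wide$true_cells <- NA_real_
  if (!is.null(spikeins)) {
    sp <- read.delim(spikeins, stringsAsFactors = FALSE)
    stopifnot(all(c("barcode", "true_cells") %in% names(sp)))
    m <- match(wide$barcode, sp$barcode)
    wide$is_spikein <- !is.na(m)
    wide$true_cells <- sp$true_cells[m]
  }
  wide
}

#' Run the full synthetic-data analysis pipeline
#'
#' Ties the analysis stages together on generated inputs: (1) simulate a
#' multi-day clone-size table; (2) infer `(g, k)` per clone class at the
#' focal day by KS parameter sweep; (3) fit exponential and
#' logistic-growth-rate ODE models to the per-class mean growth curves;
#' (4) modality analysis per day; (5) barcode split experiment with
#' spike-in calibration and the non-heritable null. All stage outputs plus
#' a JSON run manifest (config snapshot, seed, package version, output
#' digests) are written under `out_dir`; rerunning with the same config
#' reproduces the outputs byte-identically.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param focal_day Day used for sweep inference (default 8).
#' @param g_grid,k_grid Sweep grids.
#' @param n_sim_clones Clones per sweep grid point.
#' @param n_null_replicates Non-heritable null replicates.
#' @param null_kind Null growth-rate law.
#' @return Invisibly, a list with all stage results (`clones`, `sweeps`,
#'   `ode_fits`, `modality`, `heritability`, `calibration`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, focal_day = 8,
                         g_grid = seq(0, 1, by = 0.05),
                         k_grid = seq(0, 1, by = 0.05),
                         n_sim_clones = 500, n_null_replicates = 1000,
                         null_kind = "stochastic") {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  # 1. clone-size table
  clones <- gen_clone_size_table(config)
  write_clone_table(clones, path("clones.tsv"))
  if (!focal_day %in% clones$day)
    stop("focal_day ", focal_day, " not among simulated days", call. = FALSE)
  day_tab <- clones[clones$day == focal_day, ]

  # 2. KS sweep per clone class at the focal day (singletons filtered, as
  #    for observed imaging data)
  sweeps <- list()
  classes <- unique(day_tab$condition)
  for (cls in classes) {
    sizes <- day_tab$n_cells[day_tab$condition == cls]
    sizes <- sizes[sizes > 1]
    if (length(sizes) < 10) next
    obs <- clone_size_sample(sizes, day = focal_day, label = cls)
    sweeps[[cls]] <- parameter_sweep(obs, g_grid, k_grid,
                                     n_sim_clones = n_sim_clones,
                                     seed = config$seed,
                                     drop_sim_singletons = TRUE)
    write.table(as.data.frame(sweeps[[cls]]),
                path(sprintf("sweep_%s.tsv", cls)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # 3. ODE fits to per-class mean growth curves
  ode_fits <- list()
  for (cls in classes) {
    sub <- clones[clones$condition == cls, ]
    curve_df <- aggregate(n_cells ~ day, data = sub, FUN = mean)
    if (nrow(curve_df) < 2) next
    cv <- growth_curve(curve_df$day, curve_df$n_cells)
    ode_fits[[cls]] <- list(
      exponential = fit_growth_model("exponential", cv, seed = config$seed),
      logistic_rate = if (nrow(curve_df) >= 3)
        fit_growth_model("logistic_rate", cv, seed = config$seed))
  }
  jsonlite::write_json(
    lapply(ode_fits, function(fits) lapply(Filter(Negate(is.null), fits),
      function(f) list(model_kind = f$model_kind, g = f$params$g,
                       k = f$params$k, K = f$params$K, cost = f$cost,
                       converged = f$converged))),
    path("ode_fits.json"), auto_unbox = TRUE, digits = NA, null = "null")

  # 4. modality per day (log2 divisions, singletons filtered)
  modality_rows <- lapply(sort(unique(clones$day)), function(d) {
    div <- log2_divisions(clones$n_cells[clones$day == d],
                          drop_singletons = TRUE)
    if (length(div) < 10) return(NULL)
    bc <- bimodality_coefficient(div)
    gmm <- fit_gmm(div, candidate_components = 1:3, seed = config$seed)
    data.frame(day = d, n = length(div),
               bimodality_coefficient = bc$coefficient, call = bc$call,
               gmm_components = gmm$n_components,
               gmm_means = paste(signif(gmm$means, 4), collapse = ","),
               gmm_weights = paste(signif(gmm$weights, 3), collapse = ","))
  })
  modality_tab <- do.call(rbind, Filter(Negate(is.null), modality_rows))
  write.table(modality_tab, path("modality.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # 5. barcode experiment, spike-in calibration, non-heritable null
  bc_exp <- gen_barcode_experiment(config)
  write.table(bc_exp$table, path("barcodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tab_a <- bc_exp$table[bc_exp$table$sample == "A", ]
  calibration <- calibrate_spikeins(tab_a)
  main <- !bc_exp$table$is_spikein
  reads_a <- bc_exp$table$reads[bc_exp$table$sample == "A" & main]
  reads_b <- bc_exp$table$reads[bc_exp$table$sample == "B" & main]
  cells_a <- estimate_cells(calibration, reads_a)
  cells_b <- estimate_cells(calibration, reads_b)
  reference <- log2_divisions(day_tab$n_cells, drop_singletons = TRUE)
  herit <- null_distribution(cells_a, cells_b, reference = reference,
                             kind = null_kind,
                             n_replicates = n_null_replicates,
                             pre_doublings = config$pre_doublings,
                             seed = config$seed)
  jsonlite::write_json(
    list(observed_r = herit$pearson_r,
         observed_overlap = herit$overlap_fraction,
         empirical_p_r = herit$empirical_p_r,
         empirical_p_overlap = herit$empirical_p_overlap,
         null_mean_r = mean(herit$null_r, na.rm = TRUE),
         null_mean_overlap = mean(herit$null_overlap),
         null_q99_r = unname(quantile(herit$null_r, 0.99, na.rm = TRUE)),
         reads_per_cell = calibration$reads_per_cell,
         spikein_fit_r = calibration$fit_r,
         kind = herit$kind, n_replicates = herit$n_replicates),
    path("heritability.json"), auto_unbox = TRUE, digits = NA)

  outputs <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(packageVersion("clonedyn")),
    seed = config$seed,
    config = config[setdiff(names(config),
                            c("hp_params", "lp_params", "growth_dist"))],
    hp_params = unclass(config$hp_params),
    lp_params = unclass(config$lp_params),
    focal_day = focal_day,
    sweep = list(g_grid = g_grid, k_grid = k_grid,
                 n_sim_clones = n_sim_clones),
    null = list(kind = null_kind, n_replicates = n_null_replicates),
    output_md5 = as.list(tools::md5sum(file.path(out_dir, outputs))),
    timestamp = format(Sys.time(), tz = "UTC"))
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(clones = clones, sweeps = sweeps, ode_fits = ode_fits,
                 modality = modality_tab, heritability = herit,
                 calibration = calibration, manifest = manifest))
}
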