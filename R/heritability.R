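#' Overlap of the top decile of barcodes between two split samples
#'
#' Ranks barcodes by abundance within each sample, takes the top
#' `ceiling((1 - quantile) * n)` barcodes of each (ties broken by barcode
#' order for determinism), and reports the shared fraction. Because the two
#' top sets have equal size by construction, `|A ∩ B| / |A|` is symmetric;
#' the Jaccard form `|A ∩ B| / |A ∪ B|` is available as an option.
#'
#' @param sample_a,sample_b Per-barcode abundances over the same barcode
#'   universe (same length, >= 10 barcodes; names, when present, must
#'   match).
#' @param quantile Rank quantile defining "top" (default 0.9, i.e. top 10%).
#' @param denominator `"per_sample"` (`|A ∩ B| / |A|`, default) or
#'   `"union"` (Jaccard).
#' @return Overlap fraction in \[0, 1\].
#' @examples
#' top_decile_overlap(1:20, 1:20) # identical ranking -> 1
#' @export
top_decile_overlap <- function(sample_a, sample_b, quantile = 0.9,
                               denominator = c("per_sample", "union")) {
  denominator <- match.arg(denominator)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) != length(b))
    stop("samples must cover the same barcode universe", call. = FALSE)
  if (!is.null(names(sample_a)) && !is.null(names(sample_b)) &&
      !identical(names(sample_a), names(sample_b)))
    stop("barcode names differ between samples", call. = FALSE)
  n <- length(a)
  if (n < 10L) stop("need at least 10 barcodes", call. = FALSE)
  n_top <- ceiling((1 - quantile) * n)
  top_a <- order(-a, seq_len(n))[seq_len(n_top)]
  top_b <- order(-b, seq_len(n))[seq_len(n_top)]
  inter <- length(intersect(top_a, top_b))
  if (denominator == "per_sample") inter / n_top
  else inter / length(union(top_a, top_b))
}

#' Pearson correlation of barcode abundances between split samples
#'
#' @param sample_a,sample_b Per-barcode abundances (same barcode universe,
#'   >= 3 barcodes, nonzero variance in both).
#' @param normalize `"raw"` (default) or `"rpm"` (reads per million before
#'   correlating; use for sequencing read counts of unequal depth).
#' @return List with `pearson_r` and `pearson_p` (two-sided, t
#'   distribution).
#' @examples
#' abundance_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)) # r = 0.6
#' @export
abundance_correlation <- function(sample_a, sample_b,
                                  normalize = c("raw", "rpm")) {
  normalize <- match.arg(normalize)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) != length(b))
    stop("samples must cover the same barcode universe", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 barcodes", call. = FALSE)
  if (normalize == "rpm") {
    a <- a / sum(a) * 1e6
    b <- b / sum(b) * 1e6
  }
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance in a sample; correlation undefined", call. = FALSE)
  ct <- cor.test(a, b, method = "pearson")
  list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value)
}

#' Growth-rate distributions for heritability simulations
#'
#' Constructs the per-clone growth-rate law (in divisions over the assay,
#' i.e. log2 fold change) used by [simulate_split_experiment()]. Three
#' reference-based kinds mirror the non-heritable null variants:
#' * `"unimodal"` — Gaussian with the reference sample's moments,
#' * `"bimodal"` — Gaussian kernel density estimate of the reference
#'   (rule-of-thumb bandwidth), sampled by the smoothed bootstrap
#'   (resample + kernel jitter),
#' * `"stochastic"` — uniform resampling with replacement from the
#'   reference values.
#' A reference-free `"uniform"` kind draws uniformly from `range`
#' (default 0 to 5 divisions, the assay-length growth used when no
#' empirical division-count sample is supplied).
#'
#' @param kind Distribution kind.
#' @param reference Reference division-count sample (numeric or
#'   [clone_size_sample()] sizes, log2-transformed internally when a sample
#'   object is given). Required for the three reference-based kinds.
#' @param range Lower/upper divisions for `kind = "uniform"`.
#' @return A `growth_rate_dist` object.
#' @export
growth_rate_dist <- function(kind = c("stochastic", "unimodal", "bimodal",
                                      "uniform"),
                             reference = NULL, range = c(0, 5)) {
  kind <- match.arg(kind)
  if (kind != "uniform") {
    if (is.null(reference))
      stop("`reference` is required for kind = \"", kind, "\"",
           call. = FALSE)
    ref <- if (inherits(reference, "clone_size_sample"))
      log2(reference$sizes) else as.numeric(reference)
    if (length(ref) < 2L || any(!is.finite(ref)))
      stop("invalid reference sample", call. = FALSE)
    obj <- list(kind = kind, reference = ref,
                mu = mean(ref), sigma = sd(ref),
                bw = if (sd(ref) > 0) bw.nrd0(ref) else 0)
  } else {
    stopifnot(length(range) == 2L, range[1] <= range[2])
    obj <- list(kind = kind, range = as.numeric(range))
  }
  structure(obj, class = "growth_rate_dist")
}

#' Draw per-clone growth rates
#'
#' @param dist A [growth_rate_dist()].
#' @param n Number of draws.
#' @return Numeric vector of growth rates (divisions over the assay).
#' @export
draw_growth_rates <- function(dist, n) {
  stopifnot(inherits(dist, "growth_rate_dist"))
  switch(dist$kind,
         unimodal = rnorm(n, dist$mu, dist$sigma),
         bimodal = sample(dist$reference, n, replace = TRUE) +
           rnorm(n, 0, dist$bw),
         stochastic = sample(dist$reference, n, replace = TRUE),
         uniform = runif(n, dist$range[1], dist$range[2]))
}

#' Simulate a barcode expansion-and-split heritability experiment
#'
#' Each barcode starts as a single cell and expands through `pre_doublings`
#' doublings (default 4, i.e. 16 copies). Copies are split binomially
#' (p = 0.5) into samples A and B. Each barcode-in-sample then grows to
#' `round(initial_copies * 2^r)` cells, where the growth rate `r`
#' (divisions over the assay) is drawn once per barcode and shared by both
#' samples when `heritable = TRUE`, or drawn independently per sample when
#' `heritable = FALSE` (sibling cells forget their proliferative state).
#'
#' @param n_barcodes Number of barcodes (>= 10).
#' @param pre_doublings Doublings before the split (default 4).
#' @param growth_dist A [growth_rate_dist()]; default is uniform growth over
#'   0-5 divisions.
#' @param heritable Share growth rates across the split?
#' @param seed Integer seed; the run is fully determined by it.
#' @return A `split_experiment`: data.frame `counts` with columns
#'   `barcode_id`, `cells_a`, `cells_b`, `init_a`, `init_b`, plus vectors
#'   `growth_a`, `growth_b` and the call settings.
#' @examples
#' ex <- simulate_split_experiment(100, heritable = TRUE, seed = 1)
#' abundance_correlation(ex$counts$cells_a, ex$counts$cells_b)$pearson_r
#' @export
simulate_split_experiment <- function(n_barcodes, pre_doublings = 4,
                                      growth_dist = NULL, heritable = TRUE,
                                      seed = 1) {
  n_barcodes <- as.integer(n_barcodes)
  if (is.na(n_barcodes) || n_barcodes < 10L)
    stop("`n_barcodes` must be >= 10", call. = FALSE)
  if (is.null(growth_dist)) growth_dist <- growth_rate_dist("uniform")
  if (!inherits(growth_dist, "growth_rate_dist"))
    stop("`growth_dist` must be a growth_rate_dist object", call. = FALSE)
  set.seed(as.integer(seed))
  copies <- 2^pre_doublings
  init_a <- rbinom(n_barcodes, copies, 0.5)
  init_b <- copies - init_a
  r_a <- draw_growth_rates(growth_dist, n_barcodes)
  r_b <- if (heritable) r_a else draw_growth_rates(growth_dist, n_barcodes)
  # round half-up; fractional cells are not meaningful
  cells_a <- floor(init_a * 2^r_a + 0.5)
  cells_b <- floor(init_b * 2^r_b + 0.5)
  counts <- data.frame(
    barcode_id = sprintf("bc%0*d", nchar(n_barcodes), seq_len(n_barcodes)),
    cells_a = cells_a, cells_b = cells_b,
    init_a = init_a, init_b = init_b)
  structure(list(counts = counts, growth_a = r_a, growth_b = r_b,
                 pre_doublings = pre_doublings, heritable = heritable,
                 growth_dist = growth_dist, seed = as.integer(seed)),
            class = "split_experiment")
}

#' @export
print.split_experiment <- function(x, ...) {
  cat("Barcode split experiment:", nrow(x$counts), "barcodes,",
      2^x$pre_doublings, "copies pre-split,",
      if (x$heritable) "heritable" else "non-heritable",
      "growth (", x$growth_dist$kind, ")\n")
  invisible(x)
}

#' Non-heritable null distribution for the split-sample experiment
#'
#' Repeatedly simulates the expansion-and-split experiment with growth rates
#' redrawn independently per barcode-in-sample (no heritability), recording
#' the Pearson correlation and top-decile overlap of each replicate. When
#' observed paired samples are supplied, their statistics are computed and
#' compared against the null with the add-one empirical p-value
#' `(1 + #\{null >= observed\}) / (1 + n_replicates)`.
#'
#' Replicates whose simulated counts have zero variance (degenerate growth)
#' yield an undefined correlation; they are dropped from the null and
#' counted in `n_dropped`.
#'
#' @param sample_a,sample_b Optional observed per-barcode abundances (same
#'   barcode universe). When omitted only the null is returned.
#' @param reference Reference division-count sample (numeric log2 sizes or a
#'   [clone_size_sample()]) defining the growth-rate law.
#' @param kind Null growth-rate law: `"stochastic"`, `"unimodal"` or
#'   `"bimodal"` (see [growth_rate_dist()]).
#' @param n_replicates Null replicates (default 1000; < 100 warns).
#' @param n_barcodes Barcodes per replicate; defaults to the observed count,
#'   or 1000 when no observation is given.
#' @param pre_doublings Doublings before the split (default 4).
#' @param seed Master seed; replicate seeds are derived from it.
#' @return A `heritability_result`: observed `overlap_fraction`,
#'   `pearson_r`, `pearson_p` (NA when unobserved), `null_r`,
#'   `null_overlap`, `empirical_p_r`, `empirical_p_overlap`, `n_dropped`,
#'   and the settings.
#' @export
null_distribution <- function(sample_a = NULL, sample_b = NULL, reference,
                              kind = c("stochastic", "unimodal", "bimodal"),
                              n_replicates = 1000, n_barcodes = NULL,
                              pre_doublings = 4, seed = 1) {
  kind <- match.arg(kind)
  if (n_replicates < 100)
    warning("fewer than 100 replicates gives unstable empirical p-values",
            call. = FALSE)
  dist <- growth_rate_dist(kind, reference = reference)
  have_obs <- !is.null(sample_a) && !is.null(sample_b)
  if (have_obs) {
    obs_cor <- abundance_correlation(sample_a, sample_b)
    obs_overlap <- top_decile_overlap(sample_a, sample_b)
    if (is.null(n_barcodes)) n_barcodes <- length(sample_a)
  } else {
    obs_cor <- list(pearson_r = NA_real_, pearson_p = NA_real_)
    obs_overlap <- NA_real_
    if (is.null(n_barcodes)) n_barcodes <- 1000L
  }
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  null_r <- rep(NA_real_, n_replicates)
  null_overlap <- rep(NA_real_, n_replicates)
  for (i in seq_len(n_replicates)) {
    ex <- simulate_split_experiment(n_barcodes, pre_doublings, dist,
                                    heritable = FALSE, seed = rep_seeds[i])
    ca <- ex$counts$cells_a; cb <- ex$counts$cells_b
    if (sd(ca) > 0 && sd(cb) > 0) null_r[i] <- cor(ca, cb)
    null_overlap[i] <- top_decile_overlap(ca, cb)
  }
  n_dropped <- sum(is.na(null_r))
  valid_r <- null_r[!is.na(null_r)]
  emp_p_r <- if (have_obs)
    (1 + sum(valid_r >= obs_cor$pearson_r)) / (1 + n_replicates)
  else NA_real_
  emp_p_ov <- if (have_obs)
    (1 + sum(null_overlap >= obs_overlap)) / (1 + n_replicates)
  else NA_real_
  structure(list(overlap_fraction = obs_overlap,
                 pearson_r = obs_cor$pearson_r,
                 pearson_p = obs_cor$pearson_p,
                 null_r = null_r, null_overlap = null_overlap,
                 empirical_p_r = emp_p_r,
                 empirical_p_overlap = emp_p_ov,
                 n_dropped = n_dropped, kind = kind,
                 n_replicates = n_replicates, n_barcodes = n_barcodes,
                 pre_doublings = pre_doublings, seed = as.integer(seed)),
            class = "heritability_result")
}

#' @export
print.heritability_result <- function(x, ...) {
  cat("Heritability analysis (", x$kind, " null, ", x$n_replicates,
      " replicates, ", x$n_barcodes, " barcodes)\n", sep = "")
  if (!is.na(x$pearson_r)) {
    cat("  observed: r =", signif(x$pearson_r, 3),
        "| top-decile overlap =", signif(x$overlap_fraction, 3), "\n")
    cat("  empirical p (r) =", signif(x$empirical_p_r, 3),
        "| empirical p (overlap) =", signif(x$empirical_p_overlap, 3), "\n")
  }
  cat("  null: mean r =", signif(mean(x$null_r, na.rm = TRUE), 3),
      "| mean overlap =", signif(mean(x$null_overlap, na.rm = TRUE), 3),
      if (x$n_dropped > 0) paste0("| ", x$n_dropped, " degenerate dropped"),
      "\n")
  invisible(x)
}
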