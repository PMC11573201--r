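#' Convert clone sizes to division counts
#'
#' The study's size axis is log2 of the cell count per clone, referred to as
#' the number of cell divisions. Single-cell clones (which carry no growth
#' information and are filtered from the imaging analysis) can be dropped
#' before the transform.
#'
#' @param sizes Cells per clone (>= 1), numeric or [clone_size_sample()].
#' @param drop_singletons Remove size-1 clones before transforming.
#' @return Numeric division counts, one per retained clone.
#' @examples
#' log2_divisions(c(1, 8), drop_singletons = TRUE) # 3
#' @export
log2_divisions <- function(sizes, drop_singletons = FALSE) {
  if (inherits(sizes, "clone_size_sample")) sizes <- sizes$sizes
  sizes <- as.numeric(sizes)
  if (any(!is.finite(sizes)) || any(sizes < 1))
    stop("all clone sizes must be finite and >= 1", call. = FALSE)
  if (drop_singletons) {
    n_dropped <- sum(sizes == 1)
    if (n_dropped > 0)
      message(n_dropped, " singleton clone(s) dropped")
    sizes <- sizes[sizes > 1]
  }
  log2(sizes)
}

#' Classify clones as highly vs less proliferative
#'
#' Without a reference, the largest `ceiling((1 - quantile) * n)` clones are
#' labelled `highly_proliferative` (top 10% by default), with ties broken by
#' stable input order. With a reference sample, the threshold is the
#' reference's nearest-rank quantile and every clone at or above it is
#' labelled, so the labelled fraction can differ from `1 - quantile` (the
#' control-derived cutoff convention).
#'
#' @param sizes Cells per clone, numeric or [clone_size_sample()].
#' @param quantile Size quantile defining the cutoff (default 0.9).
#' @param reference Optional reference sizes from which the threshold is
#'   taken instead.
#' @return Character vector of labels (`"highly_proliferative"` /
#'   `"less_proliferative"`), with attribute `threshold`.
#' @examples
#' table(classify_proliferative(1:100))
#' @export
classify_proliferative <- function(sizes, quantile = 0.9, reference = NULL) {
  if (inherits(sizes, "clone_size_sample")) sizes <- sizes$sizes
  sizes <- as.numeric(sizes)
  n <- length(sizes)
  if (n == 0L) stop("`sizes` must be nonempty", call. = FALSE)
  labels <- rep("less_proliferative", n)
  if (is.null(reference)) {
    if (quantile == 0.9 && n < 10L)
      stop("need at least 10 clones for a top-decile split", call. = FALSE)
    n_top <- ceiling((1 - quantile) * n)
    ord <- order(-sizes, seq_len(n)) # stable: ties by input order
    top <- ord[seq_len(n_top)]
    threshold <- sizes[ord[n_top]]
    boundary_ties <- sum(sizes == threshold)
    if (n_top < n && sizes[ord[n_top + 1L]] == threshold)
      warning(boundary_ties, " clones tie at the threshold size ",
              threshold, "; top set resolved by input order", call. = FALSE)
    labels[top] <- "highly_proliferative"
  } else {
    if (inherits(reference, "clone_size_sample")) reference <- reference$sizes
    ref <- sort(as.numeric(reference))
    idx <- ceiling(quantile * length(ref)) # nearest-rank quantile
    threshold <- ref[max(idx, 1L)]
    labels[sizes >= threshold] <- "highly_proliferative"
  }
  attr(labels, "threshold") <- threshold
  labels
}

#' Calibrate spike-in barcodes: reads per cell
#'
#' Fits the least-squares line of read counts on the known spike-in cell
#' numbers (e.g. the 50/500/1000-cell ladder), giving the reads-per-cell
#' slope used to estimate cell numbers for every other barcode.
#'
#' @param table data.frame with columns `reads`, `is_spikein` and the known
#'   spike-in cell numbers in `true_cells` (or `spikein_true_cells`);
#'   typically a [read_barcode_table()] output or one sample of
#'   [gen_barcode_experiment()].
#' @return A `spikein_calibration`: `reads_per_cell` (slope), `intercept`,
#'   `fit_r` (Pearson correlation of reads and known cells), `n_points`.
#' @examples
#' tab <- data.frame(reads = c(5000, 50000, 100000),
#'                   is_spikein = TRUE,
#'                   spikein_true_cells = c(50, 500, 1000))
#' calibrate_spikeins(tab)
#' @export
calibrate_spikeins <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("reads", "is_spikein") %in% names(table)))
  cells_col <- intersect(c("true_cells", "spikein_true_cells"),
                         names(table))[1]
  if (is.na(cells_col))
    stop("no `true_cells` (or `spikein_true_cells`) column", call. = FALSE)
  sp <- table[table$is_spikein %in% TRUE, , drop = FALSE]
  sp$spikein_true_cells <- sp[[cells_col]]
  if (length(unique(sp$spikein_true_cells)) < 2L)
    stop("calibration needs spike-ins at >= 2 distinct cell levels",
         call. = FALSE)
  fit <- lm(reads ~ spikein_true_cells, data = sp)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration produced a non-positive reads-per-cell slope",
         call. = FALSE)
  structure(list(reads_per_cell = slope,
                 intercept = unname(coef(fit)[1]),
                 fit_r = cor(sp$spikein_true_cells, sp$reads),
                 n_points = nrow(sp)),
            class = "spikein_calibration")
}

#' @export
print.spikein_calibration <- function(x, ...) {
  cat("Spike-in calibration:", signif(x$reads_per_cell, 4), "reads/cell",
      "(intercept", signif(x$intercept, 3), ", r =", signif(x$fit_r, 4),
      ",", x$n_points, "points)\n")
  invisible(x)
}

#' Estimate cell numbers from read counts via a spike-in calibration
#'
#' Back-calculates `(reads - intercept) / reads_per_cell`, floored at zero.
#' Barcodes whose raw back-calculation is negative are flagged in the
#' `negative_backcalc` attribute for QC.
#'
#' @param calibration A [calibrate_spikeins()] result.
#' @param reads Read counts.
#' @return Estimated cell numbers (>= 0) with attribute
#'   `negative_backcalc`.
#' @export
estimate_cells <- function(calibration, reads) {
  stopifnot(inherits(calibration, "spikein_calibration"))
  raw <- (as.numeric(reads) - calibration$intercept) /
    calibration$reads_per_cell
  out <- pmax(0, raw)
  attr(out, "negative_backcalc") <- raw < 0
  out
}

#' Grouped summaries of division-count distributions
#'
#' Summarises a clone table (one row per clone) per group: clone count,
#' mean/median division counts, the top-decile size threshold, and
#' unit-division histogram counts.
#'
#' @param records data.frame with an `n_cells` column plus the grouping
#'   columns.
#' @param group_keys Character vector of grouping column names.
#' @return data.frame with one row per group (`n`, `mean_divisions`,
#'   `median_divisions`, `top_decile_threshold`) and attribute `histograms`,
#'   a named list of per-group division-count histogram tables (unit bins).
#' @examples
#' tab <- data.frame(day = 8, n_cells = c(2, 4, 8))
#' summarize_by_group(tab, "day")
#' @export
summarize_by_group <- function(records, group_keys) {
  stopifnot(is.data.frame(records), "n_cells" %in% names(records))
  missing_keys <- setdiff(group_keys, names(records))
  if (length(missing_keys) > 0)
    stop("unknown group key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  key <- interaction(records[group_keys], drop = TRUE, sep = "|")
  groups <- split(records$n_cells, key)
  summ <- do.call(rbind, lapply(names(groups), function(gname) {
    sizes <- groups[[gname]]
    div <- log2(sizes)
    srt <- sort(sizes)
    thr <- srt[max(ceiling(0.9 * length(srt)), 1L)]
    keyvals <- strsplit(gname, "|", fixed = TRUE)[[1]]
    out <- as.data.frame(as.list(setNames(keyvals, group_keys)),
                         stringsAsFactors = FALSE)
    cbind(out, data.frame(n = length(sizes),
                          mean_divisions = mean(div),
                          median_divisions = median(div),
                          top_decile_threshold = thr))
  }))
  attr(summ, "histograms") <- lapply(groups, function(sizes) {
    table(cut(log2(sizes), breaks = seq(0, ceiling(max(log2(sizes))) + 1),
              right = FALSE))
  })
  rownames(summ) <- NULL
  summ
}
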