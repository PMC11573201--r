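#' Parameters of the two-state clone growth model
#'
#' The two-state model describes a clone founded by a single proliferative
#' cell. Each proliferative cell (X) divides at per-capita rate `g` (per day)
#' or irreversibly transitions to a non-proliferative state (Y) at per-capita
#' rate `k` (per day). Arrested cells never re-enter the cycle and cell death
#' is assumed negligible, so the total clone size `x + y` never decreases.
#' An optional carrying capacity `K` turns the division rate logistic:
#' the division propensity is multiplied by `max(0, 1 - (x + y) / K)`.
#'
#' @param g Per-capita division rate, 1/day. Must be >= 0.
#' @param k Per-capita transition (arrest) rate, 1/day. Must be >= 0.
#' @param K Optional carrying capacity in cells; `NULL` for the pure
#'   two-parameter model.
#' @return An object of class `two_state_params`.
#' @examples
#' two_state_params(g = 0.74, k = 0)
#' two_state_params(g = 0.746, k = 0.156, K = 126)
#' @export
two_state_params <- function(g, k, K = NULL) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (g < 0) stop("division rate `g` must be nonnegative", call. = FALSE)
  if (k < 0) stop("transition rate `k` must be nonnegative", call. = FALSE)
  if (!is.null(K)) {
    stopifnot(is.numeric(K), length(K) == 1L, is.finite(K))
    if (K <= 0) stop("carrying capacity `K` must be positive", call. = FALSE)
  }
  structure(list(g = g, k = k, K = K), class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat("Two-state growth parameters: g =", x$g, "/day, k =", x$k, "/day")
  if (!is.null(x$K)) cat(", K =", x$K, "cells")
  cat("\n")
  invisible(x)
}

#' Reaction propensities of the two-state model
#'
#' Returns the instantaneous rates of the two reactions given the current
#' state: division fires at `g * x` (scaled by the logistic factor
#' `max(0, 1 - (x + y) / K)` when a carrying capacity is set) and transition
#' to arrest fires at `k * x`.
#'
#' @param x Current number of proliferative cells (>= 0).
#' @param params A [two_state_params()] object.
#' @param y Current number of non-proliferative cells; only used for the
#'   logistic capacity factor.
#' @return Named numeric vector `c(division, transition)`.
#' @examples
#' propensities(10, two_state_params(0.65, 0.3))
#' @export
propensities <- function(x, params, y = 0) {
  stopifnot(inherits(params, "two_state_params"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("proliferative cell count `x` must be a single nonnegative number",
         call. = FALSE)
  if (!is.numeric(y) || length(y) != 1L || !is.finite(y) || y < 0)
    stop("`y` must be a single nonnegative number", call. = FALSE)
  phi <- 1
  if (!is.null(params$K)) phi <- max(0, 1 - (x + y) / params$K)
  c(division = params$g * x * phi, transition = params$k * x)
}

.reason_labels <- c("t_max", "absorbed", "t_max")

#' Simulate a single clone trajectory (Gillespie algorithm)
#'
#' Exact stochastic simulation of one clone founded by a single proliferative
#' cell, run until either all cells are arrested (absorption at x = 0) or the
#' maximum time is reached. Waiting times are exponential with rate equal to
#' the total propensity and the reaction fired is chosen proportionally to
#' its propensity.
#'
#' @param params A [two_state_params()] object.
#' @param t_max Maximum simulated time, days (> 0).
#' @param seed Integer RNG seed; identical `(params, t_max, seed)` reproduce
#'   the identical trajectory.
#' @param max_cells Hard cap on total cells guarding against runaway
#'   supercritical runs (default 1e6). Hitting the cap terminates the run
#'   with `terminated_reason = "t_max"` and a warning.
#' @return A `gillespie_trajectory`: list with `times`, `x_counts`,
#'   `y_counts`, `seed` and `terminated_reason` (`"absorbed"` or `"t_max"`).
#' @examples
#' tr <- simulate_clone(two_state_params(0.65, 0.3), t_max = 8, seed = 1)
#' tail(tr$x_counts + tr$y_counts, 1) # final clone size
#' @export
simulate_clone <- function(params, t_max, seed, max_cells = 1e6) {
  stopifnot(inherits(params, "two_state_params"))
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) ||
      t_max <= 0)
    stop("`t_max` must be a single positive number of days", call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)
  K <- if (is.null(params$K)) -1 else params$K
  raw <- cpp_simulate_clone(params$g, params$k, K, t_max, max_cells)
  if (raw$reason == 2L)
    warning("cell cap (", max_cells, ") hit; trajectory truncated",
            call. = FALSE)
  structure(list(times = raw$times, x_counts = raw$x_counts,
                 y_counts = raw$y_counts, seed = seed,
                 terminated_reason = .reason_labels[raw$reason + 1L]),
            class = "gillespie_trajectory")
}

#' A sample of clone sizes for one condition and day
#'
#' The empirical object all distribution fitting is done against: cell
#' counts per clone at a fixed observation day.
#'
#' @param sizes Positive cells-per-clone counts.
#' @param day Observation day (or `NA`).
#' @param label Condition label, e.g. `"highly_proliferative"`.
#' @return An object of class `clone_size_sample`.
#' @export
clone_size_sample <- function(sizes, day = NA_real_, label = "") {
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L) stop("`sizes` must be nonempty", call. = FALSE)
  if (any(!is.finite(sizes)) || any(sizes < 1))
    stop("all clone sizes must be finite and >= 1", call. = FALSE)
  structure(list(sizes = sizes, day = day, label = label),
            class = "clone_size_sample")
}

#' @export
print.clone_size_sample <- function(x, ...) {
  cat("Clone-size sample:", length(x$sizes), "clones",
      if (!is.na(x$day)) paste0("(day ", x$day, ")"), x$label, "\n")
  cat("  size range", min(x$sizes), "-", max(x$sizes),
      "| median", median(x$sizes), "\n")
  invisible(x)
}

#' Simulate an ensemble of independent clones
#'
#' Runs [simulate_clone()]-equivalent dynamics for `n_clones` independent
#' clones (final states only) and returns their sizes at `t_obs`. The clone
#' size reported downstream is the total `x + y`: fixed-plate nuclear counts
#' cannot distinguish cycling from arrested cells. The proliferative-only
#' counts are kept as attributes for the alternative convention.
#'
#' @inheritParams simulate_clone
#' @param n_clones Number of clones (>= 1).
#' @param t_obs Observation time, days.
#' @param label Condition label passed to the returned sample.
#' @return A [clone_size_sample()] with attributes `x_final`, `y_final`,
#'   `absorbed` (logical) and `seed`.
#' @examples
#' s <- simulate_ensemble(two_state_params(0.65, 0.3), 200, t_obs = 8, seed = 1)
#' mean(s$sizes)
#' @export
simulate_ensemble <- function(params, n_clones, t_obs, seed,
                              max_cells = 1e6, label = "") {
  stopifnot(inherits(params, "two_state_params"))
  n_clones <- as.integer(n_clones)
  if (is.na(n_clones) || n_clones < 1L)
    stop("`n_clones` must be >= 1", call. = FALSE)
  if (!is.numeric(t_obs) || t_obs <= 0)
    stop("`t_obs` must be positive", call. = FALSE)
  seed <- as.integer(seed)
  set.seed(seed)
  K <- if (is.null(params$K)) -1 else params$K
  fin <- cpp_simulate_finals(params$g, params$k, K, n_clones, t_obs,
                             max_cells)
  if (any(fin[, 4] > 0))
    warning(sum(fin[, 4]), " clone(s) hit the cell cap (", max_cells, ")",
            call. = FALSE)
  out <- clone_size_sample(fin[, 1] + fin[, 2], day = t_obs, label = label)
  attr(out, "x_final") <- fin[, 1]
  attr(out, "y_final") <- fin[, 2]
  attr(out, "absorbed") <- fin[, 3] > 0
  attr(out, "seed") <- seed
  out
}
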