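#' Mean-field ODE solution of the two-state model
#'
#' Deterministic counterpart of the stochastic two-state model. With
#' `model_kind = "exponential"`:
#' \deqn{dX/dt = (g - k) X, \qquad dY/dt = k X}
#' whose solution is the closed-form exponential
#' `X(t) = x0 exp((g - k) t)`. With `model_kind = "logistic_rate"` the
#' division rate saturates with total clone size `N = X + Y`:
#' \deqn{dX/dt = g X (1 - N/K) - k X, \qquad dY/dt = k X.}
#'
#' @param params A [two_state_params()]; `K` is required for
#'   `"logistic_rate"` and ignored (must be absent) for `"exponential"`.
#' @param times Nonnegative, increasing times (days). A leading 0 is added
#'   internally if absent.
#' @param x0 Initial proliferative cells at t = 0 (> 0).
#' @param model_kind `"exponential"` or `"logistic_rate"`; defaults to
#'   logistic when `params$K` is set.
#' @param rtol,atol Integrator tolerances (lsoda).
#' @return data.frame with columns `time`, `X`, `Y`, `total`.
#' @examples
#' solve_two_state_ode(two_state_params(0.7, 0), times = 0:4)
#' @export
solve_two_state_ode <- function(params, times, x0 = 1,
                                model_kind = if (is.null(params$K))
                                  "exponential" else "logistic_rate",
                                rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(params, "two_state_params"))
  model_kind <- match.arg(model_kind, c("exponential", "logistic_rate"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("`times` must be finite and nonnegative", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (x0 <= 0) stop("`x0` must be positive", call. = FALSE)
  if (model_kind == "logistic_rate" && is.null(params$K))
    stop("logistic_rate model requires a carrying capacity `K`",
         call. = FALSE)
  had_zero <- length(times) > 0 && times[1] == 0
  tt <- if (had_zero) times else c(0, times)
  deriv <- if (model_kind == "exponential") {
    function(t, state, p) {
      list(c(dX = (p$g - p$k) * state[1], dY = p$k * state[1]))
    }
  } else {
    function(t, state, p) {
      phi <- 1 - (state[1] + state[2]) / p$K
      list(c(dX = p$g * state[1] * phi - p$k * state[1],
             dY = p$k * state[1]))
    }
  }
  sol <- deSolve::ode(y = c(X = x0, Y = 0), times = tt, func = deriv,
                      parms = params, rtol = rtol, atol = atol)
  sol <- as.data.frame(sol)
  if (!had_zero) sol <- sol[-1L, , drop = FALSE]
  data.frame(time = sol$time, X = sol$X, Y = sol$Y, total = sol$X + sol$Y,
             row.names = NULL)
}

#' Observed mean growth curve
#'
#' @param times Strictly increasing days.
#' @param values Mean cells per clone at each time (>= 0).
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("growth curve contains non-finite values", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("`values` must be >= 0", call. = FALSE)
  structure(list(times = times, values = values), class = "growth_curve")
}

#' Least-squares fit of a growth ODE model to a mean growth curve
#'
#' Integrates the chosen model from a single founding cell at t = 0 and
#' minimises the sum of squared differences between the model's total clone
#' size and the observed curve. Multi-start local optimisation (L-BFGS-B)
#' mitigates local minima; starts are drawn uniformly within the bounds from
#' a seeded stream, with `initial_guess` (when given) as the first start.
#'
#' Optimisation is Levenberg-Marquardt least squares
#' (\pkg{minpack.lm}) within box bounds.
#'
#' @param model_kind `"exponential"` (free parameters g, k) or
#'   `"logistic_rate"` (g, k, K).
#' @param curve A [growth_curve()] (or data.frame with `time`/`day` and
#'   `mean_cells` columns).
#' @param initial_guess Optional [two_state_params()] used as first start.
#' @param bounds List with elements `g`, `k` (and `K` for logistic), each a
#'   `c(lower, upper)` pair. Defaults: g, k in \[0, 2\] /day, K in
#'   \[2, 1e4\] cells.
#' @param n_starts Number of optimisation starts (default 10).
#' @param seed Seed for the start draws.
#' @param log_scale Compute the cost on log10(1 + cells); useful since clone
#'   sizes span orders of magnitude.
#' @param x0 Founding proliferative cells (default 1).
#' @return An `ode_fit`: `model_kind`, `params` ([two_state_params()]),
#'   `cost` (sum of squared residuals, cells^2), `converged`, `n_starts`,
#'   plus `doubling_time` = ln 2 / (g - k) days (NA when g <= k).
#' @examples
#' cv <- growth_curve(1:6, exp(0.5 * (1:6)))
#' fit_growth_model("exponential", cv, seed = 1)
#' @export
fit_growth_model <- function(model_kind = c("exponential", "logistic_rate"),
                             curve, initial_guess = NULL, bounds = NULL,
                             n_starts = 10, seed = 1, log_scale = FALSE,
                             x0 = 1) {
  model_kind <- match.arg(model_kind)
  if (is.data.frame(curve)) {
    tcol <- intersect(c("time", "day"), names(curve))[1]
    vcol <- intersect(c("mean_cells", "value", "values"), names(curve))[1]
    if (is.na(tcol) || is.na(vcol))
      stop("curve data.frame needs time/day and mean_cells columns",
           call. = FALSE)
    curve <- growth_curve(curve[[tcol]], curve[[vcol]])
  }
  stopifnot(inherits(curve, "growth_curve"))
  n_par <- if (model_kind == "exponential") 2L else 3L
  if (length(curve$times) < n_par)
    stop("curve needs at least ", n_par, " points for ", model_kind,
         call. = FALSE)
  default_bounds <- list(g = c(0, 2), k = c(0, 2), K = c(2, 1e4))
  if (is.null(bounds)) bounds <- default_bounds
  bounds <- utils::modifyList(default_bounds, bounds)
  lower <- c(bounds$g[1], bounds$k[1], if (n_par == 3L) bounds$K[1])
  upper <- c(bounds$g[2], bounds$k[2], if (n_par == 3L) bounds$K[2])

  resid_fn <- function(par) {
    p <- two_state_params(max(par[1], 0), max(par[2], 0),
                          K = if (n_par == 3L) max(par[3], 2) else NULL)
    sol <- tryCatch(
      solve_two_state_ode(p, curve$times, x0 = x0, model_kind = model_kind),
      error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol$total)))
      return(rep(1e6, length(curve$values)))
    if (log_scale) log10(1 + sol$total) - log10(1 + curve$values)
    else sol$total - curve$values
  }

  set.seed(as.integer(seed))
  starts <- replicate(n_starts, runif(n_par, lower, upper), simplify = FALSE)
  if (!is.null(initial_guess)) {
    stopifnot(inherits(initial_guess, "two_state_params"))
    starts[[1]] <- c(initial_guess$g, initial_guess$k,
                     if (n_par == 3L) initial_guess$K)
  }
  best <- NULL
  best_ok <- FALSE
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(st, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) {
      best <- res
      best_ok <- res$info %in% 1:3
    }
  }
  if (is.null(best))
    return(structure(list(model_kind = model_kind, params = NULL,
                          cost = NA_real_, converged = FALSE,
                          n_starts = n_starts,
                          message = "all optimisation starts failed"),
                     class = "ode_fit"))
  par <- pmin(pmax(coef(best), lower), upper)
  params <- two_state_params(par[1], par[2],
                             K = if (n_par == 3L) par[3] else NULL)
  gk <- params$g - params$k
  structure(list(model_kind = model_kind, params = params,
                 cost = best$deviance,
                 converged = best_ok,
                 n_starts = n_starts,
                 doubling_time = if (gk > 0) log(2) / gk else NA_real_),
            class = "ode_fit")
}

#' @export
print.ode_fit <- function(x, ...) {
  cat("Growth ODE fit (", x$model_kind, ")\n", sep = "")
  if (is.null(x$params)) {
    cat("  fit failed:", x$message, "\n")
    return(invisible(x))
  }
  cat("  g =", signif(x$params$g, 4), ", k =", signif(x$params$k, 4))
  if (!is.null(x$params$K)) cat(", K =", signif(x$params$K, 5))
  cat("\n  cost (SSR) =", signif(x$cost, 4),
      "| converged:", x$converged, "\n")
  if (!is.na(x$doubling_time))
    cat("  net doubling time =", signif(x$doubling_time, 4), "days\n")
  invisible(x)
}
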