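#' Sarle's bimodality coefficient with modality call
#'
#' Computes the finite-sample bimodality coefficient
#' \deqn{BC = \frac{s^2 + 1}{k_e + \frac{3 (n-1)^2}{(n-2)(n-3)}}}
#' where `s` is the bias-corrected sample skewness and `k_e` the
#' bias-corrected sample excess kurtosis. Values above 5/9 (the asymptotic
#' value for a uniform distribution) suggest bimodality, values below 1/3
#' (the Gaussian value) suggest unimodality, and values in between are
#' called ambiguous.
#'
#' @param data Numeric sample (n >= 4, nonzero variance); conventionally the
#'   log2 division counts of clones.
#' @return A `modality_call`: list with `coefficient` and `call`
#'   (`"bimodal"`, `"ambiguous"` or `"unimodal"`).
#' @examples
#' bimodality_coefficient(c(rnorm(500, 0), rnorm(500, 8)))
#' @export
bimodality_coefficient <- function(data) {
  data <- as.numeric(data)
  n <- length(data)
  if (n < 4L)
    stop("bimodality coefficient needs at least 4 observations",
         call. = FALSE)
  if (any(!is.finite(data)))
    stop("`data` contains non-finite values", call. = FALSE)
  if (var(data) == 0)
    stop("`data` has zero variance; coefficient undefined", call. = FALSE)
  s <- e1071::skewness(data, type = 2)
  ke <- e1071::kurtosis(data, type = 2)
  coef <- (s^2 + 1) / (ke + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  call <- if (coef > 5 / 9) "bimodal"
          else if (coef < 1 / 3) "unimodal"
          else "ambiguous"
  structure(list(coefficient = coef, call = call), class = "modality_call")
}

#' @export
print.modality_call <- function(x, ...) {
  cat("Bimodality coefficient:", signif(x$coefficient, 4), "->", x$call,
      "(thresholds: > 5/9 bimodal, < 1/3 unimodal)\n")
  invisible(x)
}

#' Gaussian mixture model of division counts with BIC model selection
#'
#' Fits univariate Gaussian mixtures (unequal variances) by
#' expectation-maximisation for each candidate component count and selects
#' the count minimising BIC = -2 logL + p ln n, with p = 3k - 1 free
#' parameters for k components (k means, k variances, k - 1 weights). The EM
#' engine is \pkg{mclust} (model "V").
#'
#' @param data Numeric sample, conventionally log2 division counts
#'   (n >= 10).
#' @param candidate_components Component counts to try (default 1:3).
#' @param seed Seed for the (deterministic) initialisation; kept for
#'   reproducibility bookkeeping.
#' @return A `gmm_fit`: `n_components`, `means`, `variances`, `weights`,
#'   `bic_by_k` (named by candidate), `loglik`, `seed`. Candidates with
#'   fewer than `2 * k` observations are skipped with a warning.
#' @examples
#' fit_gmm(c(rnorm(300, 0), rnorm(300, 10)), candidate_components = 1:3)
#' @export
fit_gmm <- function(data, candidate_components = 1:3, seed = 1) {
  data <- as.numeric(data)
  n <- length(data)
  if (n < 10L) stop("GMM fit needs at least 10 observations", call. = FALSE)
  if (length(candidate_components) < 1L)
    stop("at least one candidate component count is required", call. = FALSE)
  candidate_components <- sort(unique(as.integer(candidate_components)))
  keep <- candidate_components * 2L <= n
  if (!all(keep)) {
    warning("skipping candidate component count(s) ",
            paste(candidate_components[!keep], collapse = ", "),
            ": fewer than 2k observations", call. = FALSE)
    candidate_components <- candidate_components[keep]
  }
  if (length(candidate_components) == 0L)
    stop("no feasible candidate component counts", call. = FALSE)
  set.seed(as.integer(seed))
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller frame
  bic_by_k <- setNames(rep(NA_real_, length(candidate_components)),
                       candidate_components)
  fits <- vector("list", length(candidate_components))
  for (i in seq_along(candidate_components)) {
    k <- candidate_components[i]
    fit <- tryCatch(
      suppressWarnings(mclust::Mclust(data, G = k,
                                      modelNames = if (k == 1L) "X" else "V",
                                      verbose = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    p <- 3 * k - 1
    bic_by_k[i] <- -2 * fit$loglik + p * log(n)
    fits[[i]] <- fit
  }
  if (all(is.na(bic_by_k)))
    stop("EM failed for every candidate component count", call. = FALSE)
  best_i <- which.min(bic_by_k)
  fit <- fits[[best_i]]
  k <- candidate_components[best_i]
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1L) vars <- rep(vars, k)
  w <- fit$parameters$pro
  structure(list(n_components = k,
                 means = unname(fit$parameters$mean),
                 variances = unname(vars),
                 weights = unname(w / sum(w)),
                 bic_by_k = bic_by_k,
                 loglik = fit$loglik,
                 seed = as.integer(seed)),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("Gaussian mixture fit:", x$n_components, "component(s) selected by BIC\n")
  cat("  means:  ", paste(signif(x$means, 4), collapse = ", "), "\n")
  cat("  weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}
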