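# Independent oracles used across the suite.

# Brute-force two-sample KS statistic: sup |F_a - F_b| over all breakpoints.
brute_force_ks <- function(a, b) {
  z <- sort(unique(c(a, b)))
  max(abs(vapply(z, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# Closed-form mean-field solution of the exponential two-state model.
closed_X <- function(g, k, t, x0 = 1) x0 * exp((g - k) * t)
closed_Y <- function(g, k, t, x0 = 1) {
  if (g == k) x0 * k * t else x0 * k / (g - k) * (exp((g - k) * t) - 1)
}
closed_total <- function(g, k, t, x0 = 1) {
  closed_X(g, k, t, x0) + closed_Y(g, k, t, x0)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
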