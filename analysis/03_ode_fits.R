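#!/usr/bin/env Rscript
# Stage 3: deterministic growth-model fits.
#
# Builds the mean growth curve per clone class from the stage-1 table and
# fits (a) the exponential two-state ODE model and (b) the
# logistic-growth-rate model in which the division rate saturates with
# total clone size. Writes results/ode_fits.json.

suppressPackageStartupMessages(library(clonedyn))

clones <- read_clone_table("results/clone_sizes.tsv")

fits <- list()
for (cls in unique(clones$condition)) {
  sub <- clones[clones$condition == cls, ]
  curve_df <- aggregate(n_cells ~ day, data = sub, FUN = mean)
  cv <- growth_curve(curve_df$day, curve_df$n_cells)
  cat("==", cls, "mean curve:",
      paste(sprintf("day %g: %.1f", cv$times, cv$values), collapse = "; "),
      "\n")
  fe <- fit_growth_model("exponential", cv, seed = 99)
  fl <- fit_growth_model("logistic_rate", cv, seed = 99)
  print(fe); print(fl)
  pick <- if (fl$cost < fe$cost) "logistic_rate" else "exponential"
  cat("   lower-cost model:", pick, "\n\n")
  fits[[cls]] <- lapply(list(exponential = fe, logistic_rate = fl),
                        function(f) list(g = f$params$g, k = f$params$k,
                                         K = f$params$K, cost = f$cost,
                                         doubling_time = f$doubling_time,
                                         converged = f$converged))
}
jsonlite::write_json(fits, "results/ode_fits.json", auto_unbox = TRUE,
                     digits = NA, null = "null")
cat("Wrote results/ode_fits.json\n")
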