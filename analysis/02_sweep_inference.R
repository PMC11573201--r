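#!/usr/bin/env Rscript
# Stage 2: infer (g, k) per clone class by Kolmogorov-Smirnov sweep.
#
# For each clone class at day 8, simulates 500 clones per grid point over
# g, k in {0, 0.05, ..., 1} and scores the simulated size distribution
# against the observed one; the best fit minimises the KS statistic.
# Expects results/clone_sizes.tsv from stage 1. Writes
# results/sweep_<class>.tsv and results/sweep_best.tsv.

suppressPackageStartupMessages(library(clonedyn))

clones <- read_clone_table("results/clone_sizes.tsv")
day8 <- clones[clones$day == 8, ]

best_rows <- list()
for (cls in unique(day8$condition)) {
  obs <- clone_size_sample(day8$n_cells[day8$condition == cls], day = 8,
                           label = cls)
  # observed sizes were singleton-filtered at load; apply the same filter
  # to the simulated ensembles so both sides share the convention
  sw <- parameter_sweep(obs, n_sim_clones = 500, seed = 4711,
                        drop_sim_singletons = TRUE)
  write.table(as.data.frame(sw), sprintf("results/sweep_%s.tsv", cls),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(cls, ": best fit g =", sw$best$g, ", k =", sw$best$k,
      "(KS =", signif(sw$best_stat, 3), ", p =", signif(sw$best_pvalue, 3),
      ")\n")
  best_rows[[cls]] <- data.frame(condition = cls, g = sw$best$g,
                                 k = sw$best$k, ks_stat = sw$best_stat,
                                 p_value = sw$best_pvalue)
}
write.table(do.call(rbind, best_rows), "results/sweep_best.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nThe exponential class should recover k near 0; the arrest-prone",
    "class a clearly positive k (plateaus along compensating (g, k)",
    "directions are expected).\n")
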