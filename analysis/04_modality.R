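#!/usr/bin/env Rscript
# Stage 4: modality of the division-count distributions.
#
# Per observation day: Sarle's bimodality coefficient (calls bimodal above
# 5/9, unimodal below 1/3) and a Gaussian mixture fit with BIC selection of
# the component count. Writes results/modality.tsv.

suppressPackageStartupMessages(library(clonedyn))

clones <- read_clone_table("results/clone_sizes.tsv")

rows <- lapply(sort(unique(clones$day)), function(d) {
  div <- log2_divisions(clones$n_cells[clones$day == d])
  bc <- bimodality_coefficient(div)
  gmm <- fit_gmm(div, candidate_components = 1:3, seed = 11)
  cat(sprintf("day %2g: n = %3d  BC = %.3f (%s)  GMM: %d component(s), means %s, weights %s\n",
              d, length(div), bc$coefficient, bc$call, gmm$n_components,
              paste(signif(gmm$means, 3), collapse = "/"),
              paste(signif(gmm$weights, 2), collapse = "/")))
  data.frame(day = d, n = length(div),
             bimodality_coefficient = bc$coefficient, call = bc$call,
             gmm_components = gmm$n_components,
             gmm_means = paste(signif(gmm$means, 4), collapse = ","),
             gmm_weights = paste(signif(gmm$weights, 3), collapse = ","))
})
tab <- do.call(rbind, rows)
write.table(tab, "results/modality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Wrote results/modality.tsv\n")
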