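#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis of the CLL case (n = 1000 draws):
# cost-effectiveness plane and acceptability curve.
# Writes results/cll_psa_draws.tsv, results/cll_ceac.tsv and figures.

suppressPackageStartupMessages(library(earlyhta))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

params <- cll_parameter_set()
samples <- psa(build_cll_model, params, n = 1000, seed = 2026)
print(samples)

write.table(samples$draws, "results/cll_psa_draws.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

curve <- ceac(samples)
write.table(curve, "results/cll_ceac.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

quadrants <- with(samples$draws, table(
  cost = ifelse(delta_cost > 0, "higher cost", "lower cost"),
  effect = ifelse(delta_qaly > 0, "more QALYs", "fewer QALYs")))
cat("\nCE-plane quadrant counts:\n"); print(quadrants)
cat(sprintf("\nProbability cost-effective at lambda = 50,000: %.3f; at 100,000: %.3f\n",
            curve$probability[curve$lambda == 50000],
            curve$probability[curve$lambda == 100000]))

ggplot2::ggsave("results/figures/cll_ce_plane.png",
                plot_ce_plane(samples, lambda = 50000),
                width = 6, height = 5, dpi = 150)
ggplot2::ggsave("results/figures/cll_ceac.png", plot_ceac(curve),
                width = 6, height = 4, dpi = 150)
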