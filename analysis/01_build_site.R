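#!/usr/bin/env Rscript
# Step 1 — build the study site.
#
# Generates the truth-known Cambisol-like site (five layers to 60 cm,
# exponentially decreasing SOC, retained fractions linear in SOC) and emits
# its "measured" tables: noisy 2010 stocks, 2012 fluxes and the bomb-pulse
# deposition scenario. The stock and ratio tables computed from those
# observations show the diagnostic the method rests on: the soil 36Cl/Cl
# ratio is strongly enriched over the rainfall ratio, which is only
# possible if part of the bomb-pulse 36Cl is still held in the soil.

library(cl36soil)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 42L

dir.create("results/site", recursive = TRUE, showWarnings = FALSE)
truth <- gen_site(seed)
obs <- gen_observations(truth, out_dir = "results/site")

cat("Synthetic site (seed", seed, "):\n")
print(truth)
print(obs$dataset)

stocks <- compute_stock(obs$dataset$layers)
ratios <- ratio_profile(obs$dataset)
write.csv(stocks, "results/site/stocks.csv", row.names = FALSE)
write.csv(ratios$stock_ratios, "results/site/stock_ratios.csv",
          row.names = FALSE)
write.csv(ratios$flux_ratios, "results/site/flux_ratios.csv",
          row.names = FALSE)

cat("\nPer-layer 36Cl/Cl stock ratios and enrichment over rainfall:\n")
print(ratios$stock_ratios)
cat("\nFlux 36Cl/Cl ratios:\n")
print(ratios$flux_ratios)
cat("\nEnrichment > 1 in every layer: the soil still holds bomb-pulse 36Cl,\n")
cat("so retention spans the decades back to the 1952-1972 tests.\n")
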