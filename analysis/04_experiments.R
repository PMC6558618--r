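#!/usr/bin/env Rscript
# Step 4 — uncertainty-quantification experiments.
#
# Draws conductivity samples from each prior, evaluates the surrogate
# leadfield per sample, and runs the fixed, rotating and moving
# goal-function scans: five univariate experiments plus the four-variate
# one. The sample count is a desk-scale 2,000 per experiment (the full
# study scale is 10,000; pass a first argument to override).

library(eeguq)

args <- commandArgs(trailingOnly = TRUE)
n <- if (length(args) >= 1L) as.integer(args[1]) else 2000L

dir.create("results", showWarnings = FALSE)
scenario <- build_scenario(seed = 1)

for (t in scenario$head$prior$tissue) {
  model <- read_pce(file.path("results", paste0("pce_uni_", t)))
  tab <- run_univariate(t, scenario, n = n, seed = 1L, model = model)
  write_experiment_csv(tab, file.path("results",
                                      paste0("experiment_uni_", t, ".csv")))
  cat(sprintf("univariate %-5s: depth %5.1f..%5.1f mm, GoF %.4f..%.4f, sd(GoF) %.5f\n",
              t, min(tab$mov_depth_mm), max(tab$mov_depth_mm),
              min(tab$mov_gof), max(tab$mov_gof),
              stats::sd(tab$mov_gof)))
}

model4 <- read_pce("results/pce_multivariate")
tab4 <- run_multivariate(scenario, n = n, seed = 1L, model = model4)
write_experiment_csv(tab4, "results/experiment_multivariate.csv")
cat(sprintf("multivariate  : depth %5.1f..%5.1f mm, GoF %.4f..%.4f, sd(GoF) %.5f\n",
            min(tab4$mov_depth_mm), max(tab4$mov_depth_mm),
            min(tab4$mov_gof), max(tab4$mov_gof), stats::sd(tab4$mov_gof)))
cat("experiment tables written to results/experiment_*.csv\n")
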