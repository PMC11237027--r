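#!/usr/bin/env Rscript
# Monte-Carlo null bands for the delta SNP-index: two bulks of 42
# unselected F3 individuals, 10,000 replications per depth, depths 80-120,
# two-sided 95% and 99% empirical quantiles.
#
# Writes: results/ci/ci_thresholds.tsv

library(bsaqtl)

dir.create("results/ci", recursive = TRUE, showWarnings = FALSE)
cfg <- null_sim_config(
  bulk_size = 42, replications = 10000,
  depth_grid = 80:120, levels = c(0.95, 0.99), seed = 404L
)
ci <- build_ci(cfg)
write_ci(ci, "results/ci/ci_thresholds.tsv")

b80 <- ci[ci$depth == 80 & ci$level == 0.95, ]
b120 <- ci[ci$depth == 120 & ci$level == 0.95, ]
cat(sprintf(
  "95%% band at 80x: [%.3f, %.3f]; at 120x: [%.3f, %.3f] (read noise shrinks with depth).\n",
  b80$lo, b80$hi, b120$lo, b120$hi
))
n99 <- ci[ci$depth == 100 & ci$level == 0.99, ]
cat(sprintf("99%% band at 100x: [%.3f, %.3f].\n", n99$lo, n99$hi))
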