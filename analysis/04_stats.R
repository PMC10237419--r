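#!/usr/bin/env Rscript
# Cohort statistics: classify the questionnaire roster into MOVE/notMOVE,
# compare demographics (Welch t-tests; Yates-corrected chi-squared for sex
# and fast-leg side), compare initial outcome values (mean of the first
# five strides) and end-of-adaptation net work rate between groups, and run
# the within-participant epoch-variability follow-up.
#
# Writes: results/run/group_stats.csv, epoch_variability.csv.

library(splitbelt)

outdir <- "results/run"
cfg <- read_run_config(file.path(outdir, "config.yaml"))
run_stage_stats(cfg, outdir)

gs <- read.csv(file.path(outdir, "group_stats.csv"))
cat("Group comparisons (statistic, p):\n")
print(gs[, c("comparison", "test", "statistic", "p")], digits = 3)

ev <- read.csv(file.path(outdir, "epoch_variability.csv"))
cat("\nEpoch variability tests (Student's t):\n")
print(ev, digits = 3)
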