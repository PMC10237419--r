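#!/usr/bin/env Rscript
# Assemble the coefficient report (per outcome and group, with
# group-difference p-values) and the adaptation-curve figures with model
# overlays and dashed plateau lines.
#
# Writes: results/run/report_coefficients.csv, figures/*.pdf.

library(splitbelt)

outdir <- "results/run"
cfg <- read_run_config(file.path(outdir, "config.yaml"))
run_stage_report(cfg, outdir)

rep <- read.csv(file.path(outdir, "report_coefficients.csv"))
cat(sprintf("Coefficient table: %d rows (%d outcomes x 2 groups)\n",
            nrow(rep), length(unique(rep$outcome))))
print(rep[rep$outcome == "sla", ], digits = 3)
if (dir.exists(file.path(outdir, "figures")))
  cat("Figures under", file.path(outdir, "figures"), "\n")
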