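#!/usr/bin/env Rscript
# One volume-constrained cardiac cycle of the symmetric fetal LV at the
# literature-average helix configuration (tau_bar = 10, tau_diff = 123):
# fiber field, smoothed fetal volume waveform (EDV 2.2 ml, ESV 1.2 ml,
# 400 ms cycle), and the four biomechanics metrics.
#
# A reduced-resolution mesh keeps this driver interactive; rerun with
# mesh_args = list() (default resolution, >= 2500 elements) for production
# figures.

suppressPackageStartupMessages(library(lvhelix))
dir.create("results", showWarnings = FALSE)

cfg <- run_config(geometry = lv_geometry_spec("symmetric"),
                  tau_bar = 10, tau_diff = 123,
                  mesh_args = list(n_trans = 1, n_long = 6, n_circ = 10),
                  solver = solver_config(steps_per_cycle = 25),
                  output_dir = "results/single_case")
res <- run_case(cfg, helix_config(10, 123))
print(res$cycle)
cat("\nmetrics:\n")
str(res$metrics)
cat(sprintf("\nglobal strains: circumferential %.2f%%, longitudinal %.2f%%\n",
            100 * res$metrics$eps_circ, 100 * res$metrics$eps_long))
cat("artifacts under results/single_case/\n")
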