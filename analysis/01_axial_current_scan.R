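#!/usr/bin/env Rscript
# Axial current between soma and AIS as a function of the soma-AIS distance.
#
# For each AIS proximal-edge distance l in {5, ..., 45} um, one action
# potential is evoked and the maximum current crossing the soma-axon
# junction is recorded.  Resistive coupling predicts I_axial ~ 1/l: the
# log-log slope should be -1 and the product I_axial * l a constant.

suppressPackageStartupMessages(library(aisfield))

config <- default_config()
dir <- "results/01_axial_current_scan"
write_manifest(config, dir, outputs = c("axial_scan.tsv", "axial_fit.tsv"))

scan <- exp_axial_current_scan(config)
write_table(scan$table, file.path(dir, "axial_scan.tsv"))
write_table(data.frame(slope = scan$slope, slope_stderr = scan$slope_stderr,
                       c_fixed_slope_nA_um = scan$c_fixed_slope),
            file.path(dir, "axial_fit.tsv"))

cat(sprintf("log-log slope of max axial current vs distance: %.3f (se %.3f)\n",
            scan$slope, scan$slope_stderr))
cat(sprintf("fixed-slope fit I_axial = c / l with c = %.1f nA um\n",
            scan$c_fixed_slope))
cat("checks:\n")
print(unlist(scan$checks))
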