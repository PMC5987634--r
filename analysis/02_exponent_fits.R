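#!/usr/bin/env Rscript
# Far-field decay of the extracellular AP for three AIS positions.
#
# For AIS positions {0, 20, 45} um the peak-to-peak EAP amplitude is
# measured on 20 log-spaced electrodes along the soma-AIS axis (opposite
# the axon) and along the perpendicular through the soma centre, and a
# power law r^k is fitted over 200-1000 um.  The soma-AIS dipole predicts
# k close to -2 horizontally, and steeper decay vertically.

suppressPackageStartupMessages(library(aisfield))

config <- default_config()
dir <- "results/02_exponent_fits"
write_manifest(config, dir, outputs = c("exponents.tsv", "profiles.tsv"))

ef <- exp_exponent_fit(config)
write_table(ef$table, file.path(dir, "exponents.tsv"))
write_table(ef$profiles, file.path(dir, "profiles.tsv"))

print(ef$table, row.names = FALSE)
cat(sprintf("vertical exponent range: %.2f .. %.2f\n",
            ef$vertical_k_range[1], ef$vertical_k_range[2]))
cat("checks:\n")
print(unlist(ef$checks))
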