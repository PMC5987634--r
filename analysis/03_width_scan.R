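#!/usr/bin/env Rscript
# EAP width at half peak-to-peak amplitude vs soma-AIS distance.
#
# The AIS is stepped from 0 to 45 um from the soma and the EAP width is
# measured at four sites: 30 and 100 um perpendicular above the soma
# centre and 30 and 100 um along the axis on the side opposite the axon.
# The intracellular somatic spike half-width is recorded alongside: the
# extracellular width grows with the soma-AIS distance much more than the
# intracellular waveform changes.

suppressPackageStartupMessages(library(aisfield))

config <- default_config()
dir <- "results/03_width_scan"
write_manifest(config, dir, outputs = c("widths.tsv", "intracellular.tsv"))

ws <- exp_width_scan(config)
write_table(ws$table, file.path(dir, "widths.tsv"))
write_table(ws$intracellular, file.path(dir, "intracellular.tsv"))

wide <- reshape(ws$table[, c("l", "site", "width")], idvar = "l",
                timevar = "site", direction = "wide")
print(wide, row.names = FALSE)
cat(sprintf("relative change of the intracellular half-width: %.0f%%\n",
            100 * ws$intra_rel_change))
cat("checks:\n")
print(unlist(ws$checks))
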