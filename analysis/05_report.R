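#!/usr/bin/env Rscript
# Stage 5: figures from the saved tables.
#
# Clustergram (yellow = high, 32-fold above the gene median; blue = low;
# grey = no amplification; rows grouped by cluster) and per-cluster
# passage-composition pies, both rendered purely from the stage 2-3 tables.

suppressPackageStartupMessages(library(scqpcr))

paths <- render_report("results", clip_bound = 5)
message("wrote ", paths$clustergram, " and ", paths$composition_pie)
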