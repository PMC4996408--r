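#!/usr/bin/env Rscript
# Stage 2: pooled median normalization with the dropout floor.
#
# Reads the chip export from stage 1, pools all chips/passages, normalizes
# each gene to its pooled expresser median on the log2 (cycle) scale,
# clips at +/-5 (32-fold), and floors non-expressers at -5.

suppressPackageStartupMessages(library(scqpcr))

m <- read_ct_long("results/data/cohort.csv", default_gene_panel(),
                  passages = c(chip_fresh = "fresh", chip_P0 = "P0",
                               chip_P1 = "P1"))
x <- normalize_to_median(m, clip_bound = 5)

out <- cbind(x$cells[, c("cell_id", "passage")],
             as.data.frame(x$values, check.names = FALSE))
write.table(out, "results/normalized.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
mask <- cbind(x$cells[, c("cell_id", "passage")],
              as.data.frame(x$expresser, check.names = FALSE))
write.table(mask, "results/mask.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("normalized %d cells x %d genes; %d positions floored at -5",
                nrow(x$values), length(x$genes), sum(!x$expresser)))
message(sprintf("per-gene expresser medians span %.1f-%.1f cycles",
                min(x$gene_medians), max(x$gene_medians)))
message("wrote results/normalized.tsv, results/mask.tsv")
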