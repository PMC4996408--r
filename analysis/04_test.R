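#!/usr/bin/env Rscript
# Stage 4: differential-distribution testing.
#
# Two-sample K-S tests per gene, Bonferroni-corrected within each contrast
# (family size = 48): every cluster against the remaining cells, and the
# passage transitions fresh->P0 and P0->P1. Also writes the per-group
# Gaussian summaries (median-centered expresser mean/sd and dropout
# fractions) that describe each called gene.

suppressPackageStartupMessages(library(scqpcr))

m <- read_ct_long("results/data/cohort.csv", default_gene_panel(),
                  passages = c(chip_fresh = "fresh", chip_P0 = "P0",
                               chip_P1 = "P1"))
x <- normalize_to_median(m)
clusters <- read.delim("results/clusters.tsv")
model <- structure(list(k = max(clusters$cluster),
                        assignments = clusters$cluster,
                        wcss = NA_real_, n_restarts = NA_integer_,
                        seed = NA_integer_),
                   class = "ClusterModel")

cvr <- cluster_vs_rest(x, model, alpha = 0.05)
cvr <- cbind(contrast = sprintf("cluster%d_vs_rest", cvr$cluster),
             cvr[, setdiff(names(cvr), "cluster")])
pc <- passage_contrasts(x, alpha = 0.05)
ks <- rbind(cvr, pc)
write.table(ks, "results/ks_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

gs <- gaussian_summary(x, x$cells$passage)
write.table(gs, "results/gaussian_summaries.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts <- tapply(ks$significant, ks$contrast, sum)
message("significant genes (p < 0.05/48) per contrast:")
for (nm in names(counts)) message(sprintf("  %-18s %d", nm, counts[[nm]]))
message("wrote results/ks_results.tsv, gaussian_summaries.tsv")
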