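#!/usr/bin/env Rscript
# Stage 3: subpopulation discovery.
#
# Silhouette-guided k-means over k = 2..8 on the normalized cohort from
# stage 2, hierarchical ordering for the clustergram, per-cluster passage
# composition, and agreement with the implanted ground truth.

suppressPackageStartupMessages(library(scqpcr))

seed <- 20260922L
m <- read_ct_long("results/data/cohort.csv", default_gene_panel(),
                  passages = c(chip_fresh = "fresh", chip_P0 = "P0",
                               chip_P1 = "P1"))
x <- normalize_to_median(m)
truth <- read.delim("results/data/truth.tsv")

k_sel <- select_cluster_count(x, k_min = 2L, k_max = 8L,
                              n_restarts = 50L, seed = seed)
sil <- attr(k_sel, "silhouette")
message("mean silhouette by k: ",
        paste(sprintf("k=%s: %.3f", names(sil), sil), collapse = ", "))
message(sprintf("selected k = %d", as.integer(k_sel)))

model <- attr(k_sel, "models")[[as.character(as.integer(k_sel))]]
ari <- adjusted_rand_index(model$assignments, truth$true_label)
message(sprintf("adjusted Rand agreement with implanted labels: %.3f", ari))

ord <- order_hierarchically(x, model)
comp <- composition(model, x$cells$passage)

write.table(data.frame(cell_id = x$cells$cell_id, passage = x$cells$passage,
                       cluster = model$assignments,
                       order = order(ord$cell_order)),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(comp, "results/composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(k = as.integer(names(sil)), mean_silhouette = sil),
            "results/silhouette_by_k.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("per-cluster passage composition:")
for (cl in unique(comp$cluster)) {
  sub <- comp[comp$cluster == cl, ]
  message(sprintf("  cluster %d (n=%d): %s", cl, sum(sub$n),
                  paste(sprintf("%s %.0f%%", sub$passage, 100 * sub$fraction),
                        collapse = ", ")))
}
message("wrote results/clusters.tsv, composition.tsv, silhouette_by_k.tsv")
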