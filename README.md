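# scqpcr

Subpopulation analysis for single-cell gene expression measured on 48x48
microfluidic qPCR dynamic arrays.

Single-cell qPCR chips report one cycle-threshold (Ct) value per cell x
gene reaction; reactions that fail to amplify within the cycle limit (40
cycles) carry no Ct at all. This package implements the complete analysis
path for such data, for anyone profiling cell populations (e.g. cultured
stem cells across passages) on these chips:

1. **Chip I/O** -- read, validate and merge chip-level CSV exports (long
   or grid dialect); reactions with Ct >= 40 are *non-expressers*.
2. **Normalization** -- per-gene log2 fold change vs the pooled expresser
   median: `x = clip(median_g - Ct, -5, +5)`; one cycle = one log2 unit;
   the bounds are 32-fold; non-expressers are floored at -5.
3. **Subpopulation discovery** -- seeded k-means minimizing the
   within-cluster sum of squares in the full 48-gene space, with the
   cluster count chosen by mean silhouette width (k = 2..8), hierarchical
   average-linkage ordering for clustergrams, and per-cluster passage
   composition.
4. **Differential distributions** -- per-gene two-sample
   Kolmogorov-Smirnov tests (`D = sup |F_a - F_b|`, exact small-sample
   p-values by lattice-path counting, asymptotic otherwise) for each
   cluster vs the rest and for the fresh->P0 and P0->P1 passage
   transitions, Bonferroni-corrected (significant iff `p < alpha/48`).
5. **Synthetic cohorts** -- a seeded generator with implanted
   subpopulations, passage-dependent mixing and level-dependent
   amplification dropout, so the whole pipeline is testable without
   instrument data.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic design (three passages x 80 cells, 48 genes, three implanted
subpopulations shifting 10-gene blocks by 4 cycles):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize.R
Rscript analysis/03_cluster.R
Rscript analysis/04_test.R
Rscript analysis/05_report.R
```

which prints, among other things:

```
cohort: 240 cells x 48 genes; 1232 (10.7%) reactions failed to amplify
mean silhouette by k: k=2: 0.157, k=3: 0.212, k=4: 0.164, ...
selected k = 3
adjusted Rand agreement with implanted labels: 0.989
per-cluster passage composition:
  cluster 1 (n=62): fresh 8%, P0 18%, P1 74%
  cluster 2 (n=96): fresh 16%, P0 57%, P1 27%
  cluster 3 (n=82): fresh 73%, P0 17%, P1 10%
significant genes (p < 0.05/48) per contrast:
  cluster1_vs_rest   30
  ...
```

Read: ~10% of reactions dropped out; silhouette selection recovers the
three implanted subpopulations essentially perfectly (adjusted Rand
0.989); each passage is enriched in "its" cluster, mirroring the mixing
design; and each cluster's shifted gene block (plus the genes it displaces
in the pooled median) is called against the rest of the cohort. Tables
land in `results/`, figures (`clustergram.png` with the yellow/blue
32-fold scale and grey non-expressers, `composition_pie.png`) are rendered
from the saved tables alone.

The same flow is available as one call:

```r
library(scqpcr)
cfg <- pipeline_config(synthetic = default_study_spec(seed = 1), seed = 1,
                       out_dir = "my_run")
res <- run_pipeline(cfg)           # tables + figures + manifest.json
replay_pipeline("my_run/manifest.json", out_dir = "my_run_replay")
# -> byte-identical tables
```

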