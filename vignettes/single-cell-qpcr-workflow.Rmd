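---
title: "Methods: single-cell qPCR subpopulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell qPCR subpopulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqpcr)
```

## The measurement and its quirks

A microfluidic dynamic array runs 48 single cells against 48 qPCR assays,
producing one cycle-threshold (Ct) value per cell x gene reaction: the
cycle at which fluorescence crosses detection. One cycle is one template
doubling, so Ct is a *negative* log2 expression scale -- lower Ct, more
transcript. Two features dominate the analysis design:

* **Amplification failure.** A reaction that has not crossed threshold by
  the last cycle (default 40) has no Ct. In single cells this is common
  and biologically loaded: a transcript may genuinely be absent, or sit
  below the limit of detection. We treat these reactions as
  *non-expressers*, an explicit state, never a sentinel number. The rule
  is strict: Ct >= cycle limit is a non-expresser.
* **No stable reference.** With single cells there is no trustworthy
  housekeeping normalizer, so each gene is referenced to its own pooled
  median across every chip and passage.

## Normalization

For gene $g$ with pooled expresser median $m_g$, an expressing reaction
with threshold $\mathrm{Ct}_{ig}$ gets

$$x_{ig} = \mathrm{clip}(m_g - \mathrm{Ct}_{ig},\ -L,\ +L), \qquad L = 5,$$

and every non-expresser is assigned the floor $-L$. The bound $L = 5$
log2 units is 32-fold either way; the floor and the lower clip coincide
deliberately, so "very low" and "undetected" meet at the same point of the
scale. Medians are computed over expressing reactions only (a reaction
without a Ct cannot contribute without imputation, which we refuse); the
per-gene expresser counts are kept in the result for audit. Even-count
medians are the usual midpoint, keeping the statistic deterministic.
`fold_change()` maps the scale back to linear fold (+5 -> 32x).

## Subpopulation discovery

Cells are partitioned by k-means in the full normalized gene space,
minimizing the within-cluster sum of squared Euclidean distances (WCSS).
Floored non-expressers participate at $-5$: dropout patterning is part of
a cell's profile, and excluding it would blind the clustering to the most
extreme expression differences.

Numerical choices, all deterministic given the seed:

* **Initialization.** Each restart seeds centers by squared-distance
  weighted spreading (first center a random cell; each next one drawn with
  probability proportional to its squared distance from the chosen
  centers). This keeps starts well separated while letting the default 50
  restarts explore genuinely different initializations; the best restart
  by WCSS wins. On tiny instances this reliably attains the exhaustive
  minimum over all partitions (tested up to n = 8).
* **Empty clusters** occasionally arise mid-iteration; they are repaired
  by donating the cell farthest from its own centroid, so exactly `k`
  clusters are always returned.
* **Convergence** is an assignment fixpoint or a relative WCSS change
  below 1e-10; WCSS is asserted non-increasing across iterations.

The cluster count is chosen by mean silhouette width over k = 2..8
(computed via `cluster::silhouette`), ties toward the smaller k. The
criterion is a package design choice -- any partition-quality index could
stand in its place -- made because silhouette is simple, metric-consistent
with the WCSS objective, and recovers the implanted structure of the
synthetic design reliably.

For clustergram display, cells are ordered by cluster and then by
average-linkage agglomeration on Euclidean distance within each cluster;
genes by one global pass. The agglomeration is implemented in-package with
explicit tie-breaking (merge the smallest-index pair at equal distance;
earlier-created cluster stays left), so identical rows keep their input
order and the display is reproducible to the byte -- a guarantee
`stats::hclust` leaf ordering does not make.

## Differential distributions

Per gene, the two-sample Kolmogorov-Smirnov statistic
$D = \sup_t |\hat F_a(t) - \hat F_b(t)|$ is evaluated exactly over the
pooled sample support with right-continuous ECDFs, which handles the heavy
ties at the $-5$ floor correctly. Contrasts are each cluster against all
remaining cells, and the passage transitions fresh->P0 and P0->P1 (not
fresh->P1). Within each contrast, Bonferroni control at family size
m = panel size (48) declares a gene significant when $p < \alpha/m$;
$\alpha = 0.05$ is the default and $\alpha = 0.01$ is exposed as a
stricter preset, since both conventions appear in practice.

P-values: for $\min(n_a, n_b) \le 10$ and $n_a n_b \le 10{,}000$ the exact
null probability is computed by lattice-path counting over pooled-rank
interleavings (carried as a probability recursion for stability; cluster
fragments can be small, where the asymptotic is unreliable). Otherwise the
Kolmogorov limiting distribution is evaluated at the effective sample size
$n_e = n_a n_b/(n_a+n_b)$, i.e. $p = Q_{KS}(\sqrt{n_e}\,D)$ -- the same
asymptotic as `stats::ks.test`; at $n_a = n_b = 10$ it agrees with the
exact computation within 10% relative error across mid-range $D$. The
exact computation assumes continuous data (no ties); with the floor ties
present it is conservative, which we accept.

By default K-S samples **include** floored non-expressers: a difference in
dropout rate is a difference in expression distribution. A switch
(`include_nonexpressers = FALSE`) restricts testing to expressers, since
per-group Gaussian curve summaries are naturally drawn on expressers only;
genes whose expresser sample empties out are then flagged, not tested.
`gaussian_summary()` reports, per gene and group, the mean and sample SD
of expresser values centered at the group expresser median, plus the
expresser fraction (1 - dropout fraction).

## The synthetic cohort generator

The study data this pipeline is built for (fresh vs passage-0 vs
passage-1 adipose-derived stem cells on 48-gene chips) are not publicly
deposited, so the package carries a generative stand-in that every
downstream stage is tested against:

* per-gene baseline Ct drawn once from U(18, 30) -- mid-dynamic-range
  qPCR levels -- with within-population SD of 1 cycle;
* `k_true = 3` subpopulations, each up-shifting its own disjoint block of
  10 informative genes by 4 cycles (~16-fold), large enough that the
  partition is identifiable but small against the 48-gene background;
* passage-dependent mixing with defaults fresh = (0.70, 0.20, 0.10),
  P0 = (0.20, 0.65, 0.15), P1 = (0.10, 0.30, 0.60). These lean each
  passage toward "its" subpopulation, qualitatively reproducing a design
  in which one subgroup is enriched for primary cells, one dominated by
  P0 with a strong P1 minority, and one mostly P1. **The numbers are
  invented defaults of this package**, configurable, and must not be read
  as measured proportions;
* dropout with a level-independent base rate (0.1) plus 0.05 per cycle of
  expected Ct above 30, capped at 0.95 -- the limit-of-detection behavior
  of qPCR, where weak transcripts fail disproportionately. Both terms can
  be zeroed;
* 80 cells per passage group (within the 60-100 range such chip runs
  yield), 40-cycle limit.

A latent Ct at or beyond the cycle limit is recorded as non-amplified
(right-censoring at the detection limit) rather than clamped to a numeric
value: under the strict 40-cycle rule such a reaction could never count as
an expresser anyway, and censoring is what the instrument would report.

Randomness is one global seed; each cell consumes a substream derived from
(seed, group, cell index), so enlarging one passage group never perturbs
another group's draws, and equal specs give bit-identical cohorts.

What the generator does *not* emulate: pre-amplification bias, chip
spatial effects, melt-curve artifacts, correlated gene modules beyond the
block shifts, or doublets. Passing recovery tests on this design therefore
shows the machinery is correct and well-calibrated, not that real
stem-cell populations contain exactly three clusters.

## Pipeline reproducibility

`run_pipeline()` executes acquire -> normalize -> cluster -> order ->
compose -> test, writes every table first, and renders figures *from the
saved tables only*, so any figure can be regenerated post hoc
(`render_report()`). A JSON manifest records the full configuration
(doubles serialized to 17 significant digits, enough for a bit-exact
round-trip), and `replay_pipeline()` reproduces every table byte for byte
from the manifest alone. The run log records row counts per stage, so any
cell/gene attrition is visible.

## Problem sizes used in the checks

The default test suite works at the scale the method targets: cohorts of
240 cells x 48 genes for recovery checks, 200 replicate null cohorts of 50
tested cells for the family-wise error measurement, exhaustive-enumeration
oracles up to 8 points (k-means) and 5 + 5 samples (exact K-S p-values).
These sizes make the exhaustive checks feasible while matching the
dimensionality of a real chip.

## Known limitations

* The exact K-S p-value is a no-ties null; with floor ties it is
  conservative rather than exact.
* Silhouette-guided selection inherits silhouette's bias toward compact,
  balanced clusters; `k` can always be fixed explicitly.
* Medians-before-QC: no cell-level quality filtering is applied before
  normalization; a chip full of failed wells will pull pooled medians.
  Blank grid rows are dropped (with a warning) at read time only.
* No housekeeping/efficiency correction, no dropout imputation, no batch
  correction across chips beyond the pooled-median reference.
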