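#' Synthetic cohort specification
#'
#' Describes a generative model for single-cell qPCR Ct data with implanted
#' subpopulation structure: each of `k_true` subpopulations shifts a block of
#' informative genes away from the per-gene baseline Ct, passage groups mix
#' the subpopulations in different proportions, and each reaction can fail
#' to amplify with a probability that grows with its expected Ct (weakly
#' expressed transcripts sit near the limit of detection and drop out more
#' often).
#'
#' One Ct cycle equals one log2 expression unit, so a shift of -4 cycles is
#' a ~16-fold up-regulation on the normalized scale.
#'
#' @param n_genes Panel size (default 48).
#' @param k_true Number of implanted subpopulations (default 3).
#' @param baseline_ct Per-gene mean Ct in cycles; default drawn uniformly in
#'   `[18, 30]` from the spec seed.
#' @param within_sd Per-gene Ct standard deviation in cycles (default 1).
#' @param shift_matrix `k_true x n_genes` matrix of subpopulation Ct offsets
#'   in cycles. Default: subpopulation `j` shifts its own disjoint block of
#'   10 genes by -4 cycles.
#' @param mixing Row-stochastic matrix (one row per passage group, columns =
#'   subpopulations) of mixture proportions. Rows are named with passage
#'   labels. The default leans each passage toward its "own" subpopulation;
#'   these proportions are illustrative defaults of this package, not
#'   measurements.
#' @param cells_per_group Cells sampled per passage group (default 80; the
#'   chips profiled 60-100 cells per group).
#' @param dropout_base Level-independent reaction failure probability
#'   (default 0.1).
#' @param dropout_slope Added failure probability per cycle of expected Ct
#'   above `ct0` (default 0.05/cycle).
#' @param ct0 Ct at which level-dependent dropout starts (default 30
#'   cycles).
#' @param dropout_cap Upper bound on the per-reaction failure probability
#'   (default 0.95).
#' @param cycle_limit qPCR cycle limit (default 40).
#' @param seed Integer seed driving all randomness.
#' @return A validated `SyntheticCohortSpec` list.
#' @export
cohort_spec <- function(n_genes = 48L,
                        k_true = 3L,
                        baseline_ct = NULL,
                        within_sd = 1,
                        shift_matrix = NULL,
                        mixing = NULL,
                        cells_per_group = 80L,
                        dropout_base = 0.1,
                        dropout_slope = 0.05,
                        ct0 = 30,
                        dropout_cap = 0.95,
                        cycle_limit = 40L,
                        seed = 1L) {
  n_genes <- .assert_count(n_genes, "n_genes")
  k_true <- .assert_count(k_true, "k_true")
  cells_per_group <- .assert_count(cells_per_group, "cells_per_group")
  cycle_limit <- .assert_count(cycle_limit, "cycle_limit")
  .assert_scalar_number(within_sd, "within_sd", lower = 0)
  .assert_scalar_number(dropout_base, "dropout_base", 0, 1)
  .assert_scalar_number(dropout_slope, "dropout_slope", lower = 0)
  .assert_scalar_number(dropout_cap, "dropout_cap", 0, 1)
  .assert_scalar_number(ct0, "ct0", lower = 0)
  seed <- .assert_count(seed, "seed", lower = 0L)

  if (is.null(baseline_ct)) {
    baseline_ct <- .with_local_seed(.mix_seed(seed, 101L),
                                    stats::runif(n_genes, 18, 30))
  }
  if (length(baseline_ct) != n_genes || !is.numeric(baseline_ct) ||
      anyNA(baseline_ct)) {
    stop("`baseline_ct` must be a numeric vector of length n_genes",
         call. = FALSE)
  }
  if (is.null(shift_matrix)) {
    shift_matrix <- matrix(0, k_true, n_genes)
    block <- 10L
    for (j in seq_len(k_true)) {
      lo <- (j - 1L) * block + 1L
      hi <- min(j * block, n_genes)
      if (lo <= n_genes) shift_matrix[j, lo:hi] <- -4
    }
  }
  if (!is.matrix(shift_matrix) ||
      !identical(dim(shift_matrix), c(k_true, n_genes))) {
    stop("`shift_matrix` must be a ", k_true, " x ", n_genes, " matrix",
         call. = FALSE)
  }
  if (is.null(mixing)) {
    mixing <- .default_mixing(k_true)
  }
  if (!is.matrix(mixing) || ncol(mixing) != k_true) {
    stop("`mixing` must be a matrix with ", k_true, " columns", call. = FALSE)
  }
  if (is.null(rownames(mixing))) {
    rownames(mixing) <- .canonical_passages[seq_len(nrow(mixing))]
  }
  if (any(mixing < 0)) stop("`mixing` entries must be >= 0", call. = FALSE)
  if (any(abs(rowSums(mixing) - 1) > 1e-9)) {
    stop("each `mixing` row must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(
    list(n_genes = n_genes, k_true = k_true,
         baseline_ct = as.numeric(baseline_ct), within_sd = within_sd,
         shift_matrix = shift_matrix, mixing = mixing,
         cells_per_group = cells_per_group,
         dropout_base = dropout_base, dropout_slope = dropout_slope,
         ct0 = ct0, dropout_cap = dropout_cap,
         cycle_limit = cycle_limit, seed = seed),
    class = "SyntheticCohortSpec"
  )
}

# Default passage -> subpopulation proportions. Chosen so that, as in the
# study design being emulated, subpopulation 1 is enriched for fresh cells,
# subpopulation 2 is dominated by P0 with a strong P1 minority, and
# subpopulation 3 is mostly P1. Illustrative values, not measurements.
.default_mixing <- function(k_true) {
  if (k_true == 3L) {
    m <- rbind(fresh = c(0.70, 0.20, 0.10),
               P0    = c(0.20, 0.65, 0.15),
               P1    = c(0.10, 0.30, 0.60))
  } else {
    # lean each of the first min(3, k) groups toward its own subpopulation
    m <- matrix(1 / k_true, nrow = 3L, ncol = k_true)
    for (g in seq_len(3L)) {
      j <- ((g - 1L) %% k_true) + 1L
      m[g, ] <- 0.3 / (k_true - 1)
      m[g, j] <- 0.7
      if (k_true == 1L) m[g, ] <- 1
    }
    rownames(m) <- .canonical_passages
  }
  m
}

#' Default synthetic study design
#'
#' The documented default cohort: a 48-gene panel, three subpopulations each
#' up-shifting its own 10-gene block by 4 cycles (~16-fold), 80 cells in
#' each of the fresh, P0 and P1 passage groups with passage-dependent
#' subpopulation mixing, level-dependent dropout, and a 40-cycle limit.
#'
#' @param seed Integer seed (default 1).
#' @return A `SyntheticCohortSpec`.
#' @export
default_study_spec <- function(seed = 1L) {
  cohort_spec(seed = seed)
}

#' Generate a synthetic single-cell qPCR cohort
#'
#' For each passage group, draws `cells_per_group` cells; each cell's
#' subpopulation is sampled from that group's mixing row, its latent
#' per-gene Ct is `baseline_ct + shift + N(0, within_sd)`, and each reaction
#' independently fails with probability
#' `min(dropout_base + dropout_slope * max(0, latent - ct0), dropout_cap)`.
#' Latent Ct values at or beyond the cycle limit are right-censored: the
#' reaction is recorded as non-amplified, exactly as a real reaction that
#' has not crossed threshold by the last cycle would be. Surviving Ct values
#' are floored at 0.01 cycles.
#'
#' Each cell consumes its own RNG substream derived from
#' `(seed, group, cell index)`, so enlarging one passage group never
#' perturbs another group's draws.
#'
#' @param spec A [cohort_spec()].
#' @return A `SyntheticCohort`: list with `matrix` (a `CtMatrix`) and
#'   `true_labels` (integer subpopulation index per cell, in row order of
#'   `matrix$cells`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  groups <- rownames(spec$mixing)
  runs <- vector("list", length(groups))
  labels <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    n <- spec$cells_per_group
    ct <- matrix(NA_real_, n, spec$n_genes)
    lab <- integer(n)
    for (i in seq_len(n)) {
      cell <- .with_local_seed(
        .mix_seed(spec$seed, g * 1000003L, i),
        .draw_cell(spec, spec$mixing[g, ])
      )
      ct[i, ] <- cell$ct
      lab[i] <- cell$label
    }
    dimnames(ct) <- list(sprintf("c%03d", seq_len(n)),
                         sprintf("G%02d", seq_len(spec$n_genes)))
    runs[[g]] <- new_chip_run(chip_id = paste0("chip_", groups[[g]]),
                              passage = groups[[g]], ct = ct,
                              cycle_limit = spec$cycle_limit)
    labels[[g]] <- lab
  }
  structure(
    list(matrix = merge_runs(runs),
         true_labels = unlist(labels, use.names = FALSE),
         spec = spec),
    class = "SyntheticCohort"
  )
}

.draw_cell <- function(spec, probs) {
  label <- sample.int(spec$k_true, 1L, prob = probs)
  latent <- spec$baseline_ct + spec$shift_matrix[label, ] +
    stats::rnorm(spec$n_genes, 0, spec$within_sd)
  p_fail <- pmin(spec$dropout_base +
                   spec$dropout_slope * pmax(0, latent - spec$ct0),
                 spec$dropout_cap)
  failed <- stats::runif(spec$n_genes) < p_fail
  ct <- pmax(latent, 0.01)
  ct[failed | ct >= spec$cycle_limit] <- NA_real_
  list(label = label, ct = ct)
}
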