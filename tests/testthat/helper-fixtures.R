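# Shared fixtures and independent brute-force oracles. Oracles never call
# the code paths they check.

# Build a CtMatrix from a plain numeric matrix (NA = non-amplified),
# one chip per passage label.
make_ct <- function(ct, passages, cycle_limit = 40L) {
  stopifnot(nrow(ct) == length(passages))
  if (is.null(rownames(ct))) rownames(ct) <- sprintf("c%02d", seq_len(nrow(ct)))
  if (is.null(colnames(ct))) colnames(ct) <- sprintf("G%02d", seq_len(ncol(ct)))
  runs <- lapply(unique(passages), function(p) {
    scqpcr:::new_chip_run(chip_id = paste0("chip_", p), passage = p,
                          ct = ct[passages == p, , drop = FALSE],
                          cycle_limit = cycle_limit)
  })
  merge_runs(runs)
}

write_grid_csv <- function(ct, path) {
  df <- data.frame(cell_id = rownames(ct), ct, check.names = FALSE)
  for (j in seq_len(ncol(ct)) + 1L) df[[j]] <- ifelse(is.na(df[[j]]), "", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# ECDF sup-distance by direct evaluation over a dense grid of both samples.
ks_D_oracle <- function(a, b) {
  ts <- sort(unique(c(a, b)))
  max(vapply(ts, function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1L)))
}

# Exact null P(D >= d) by full enumeration of all C(na+nb, na)
# interleavings of pooled ranks (distinct values, no ties).
ks_p_oracle <- function(d, na, nb) {
  pos <- utils::combn(na + nb, na)
  stat_of <- function(apos) {
    is_a <- seq_len(na + nb) %in% apos
    fa <- cumsum(is_a) / na
    fb <- cumsum(!is_a) / nb
    max(abs(fa - fb))
  }
  ds <- apply(pos, 2L, stat_of)
  mean(ds >= d - 1e-12)
}

# Exhaustive minimum WCSS over all assignments of n points into k
# non-empty clusters.
wcss_oracle <- function(v, k) {
  n <- nrow(v)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    best <- min(best, wcss_of(v, lab))
  }
  best
}

# Mean silhouette width by a direct pairwise double loop.
silhouette_oracle <- function(v, lab) {
  n <- nrow(v)
  dm <- as.matrix(stats::dist(v))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a_i <- mean(dm[i, own])
    b_i <- min(vapply(setdiff(unique(lab), lab[i]), function(cl) {
      mean(dm[i, lab == cl])
    }, numeric(1L)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Small null cohort spec: no implanted shifts, so every group and every
# subpopulation share one distribution.
null_spec <- function(seed, cells_per_group = 30L, n_genes = 48L) {
  cohort_spec(n_genes = n_genes, k_true = 3L,
              shift_matrix = matrix(0, 3L, n_genes),
              cells_per_group = cells_per_group, seed = seed)
}
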