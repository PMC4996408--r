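# Two-sample Kolmogorov-Smirnov machinery and the contrasts it powers:
# cluster-vs-rest and passage-pair differential-distribution testing with
# Bonferroni family-wise control, plus Gaussian per-group summaries.

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The sup-norm distance between the two empirical cumulative distribution
#' functions, evaluated exactly over the pooled sample support (sufficient
#' because both ECDFs are right-continuous step functions that only change
#' at sample points).
#'
#' @param a,b Non-empty numeric samples.
#' @return `D` in `[0, 1]`.
#' @export
ks_statistic <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  support <- sort(unique(c(a, b)))
  fa <- findInterval(support, sort(a)) / length(a)
  fb <- findInterval(support, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' Two-sided p-value for the two-sample K-S statistic
#'
#' For small samples (`min(n_a, n_b) <= 10` and `n_a * n_b <= 10000`) the
#' exact null probability `P(D >= d)` is computed by counting the lattice
#' paths of pooled-rank interleavings whose running ECDF difference stays
#' below `d`; all interleavings are equally likely under the null, and the
#' count recursion is carried as a probability so it is numerically stable.
#' Larger samples use the Kolmogorov limiting distribution evaluated at the
#' effective sample size `n_e = n_a n_b / (n_a + n_b)`, i.e.
#' `p = Q_KS(sqrt(n_e) * D)` -- the same asymptotic as two-sample
#' [stats::ks.test()].
#'
#' @param D K-S statistic in `[0, 1]`.
#' @param n_a,n_b Sample sizes (>= 1).
#' @param exact `NULL` (auto, as above), `TRUE`, or `FALSE`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
ks_pvalue <- function(D, n_a, n_b, exact = NULL) {
  .assert_scalar_number(D, "D", 0, 1)
  n_a <- .assert_count(n_a, "n_a")
  n_b <- .assert_count(n_b, "n_b")
  if (is.null(exact)) {
    exact <- min(n_a, n_b) <= 10L && n_a * n_b <= 10000L
  }
  if (D <= 0) return(1)
  if (exact) .ks_pvalue_exact(D, n_a, n_b) else .ks_pvalue_asymptotic(D, n_a, n_b)
}

# Exact P(D >= D_obs) by lattice-path counting. A pooled ordering is a
# monotone path from (0,0) to (n_a, n_b); at vertex (i, j) the ECDF
# difference is (i/n_a - j/n_b) = (i*n_b - j*n_a) / (n_a*n_b), an integer
# multiple of 1/(n_a*n_b). q(i,j) is the null probability that a uniformly
# random path reaches (i,j) while keeping |i*n_b - j*n_a| < m, where
# m = ceiling(D_obs * n_a * n_b) is the smallest achievable numerator
# at least D_obs.
.ks_pvalue_exact <- function(D, n_a, n_b) {
  m <- ceiling(D * n_a * n_b - 1e-9)
  if (m <= 0) return(1)
  q <- matrix(0, n_a + 1L, n_b + 1L)
  q[1L, 1L] <- 1
  for (i in 0:n_a) {
    for (j in 0:n_b) {
      if (i == 0L && j == 0L) next
      if (abs(i * n_b - j * n_a) >= m) { q[i + 1L, j + 1L] <- 0; next }
      acc <- 0
      if (i > 0L) acc <- acc + q[i, j + 1L] * i / (i + j)
      if (j > 0L) acc <- acc + q[i + 1L, j] * j / (i + j)
      q[i + 1L, j + 1L] <- acc
    }
  }
  min(max(1 - q[n_a + 1L, n_b + 1L], 0), 1)
}

.ks_pvalue_asymptotic <- function(D, n_a, n_b) {
  n_e <- n_a * n_b / (n_a + n_b)
  lambda <- sqrt(n_e) * D
  if (lambda < 0.2) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

.binary_groups <- function(groups, n) {
  if (length(groups) != n) {
    stop("`groups` length (", length(groups),
         ") does not match the number of cells (", n, ")", call. = FALSE)
  }
  f <- factor(groups)
  if (nlevels(f) != 2L) {
    stop("`groups` must define exactly two non-empty groups, got levels: ",
         paste(levels(f), collapse = ", "), call. = FALSE)
  }
  f
}

#' Per-gene K-S contrast between two groups of cells
#'
#' Runs one two-sample K-S test per gene between the cells of the two
#' groups and applies Bonferroni family-wise control: a gene is significant
#' when `p < alpha / m`. By default the samples are the normalized values
#' including floored non-expressers at `-clip_bound` -- a difference in
#' dropout rate is itself a difference in expression distribution. Set
#' `include_nonexpressers = FALSE` to test expressing reactions only; genes
#' whose expresser sample is empty in either group are then reported with
#' `NA` statistics and `significant = FALSE`.
#'
#' @param x A `NormalizedMatrix`.
#' @param groups Per-cell labels defining exactly two non-empty groups.
#' @param alpha Family-wise level (default 0.05; the stricter 0.01 preset is
#'   `alpha = 0.01`).
#' @param m Family size for the Bonferroni correction (default: panel size).
#' @param include_nonexpressers Include floored non-expressers in the tested
#'   samples (default `TRUE`).
#' @return Data frame with one row per gene: `gene`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `D`, `p`, `alpha_family`, `m_tests`, `significant`,
#'   `dropout_a`, `dropout_b`.
#' @export
test_contrast <- function(x, groups, alpha = 0.05, m = NULL,
                          include_nonexpressers = TRUE) {
  stopifnot(inherits(x, "NormalizedMatrix"))
  .assert_scalar_number(alpha, "alpha", 0, 1)
  f <- .binary_groups(groups, nrow(x$values))
  if (is.null(m)) m <- length(x$genes)
  m <- .assert_count(m, "m")
  ia <- which(f == levels(f)[[1L]])
  ib <- which(f == levels(f)[[2L]])
  res <- lapply(seq_along(x$genes), function(g) {
    va <- x$values[ia, g]; vb <- x$values[ib, g]
    ea <- x$expresser[ia, g]; eb <- x$expresser[ib, g]
    if (!include_nonexpressers) { va <- va[ea]; vb <- vb[eb] }
    if (length(va) == 0L || length(vb) == 0L) {
      D <- NA_real_; p <- NA_real_
    } else {
      D <- ks_statistic(va, vb)
      p <- ks_pvalue(D, length(va), length(vb))
    }
    data.frame(
      gene = x$genes[[g]],
      group_a = levels(f)[[1L]], group_b = levels(f)[[2L]],
      n_a = length(va), n_b = length(vb),
      D = D, p = p, alpha_family = alpha, m_tests = m,
      significant = !is.na(p) && p < alpha / m,
      dropout_a = mean(!ea), dropout_b = mean(!eb),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cluster-vs-rest differential distribution testing
#'
#' For each cluster, compares the empirical expression distribution of its
#' cells against that of all remaining cells in the experiment, gene by
#' gene, with Bonferroni control within each contrast.
#'
#' @param x A `NormalizedMatrix`.
#' @param model A `ClusterModel` fitted on `x`.
#' @inheritParams test_contrast
#' @return Data frame of per-gene results with a leading `cluster` column;
#'   within each contrast, `group_a` is the cluster and `group_b` the rest.
#' @export
cluster_vs_rest <- function(x, model, alpha = 0.05, m = NULL,
                            include_nonexpressers = TRUE) {
  stopifnot(inherits(x, "NormalizedMatrix"), inherits(model, "ClusterModel"))
  if (model$k < 2L) {
    stop("cluster-vs-rest needs k >= 2 (with k = 1 the rest is empty)",
         call. = FALSE)
  }
  out <- lapply(seq_len(model$k), function(cl) {
    lab <- ifelse(model$assignments == cl,
                  sprintf("cluster%d", cl), "rest")
    lab <- factor(lab, levels = c(sprintf("cluster%d", cl), "rest"))
    res <- test_contrast(x, lab, alpha = alpha, m = m,
                         include_nonexpressers = include_nonexpressers)
    cbind(cluster = cl, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Passage-pair differential distribution testing
#'
#' Tests the transitions the study design defines: primary isolation to
#' first culture (`fresh` vs `P0`) and the first passaging step (`P0` vs
#' `P1`). Only contrasts whose two passages are both present are run; if
#' none is possible, the available groups are listed in the error.
#'
#' @param x A `NormalizedMatrix` whose `cells$passage` carries the labels.
#' @inheritParams test_contrast
#' @return Data frame of per-gene results with a leading `contrast` column
#'   (`"fresh_vs_P0"`, `"P0_vs_P1"`).
#' @export
passage_contrasts <- function(x, alpha = 0.05, m = NULL,
                              include_nonexpressers = TRUE) {
  stopifnot(inherits(x, "NormalizedMatrix"))
  present <- unique(x$cells$passage)
  pairs <- list(c("fresh", "P0"), c("P0", "P1"))
  runnable <- Filter(function(p) all(p %in% present), pairs)
  if (length(runnable) == 0L) {
    stop("no passage contrast possible; available groups: ",
         paste(present, collapse = ", "), call. = FALSE)
  }
  out <- lapply(runnable, function(p) {
    keep <- x$cells$passage %in% p
    sub <- subset_cells(x, keep)
    lab <- factor(sub$cells$passage, levels = p)
    res <- test_contrast(sub, lab, alpha = alpha, m = m,
                         include_nonexpressers = include_nonexpressers)
    cbind(contrast = paste(p, collapse = "_vs_"), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Subset a NormalizedMatrix by cells
#'
#' @param x A `NormalizedMatrix`.
#' @param keep Logical or integer cell index.
#' @return The subsetted `NormalizedMatrix` (medians and clip bound are kept
#'   from the pooled normalization, as the pipeline normalizes once over the
#'   full cohort).
#' @export
subset_cells <- function(x, keep) {
  stopifnot(inherits(x, "NormalizedMatrix"))
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$expresser <- x$expresser[keep, , drop = FALSE]
  out$cells <- x$cells[keep, , drop = FALSE]
  rownames(out$cells) <- NULL
  out
}

#' Gaussian per-group expression summaries
#'
#' For every gene and group: the mean and sample standard deviation of the
#' expressing reactions after centering at the group's expresser median
#' (the numbers behind median-centered Gaussian curve displays), together
#' with the expresser fraction (1 minus the failed-amplification fraction).
#' Groups with fewer than two expressers get `NA` spread and are flagged.
#'
#' @param x A `NormalizedMatrix`.
#' @param groups Per-cell group labels (any number of groups).
#' @return Data frame with columns `gene`, `group`, `n_cells`,
#'   `n_expressers`, `expresser_fraction`, `mean`, `sd`, `degenerate`.
#' @export
gaussian_summary <- function(x, groups) {
  stopifnot(inherits(x, "NormalizedMatrix"))
  if (length(groups) != nrow(x$values)) {
    stop("`groups` length does not match the number of cells", call. = FALSE)
  }
  f <- factor(groups, levels = unique(groups))
  out <- lapply(levels(f), function(gr) {
    idx <- which(f == gr)
    do.call(rbind, lapply(seq_along(x$genes), function(g) {
      v <- x$values[idx, g][x$expresser[idx, g]]
      n_e <- length(v)
      centered <- v - stats::median(v)
      data.frame(
        gene = x$genes[[g]], group = gr,
        n_cells = length(idx), n_expressers = n_e,
        expresser_fraction = n_e / length(idx),
        mean = if (n_e >= 1L) mean(centered) else NA_real_,
        sd = if (n_e >= 2L) stats::sd(centered) else NA_real_,
        degenerate = n_e < 2L,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
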