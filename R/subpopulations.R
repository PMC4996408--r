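# Subpopulation discovery: seeded k-means on the normalized log2 scale,
# silhouette-guided cluster-count selection, deterministic average-linkage
# ordering for clustergrams, and per-cluster passage composition.

.values_matrix <- function(x) {
  if (inherits(x, "NormalizedMatrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a NormalizedMatrix or a numeric matrix", call. = FALSE)
}

# Squared Euclidean distance of every row of x to every centroid row.
.dist2_to_centroids <- function(x, centroids) {
  cross <- x %*% t(centroids)
  sweep(-2 * cross, 2L, rowSums(centroids^2), "+") + rowSums(x^2)
}

#' Seeded k-means clustering of cells
#'
#' Partitions cells into `k` clusters by Lloyd's algorithm on the full
#' normalized gene space (floored non-expressers participate at the floor
#' value: dropout is part of a cell's expression profile), minimizing the
#' within-cluster sum of squared Euclidean distances (WCSS). Each restart
#' starts from a seeded center spread: the first center is a random cell,
#' each further center a cell drawn with probability proportional to its
#' squared distance from the centers chosen so far, so centers start well
#' separated while restarts still explore distinct initializations.
#' Clusters emptied during iteration are repaired by donating the cell
#' currently farthest from its own centroid, so exactly `k` clusters are
#' always returned. The best of `n_restarts` restarts (lowest WCSS) wins;
#' the whole procedure is deterministic given `seed`.
#'
#' @param x A `NormalizedMatrix` or numeric cells x genes matrix.
#' @param k Number of clusters (1 <= k <= cells).
#' @param n_restarts Number of seeded restarts (default 50).
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap per restart (default 100).
#' @return A `ClusterModel`: list with `k`, `centroids` (k x genes),
#'   `assignments` (integer per cell), `wcss`, `n_restarts`, `seed`,
#'   `iterations`.
#' @export
fit_kmeans <- function(x, k, n_restarts = 50L, seed = 1L, max_iter = 100L) {
  v <- .values_matrix(x)
  k <- .assert_count(k, "k")
  n_restarts <- .assert_count(n_restarts, "n_restarts")
  if (k > nrow(v)) {
    stop("k = ", k, " exceeds the number of cells (", nrow(v), ")",
         call. = FALSE)
  }
  if (any(!is.finite(v))) stop("x must be finite", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .with_local_seed(.mix_seed(seed, 7L, r),
                            .lloyd_once(v, k, max_iter))
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  structure(
    list(k = k, centroids = best$centroids, assignments = best$assignments,
         wcss = best$wcss, n_restarts = n_restarts, seed = seed,
         iterations = best$iterations),
    class = "ClusterModel"
  )
}

# Distance-squared-weighted center spreading (k-means++ seeding): favors
# well-separated starts; falls back to the farthest point if all remaining
# distances are zero (duplicate points).
.spread_init <- function(v, k) {
  centers <- integer(k)
  centers[1L] <- sample.int(nrow(v), 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(v, 2L, v[centers[1L], ], "-")^2)
    for (j in 2L:k) {
      tot <- sum(d2)
      centers[j] <- if (tot <= 0) which.max(d2) else
        sample.int(nrow(v), 1L, prob = d2 / tot)
      d2 <- pmin(d2, rowSums(sweep(v, 2L, v[centers[j], ], "-")^2))
    }
  }
  v[centers, , drop = FALSE]
}

.lloyd_once <- function(v, k, max_iter) {
  n <- nrow(v)
  centroids <- .spread_init(v, k)
  assign_old <- integer(n)
  wcss_old <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- .dist2_to_centroids(v, centroids)
    assignments <- max.col(-d2, ties.method = "first")
    # repair empty clusters: donate the cell farthest from its centroid
    repeat {
      sizes <- tabulate(assignments, k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      own <- d2[cbind(seq_len(n), assignments)]
      own[sizes[assignments] <= 1L] <- -Inf    # don't empty another cluster
      donor <- which.max(own)
      assignments[donor] <- empty[[1L]]
    }
    for (j in seq_len(k)) {
      centroids[j, ] <- colMeans(v[assignments == j, , drop = FALSE])
    }
    wcss <- sum((v - centroids[assignments, , drop = FALSE])^2)
    if (wcss > wcss_old + 1e-8) {
      stop("internal error: WCSS increased across a Lloyd iteration",
           call. = FALSE)
    }
    converged <- identical(assignments, assign_old) ||
      (is.finite(wcss_old) && abs(wcss_old - wcss) < 1e-10 * max(wcss_old, 1))
    assign_old <- assignments
    wcss_old <- wcss
    if (converged) break
  }
  list(centroids = centroids, assignments = assignments, wcss = wcss_old,
       iterations = it)
}

#' Within-cluster sum of squares of an arbitrary labeling
#'
#' @param v Numeric matrix of points (rows).
#' @param assignments Integer cluster label per row.
#' @return Total squared Euclidean distance of each point to its cluster
#'   mean.
#' @export
wcss_of <- function(v, assignments) {
  v <- .values_matrix(v)
  stopifnot(length(assignments) == nrow(v))
  sum(vapply(split(seq_len(nrow(v)), assignments), function(idx) {
    sub <- v[idx, , drop = FALSE]
    sum(sweep(sub, 2L, colMeans(sub), "-")^2)
  }, numeric(1L)))
}

#' Choose the cluster count by mean silhouette width
#'
#' Fits k-means for each candidate `k` and returns the `k` whose partition
#' maximizes the mean silhouette width over cells; ties break toward the
#' smaller `k`. The silhouette contrasts a cell's mean distance to its own
#' cluster against its mean distance to the nearest other cluster.
#'
#' @inheritParams fit_kmeans
#' @param k_min,k_max Candidate range (defaults 2..8).
#' @return The selected integer `k`. The per-`k` mean silhouette widths are
#'   attached as attribute `"silhouette"`, the fitted models as `"models"`.
#' @export
select_cluster_count <- function(x, k_min = 2L, k_max = 8L,
                                 n_restarts = 50L, seed = 1L) {
  v <- .values_matrix(x)
  k_min <- .assert_count(k_min, "k_min", lower = 2L)
  k_max <- .assert_count(k_max, "k_max")
  if (nrow(v) < 3L) stop("need at least 3 cells", call. = FALSE)
  if (k_max > nrow(v)) {
    stop("k_max = ", k_max, " exceeds the number of cells", call. = FALSE)
  }
  if (k_max < k_min) stop("k_max < k_min", call. = FALSE)
  d <- stats::dist(v)
  ks <- k_min:k_max
  models <- vector("list", length(ks))
  sil <- numeric(length(ks))
  for (i in seq_along(ks)) {
    models[[i]] <- fit_kmeans(v, ks[[i]], n_restarts = n_restarts,
                              seed = .mix_seed(seed, 31L, ks[[i]]))
    sw <- cluster::silhouette(models[[i]]$assignments, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  best <- ks[[which.max(sil)]]     # which.max: first max -> smaller k wins
  structure(best,
            silhouette = stats::setNames(sil, ks),
            models = stats::setNames(models, ks))
}

# Deterministic average-linkage (UPGMA) leaf order on a distance matrix.
# Merges the pair at minimal average distance; ties break toward the
# smallest pair of input indices; the earlier-created cluster stays on the
# left, so identical points keep their input order.
.average_linkage_order <- function(d) {
  n <- attr(d, "Size")
  if (is.null(n)) { d <- stats::as.dist(d); n <- attr(d, "Size") }
  if (n == 1L) return(1L)
  dm <- as.matrix(d)
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (ai in seq_along(idx)) {
      i <- idx[[ai]]
      for (bj in seq_along(idx)) {
        if (bj <= ai) next
        j <- idx[[bj]]
        if (dm[i, j] < best_d - 1e-12) { best_d <- dm[i, j]; best <- c(i, j) }
      }
    }
    i <- best[[1L]]; j <- best[[2L]]
    # Lance-Williams average-linkage update onto slot i
    idx_other <- setdiff(idx, c(i, j))
    if (length(idx_other) > 0L) {
      new_d <- (sizes[i] * dm[i, idx_other] + sizes[j] * dm[j, idx_other]) /
        (sizes[i] + sizes[j])
      dm[i, idx_other] <- new_d
      dm[idx_other, i] <- new_d
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  members[[which(active)]]
}

#' Hierarchical ordering of cells and genes for clustergram display
#'
#' Cells are ordered by cluster index first, then within each cluster by
#' average-linkage agglomeration on Euclidean distance with deterministic
#' input-index tie-breaking; genes are ordered by one global average-linkage
#' pass. The partition itself is untouched -- this ordering only arranges
#' rows and columns so expression patterning within and across clusters is
#' visible.
#'
#' @param x A `NormalizedMatrix` or numeric matrix the model was fitted on.
#' @param model A `ClusterModel` from [fit_kmeans()].
#' @return A `DendrogramOrder`: list with `cell_order` and `gene_order`,
#'   each a permutation of indices.
#' @export
order_hierarchically <- function(x, model) {
  v <- .values_matrix(x)
  stopifnot(inherits(model, "ClusterModel"),
            length(model$assignments) == nrow(v))
  cell_order <- unlist(lapply(seq_len(model$k), function(cl) {
    idx <- which(model$assignments == cl)
    if (length(idx) <= 2L) return(idx)
    idx[.average_linkage_order(stats::dist(v[idx, , drop = FALSE]))]
  }), use.names = FALSE)
  gene_order <- if (ncol(v) <= 2L) seq_len(ncol(v)) else
    .average_linkage_order(stats::dist(t(v)))
  structure(list(cell_order = cell_order, gene_order = gene_order),
            class = "DendrogramOrder")
}

#' Passage composition of each cluster
#'
#' Counts and fractions of cells from each passage group within each
#' cluster -- the numbers behind per-cluster composition pie charts.
#'
#' @param model A `ClusterModel`.
#' @param passages Character vector of per-cell passage labels, in the cell
#'   order the model was fitted on.
#' @return Data frame with columns `cluster`, `passage`, `n`, `fraction`;
#'   fractions sum to 1 within each cluster.
#' @export
composition <- function(model, passages) {
  stopifnot(inherits(model, "ClusterModel"))
  if (length(passages) != length(model$assignments)) {
    stop("`passages` length (", length(passages),
         ") does not match the number of clustered cells (",
         length(model$assignments), ")", call. = FALSE)
  }
  passages <- factor(passages, levels = unique(passages))
  tab <- table(cluster = model$assignments, passage = passages)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df$cluster <- as.integer(df$cluster)
  names(df)[names(df) == "Freq"] <- "n"
  totals <- stats::ave(df$n, df$cluster, FUN = sum)
  df$fraction <- df$n / totals
  df[order(df$cluster, match(df$passage, levels(passages))), c(
    "cluster", "passage", "n", "fraction"), drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and a reference
#' labeling: 1 for identical partitions (up to label permutation), ~0 for
#' independent ones. Used to score recovery of implanted subpopulations.
#'
#' @param a,b Two label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: k = %d, WCSS = %.4f (%d restarts, seed %d)\n",
              x$k, x$wcss, x$n_restarts, x$seed))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$k),
                                collapse = ", "), "\n")
  invisible(x)
}
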