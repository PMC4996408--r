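test_that("k = 1 recovers the grand centroid and total sum of squares", {
  set.seed(2)
  v <- matrix(rnorm(60), 15, 4)
  fit <- fit_kmeans(v, 1L, n_restarts = 3L, seed = 1L)
  expect_equal(fit$centroids[1, ], colMeans(v), ignore_attr = TRUE)
  expect_equal(fit$wcss, sum(sweep(v, 2, colMeans(v))^2))
  expect_identical(fit$assignments, rep(1L, 15))
})

test_that("two separated triads: partition and WCSS match exhaustive search", {
  v <- rbind(c(0, 0), c(0.4, 0), c(0, 0.4),
             c(10, 10), c(10.4, 10), c(10, 10.4))
  fit <- fit_kmeans(v, 2L, n_restarts = 10L, seed = 7L)
  expect_identical(fit$assignments[1:3], rep(fit$assignments[[1L]], 3))
  expect_identical(fit$assignments[4:6], rep(fit$assignments[[4L]], 3))
  expect_false(fit$assignments[[1L]] == fit$assignments[[4L]])
  expect_equal(fit$wcss, wcss_oracle(v, 2L), tolerance = 1e-12)
})

test_that("k-means attains the exhaustive WCSS minimum on random tiny sets", {
  set.seed(5)
  for (case in 1:4) {
    n <- sample(6:8, 1)
    v <- matrix(rnorm(n * 3), n, 3)
    for (k in 2:3) {
      fit <- fit_kmeans(v, k, n_restarts = 30L, seed = case)
      expect_equal(fit$wcss, wcss_oracle(v, k), tolerance = 1e-10)
      # model invariants: centroids are cluster means; wcss consistent
      for (j in seq_len(k)) {
        expect_equal(fit$centroids[j, ],
                     colMeans(v[fit$assignments == j, , drop = FALSE]),
                     ignore_attr = TRUE)
      }
      expect_equal(fit$wcss, wcss_of(v, fit$assignments))
      expect_true(all(tabulate(fit$assignments, k) > 0))
    }
  }
})

test_that("duplicating every cell doubles WCSS and keeps centroids", {
  set.seed(6)
  v <- matrix(rnorm(40), 10, 4)
  f1 <- fit_kmeans(v, 2L, n_restarts = 25L, seed = 9L)
  f2 <- fit_kmeans(rbind(v, v), 2L, n_restarts = 25L, seed = 9L)
  perm <- order(f1$centroids[, 1])
  perm2 <- order(f2$centroids[, 1])
  expect_equal(f1$centroids[perm, ], f2$centroids[perm2, ], tolerance = 1e-8)
  expect_equal(2 * f1$wcss, f2$wcss, tolerance = 1e-8)
})

test_that("fit_kmeans validates k and rejects non-finite input", {
  v <- matrix(rnorm(20), 5, 4)
  expect_error(fit_kmeans(v, 6L), "exceeds")
  expect_error(fit_kmeans(v, 0L), "k")
  v[1, 1] <- NA
  expect_error(fit_kmeans(v, 2L), "finite")
})

test_that("silhouette selection: separated point masses give k = 2, width 1", {
  v <- rbind(matrix(0, 5, 2), matrix(10, 5, 2))
  k <- select_cluster_count(v, k_min = 2L, k_max = 4L,
                            n_restarts = 10L, seed = 1L)
  expect_identical(as.integer(k), 2L)
  expect_equal(unname(attr(k, "silhouette")[["2"]]), 1)
})

test_that("mean silhouette agrees with a direct double-loop computation", {
  set.seed(12)
  v <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 4), 10, 2))
  fit <- fit_kmeans(v, 2L, n_restarts = 10L, seed = 2L)
  sw <- cluster::silhouette(fit$assignments, dist(v))
  expect_equal(mean(sw[, "sil_width"]), silhouette_oracle(v, fit$assignments),
               tolerance = 1e-12)
})

test_that("selection is invariant under cell permutation", {
  co <- generate_cohort(cohort_spec(cells_per_group = 20L, seed = 31L))
  x <- normalize_to_median(co$matrix)
  k1 <- select_cluster_count(x, k_max = 5L, n_restarts = 10L, seed = 3L)
  set.seed(99); perm <- sample(nrow(x$values))
  k2 <- select_cluster_count(x$values[perm, ], k_max = 5L,
                             n_restarts = 10L, seed = 3L)
  expect_identical(as.integer(k1), as.integer(k2))
})

test_that("implanted subpopulations are recovered on the default design", {
  co <- generate_cohort(default_study_spec(seed = 19L))
  x <- normalize_to_median(co$matrix)
  k <- select_cluster_count(x, n_restarts = 25L, seed = 19L)
  expect_identical(as.integer(k), 3L)
  model <- attr(k, "models")[["3"]]
  expect_gte(adjusted_rand_index(model$assignments, co$true_labels), 0.9)
})

test_that("adjusted Rand index matches mclust on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(8)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjusted_rand_index(1:2, c(5L, 9L)), 1)
})

test_that("hierarchical ordering: clusters contiguous, ties keep input order", {
  v <- matrix(0, 6, 3)
  model <- structure(list(k = 1L, assignments = rep(1L, 6),
                          centroids = matrix(0, 1, 3), wcss = 0,
                          n_restarts = 1L, seed = 1L),
                     class = "ClusterModel")
  ord <- order_hierarchically(v, model)
  expect_identical(ord$cell_order, 1:6)    # all ties: input order

  set.seed(14)
  v2 <- rbind(matrix(rnorm(12), 4, 3), matrix(rnorm(15, 6), 5, 3))
  m2 <- fit_kmeans(v2, 2L, n_restarts = 10L, seed = 4L)
  o2 <- order_hierarchically(v2, m2)
  expect_identical(sort(o2$cell_order), 1:9)
  expect_identical(sort(o2$gene_order), 1:3)
  cl_along_order <- m2$assignments[o2$cell_order]
  expect_identical(cl_along_order, sort(cl_along_order))  # contiguous blocks
})

test_that("average-linkage leaf order matches manual agglomeration on 4 points", {
  # 1D points 0, 10, 1, 24: d(1,3)=1 merges first -> {1,3};
  # d({1,3},2) = (10+9)/2 = 9.5 vs d(2,4)=14, d({1,3},4)=23.5,
  # so {1,3} joins 2; leaf order 1,3,2,4.
  v <- matrix(c(0, 10, 1, 24), ncol = 1)
  model <- structure(list(k = 1L, assignments = rep(1L, 4),
                          centroids = matrix(mean(v), 1, 1), wcss = 0,
                          n_restarts = 1L, seed = 1L),
                     class = "ClusterModel")
  ord <- order_hierarchically(cbind(v, 0), model)
  expect_identical(ord$cell_order, c(1L, 3L, 2L, 4L))
})

test_that("composition counts and fractions are conserved", {
  model <- structure(list(k = 2L, assignments = c(1L, 1L, 1L, 1L, 1L, 1L,
                                                  1L, 1L, 1L, 1L, 2L, 2L),
                          centroids = NULL, wcss = 0, n_restarts = 1L,
                          seed = 1L), class = "ClusterModel")
  passages <- c(rep("P0", 6), rep("P1", 4), "fresh", "fresh")
  comp <- composition(model, passages)
  c1 <- comp[comp$cluster == 1, ]
  expect_equal(c1$fraction[c1$passage == "P0"], 0.6)
  expect_equal(c1$fraction[c1$passage == "P1"], 0.4)
  c2 <- comp[comp$cluster == 2, ]
  expect_equal(c2$fraction[c2$passage == "fresh"], 1)
  expect_equal(sum(comp$n), 12L)
  agg <- tapply(comp$n, comp$passage, sum)
  expect_equal(as.vector(agg[c("fresh", "P0", "P1")]), c(2L, 6L, 4L))
  expect_error(composition(model, passages[-1]), "match")
})
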