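test_that("K-S statistic: identity, separation, and a hand-computed case", {
  expect_equal(ks_statistic(c(3, 1, 2), c(1, 2, 3)), 0)
  expect_equal(ks_statistic(c(0, 1), c(2, 3)), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_error(ks_statistic(numeric(0), 1), "non-empty")
})

test_that("K-S statistic equals the brute-force ECDF oracle on small instances", {
  # all pairs of samples with sizes 1..3 drawn from a tiny tied value set
  vals <- c(0, 1, 1, 2, 3)
  set.seed(20)
  for (rep in 1:200) {
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    a <- sample(vals, na, replace = TRUE)
    b <- sample(vals, nb, replace = TRUE)
    expect_equal(ks_statistic(a, b), ks_D_oracle(a, b))
  }
  # symmetry and invariance under a common strictly increasing transform
  set.seed(21)
  a <- rnorm(12); b <- rnorm(9, 0.5)
  expect_equal(ks_statistic(a, b), ks_statistic(b, a))
  expect_equal(ks_statistic(exp(a), exp(b)), ks_statistic(a, b))
})

test_that("exact small-n p-values match full interleaving enumeration", {
  for (sizes in list(c(3L, 3L), c(4L, 5L), c(5L, 5L), c(2L, 7L))) {
    na <- sizes[[1L]]; nb <- sizes[[2L]]
    # every achievable D is a multiple of 1/(na*nb); sweep a grid of them
    for (m in seq_len(na * nb)) {
      d <- m / (na * nb)
      expect_equal(ks_pvalue(d, na, nb, exact = TRUE),
                   ks_p_oracle(d, na, nb), tolerance = 1e-12,
                   label = sprintf("p(D=%d/%d, %d, %d)", m, na * nb, na, nb))
    }
  }
  expect_equal(ks_pvalue(1, 5, 5), 2 / choose(10, 5))
  expect_equal(ks_pvalue(0, 8, 3), 1)
})

test_that("asymptotic p: monotone in D, near-exact at n = 10, matches ks.test", {
  ps <- vapply(seq(0.05, 1, 0.05), ks_pvalue, numeric(1L),
               n_a = 40L, n_b = 60L, exact = FALSE)
  expect_true(all(diff(ps) <= 0))
  for (D in seq(0.3, 0.6, 0.1)) {
    pe <- ks_pvalue(D, 10L, 10L, exact = TRUE)
    pa <- ks_pvalue(D, 10L, 10L, exact = FALSE)
    expect_lt(abs(pa - pe) / pe, 0.10)
  }
  set.seed(30)
  a <- rnorm(80); b <- rnorm(120, 0.3)
  D <- ks_statistic(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(D, unname(ref$statistic))
  expect_equal(ks_pvalue(D, 80L, 120L), ref$p.value, tolerance = 1e-8)
})

test_that("contrast testing applies the Bonferroni threshold per gene", {
  # one gene shifted by 3 cycles between 80 and 160 cells; the rest null
  set.seed(41)
  ct <- matrix(rnorm(240 * 4, 25, 1), 240, 4)
  ct[1:80, 2] <- ct[1:80, 2] - 3
  x <- normalize_to_median(make_ct(ct, rep(c("fresh", "P0", "P1"), c(80, 80, 80))))
  grp <- rep(c("A", "B"), c(80, 160))
  res <- test_contrast(x, grp, alpha = 0.05, m = 48L)
  expect_identical(nrow(res), 4L)
  expect_equal(res$alpha_family / res$m_tests, rep(0.05 / 48, 4))
  expect_true(res$significant[[2L]])
  expect_false(any(res$significant[-2L]))
  expect_equal(res$n_a, rep(80L, 4)); expect_equal(res$n_b, rep(160L, 4))
  expect_error(test_contrast(x, rep("A", 240)), "two non-empty")
})

test_that("dropout fractions are reported per group and conserved", {
  ct <- matrix(c(20, NA, 21, NA, NA, 22, 23, 24), ncol = 2)
  x <- normalize_to_median(make_ct(ct, rep("fresh", 4)))
  res <- test_contrast(x, c("A", "A", "B", "B"), m = 2L)
  expect_equal(res$dropout_a, c(0.5, 0.5))
  expect_equal(res$dropout_b, c(0.5, 0))
  gs <- gaussian_summary(x, c("A", "A", "B", "B"))
  # rows: (G01, A), (G02, A), (G01, B), (G02, B)
  expect_equal(gs$expresser_fraction, c(0.5, 0.5, 0.5, 1))
  dropout <- c(res$dropout_a, res$dropout_b)   # same (gene, group) order
  expect_equal(gs$expresser_fraction + dropout, rep(1, 4))
})

test_that("expresser-only testing flags genes with empty expresser samples", {
  ct <- matrix(c(NA, NA, 21, 22, 25, 26, 27, 28), ncol = 2)
  x <- normalize_to_median(make_ct(ct, rep("fresh", 4)))
  res <- test_contrast(x, c("A", "A", "B", "B"), include_nonexpressers = FALSE)
  expect_true(is.na(res$D[[1L]]))
  expect_false(res$significant[[1L]])
  expect_false(is.na(res$D[[2L]]))
})

test_that("cluster-vs-rest: k = 1 errors; implanted block is flagged", {
  co <- generate_cohort(default_study_spec(seed = 23L))
  x <- normalize_to_median(co$matrix)
  m1 <- structure(list(k = 1L, assignments = rep(1L, nrow(x$values)),
                       wcss = 0, n_restarts = 1L, seed = 1L),
                  class = "ClusterModel")
  expect_error(cluster_vs_rest(x, m1), "k >= 2")

  model <- fit_kmeans(x, 3L, n_restarts = 20L, seed = 23L)
  res <- cluster_vs_rest(x, model)
  # each true subpopulation up-shifts its own 10-gene block ~16-fold;
  # map fitted clusters to truth by majority and check the block is called
  for (cl in 1:3) {
    truth <- as.integer(names(which.max(table(
      co$true_labels[model$assignments == cl]))))
    block <- paste0("G", sprintf("%02d", ((truth - 1) * 10 + 1):(truth * 10)))
    called <- res$gene[res$cluster == cl & res$significant]
    expect_true(all(block %in% called))
  }
})

test_that("identical groups by construction yield no significant gene", {
  set.seed(51)
  ct <- matrix(rnorm(40 * 6, 25, 1), 40, 6)
  ct2 <- rbind(ct, ct)   # exchangeable by construction
  x <- normalize_to_median(make_ct(ct2, rep("fresh", 80)))
  res <- test_contrast(x, rep(c("A", "B"), each = 40))
  expect_equal(res$D, rep(0, 6))
  expect_false(any(res$significant))
})

test_that("passage contrasts run the design's two transitions", {
  co <- generate_cohort(cohort_spec(cells_per_group = 20L, seed = 33L))
  x <- normalize_to_median(co$matrix)
  res <- passage_contrasts(x)
  expect_setequal(unique(res$contrast), c("fresh_vs_P0", "P0_vs_P1"))
  expect_identical(nrow(res), 2L * 48L)

  keep <- x$cells$passage %in% c("fresh", "P0")
  sub <- subset_cells(x, keep)
  res2 <- passage_contrasts(sub)
  expect_identical(unique(res2$contrast), "fresh_vs_P0")

  only_fresh <- subset_cells(x, x$cells$passage == "fresh")
  expect_error(passage_contrasts(only_fresh), "available groups")
})

test_that("a shifted gene is called in the fresh-to-P0 transition", {
  set.seed(61)
  ct <- matrix(rnorm(90 * 4, 25, 1), 90, 4)
  pass <- rep(c("fresh", "P0", "P1"), each = 30)
  ct[pass == "P0", 3] <- ct[pass == "P0", 3] - 3   # 8-fold up at P0
  x <- normalize_to_median(make_ct(ct, pass))
  res <- passage_contrasts(x, m = 4L)
  hit <- res[res$contrast == "fresh_vs_P0" & res$gene == "G03", ]
  expect_true(hit$significant)
})

test_that("Bonferroni nesting: calls at a smaller alpha are a subset", {
  co <- generate_cohort(cohort_spec(cells_per_group = 30L, seed = 71L))
  x <- normalize_to_median(co$matrix)
  model <- fit_kmeans(x, 3L, n_restarts = 10L, seed = 71L)
  strict <- cluster_vs_rest(x, model, alpha = 0.01)
  loose <- cluster_vs_rest(x, model, alpha = 0.05)
  key <- function(r) paste(r$cluster, r$gene)[r$significant]
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("family-wise error is controlled under a pure-null cohort", {
  # 60 replicates here (the deeper 200-replicate run lives in the
  # acceptance suite); each replicate tests fresh vs P0 on a no-shift cohort
  hits <- vapply(1:60, function(r) {
    co <- generate_cohort(null_spec(seed = 1000L + r, cells_per_group = 25L))
    x <- normalize_to_median(co$matrix)
    keep <- x$cells$passage %in% c("fresh", "P0")
    res <- test_contrast(subset_cells(x, keep),
                         x$cells$passage[keep])
    any(res$significant)
  }, logical(1L))
  fwer <- mean(hits)
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})

test_that("Gaussian summaries center at the group expresser median", {
  ct <- matrix(c(24, 25, 26, NA), ncol = 1)
  x <- normalize_to_median(make_ct(ct, rep("fresh", 4)))
  gs <- gaussian_summary(x, rep("g1", 4))
  expect_equal(gs$mean, 0)        # {-1, 0, 1} centered
  expect_equal(gs$sd, 1)          # sample sd
  expect_equal(gs$expresser_fraction, 0.75)
  expect_false(gs$degenerate)

  ct2 <- matrix(c(NA, NA, NA, 25, 26, 27), ncol = 1)
  x2 <- normalize_to_median(make_ct(ct2, rep("fresh", 6)))
  gs2 <- gaussian_summary(x2, rep(c("dead", "live"), each = 3))
  dead <- gs2[gs2$group == "dead", ]
  expect_equal(dead$expresser_fraction, 0)
  expect_true(dead$degenerate)
  expect_true(is.na(dead$sd))
})
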