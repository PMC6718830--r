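test_that("size factors recover depth ratios and match the external implementation", {
  m <- small_counts(80, 4, seed = 8, mu = 100)
  doubled <- cbind(m[, 1, drop = FALSE], m[, 1, drop = FALSE] * 2L)
  colnames(doubled) <- c("A", "B")
  sf <- size_factors(doubled)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  same <- m[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(size_factors(same)), rep(1, 3))

  with_zero <- rbind(m, zero = 0L)
  expect_equal(size_factors(with_zero), size_factors(m))

  # cross-check against the reference median-of-ratios implementation
  # (odd gene count: the reference takes medians on the log scale, which
  # coincides with the ratio-scale median only at an exact order statistic)
  m_odd <- small_counts(81, 4, seed = 8, mu = 100)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m_odd)
  ours <- size_factors(m_odd)
  expect_equal(unname(ours / exp(mean(log(ours)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-8)
})

test_that("BH q values match the brute-force oracle and handle missing p", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  p <- c(0.01, NA, 0.5)
  q <- bh_fdr(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], oracle_bh(p[c(1, 3)]))
})

test_that("the NB LRT is calibrated under the null and powered for planted effects", {
  cs <- cohort_spec(n_per_group = c(lymphoid = 10, myeloid = 10, fibroid = 10),
                    n_genes = 600,
                    de_class_sizes = c(L = 30, M = 0, F = 0, LM = 0, MF = 0,
                                       LF = 0),
                    log2_effect = 2, ungraded_frac = 0,
                    library_size_range = c(1, 1), seed = 17)
  co <- generate_cohort(cs)
  fit <- fit_nb_lrt(co$counts, co$annotations$pathotype)
  q <- bh_fdr(fit$p)
  planted <- names(co$truth$de_class_map)
  expect_gt(mean(q[match(planted, rownames(co$counts))] < 0.05), 0.9)
  null_p <- fit$p[!rownames(co$counts) %in% planted]
  null_p <- null_p[!is.na(null_p)]
  expect_gt(suppressWarnings(ks.test(null_p, "punif")$p.value), 0.01)

  # an all-equal gene carries no group signal at unit normalisation
  flat <- co$counts
  flat[1, ] <- 55L
  p_flat <- fit_nb_lrt(flat, co$annotations$pathotype,
                       size_factors = rep(1, ncol(flat)))$p[1]
  expect_equal(p_flat, 1, tolerance = 1e-6)
})

test_that("per-gene statistics are invariant to sample order", {
  cs <- cohort_spec(n_per_group = c(lymphoid = 5, myeloid = 5, fibroid = 5),
                    n_genes = 120,
                    de_class_sizes = c(L = 10, M = 0, F = 0, LM = 0, MF = 0,
                                       LF = 0), ungraded_frac = 0, seed = 2)
  co <- generate_cohort(cs)
  de1 <- run_threeway_de(co$counts, co$annotations$pathotype)
  perm <- sample(ncol(co$counts))
  de2 <- run_threeway_de(co$counts[, perm], co$annotations$pathotype[perm])
  expect_equal(de2$lrt_p, de1$lrt_p, tolerance = 1e-9)
  expect_equal(de2$color_class, de1$color_class)
  expect_equal(de2$mean_lymphoid, de1$mean_lymphoid, tolerance = 1e-12)
})

test_that("colour classes follow the minimum-reference pairwise rules", {
  means <- rbind(c(5, 1, 1), c(5, 5, 1), c(5, 1, 1), c(2, 1, 1), c(1, 1, 5))
  colnames(means) <- c("lymphoid", "myeloid", "fibroid")
  pq <- matrix(1, 5, 3,
               dimnames = list(NULL, c("lymphoid.myeloid", "myeloid.fibroid",
                                       "lymphoid.fibroid")))
  pq[1, c("lymphoid.myeloid", "lymphoid.fibroid")] <- 0.001  # L up alone
  pq[2, c("lymphoid.fibroid", "myeloid.fibroid")] <- 0.001   # L+M up vs F
  pq[3, ] <- 1                                               # LRT sig, no pair
  pq[5, c("lymphoid.fibroid", "myeloid.fibroid")] <- 0.001   # F up vs tie ref
  lrt_q <- c(0.001, 0.001, 0.001, 0.2, 0.001)
  cls <- assign_color_class(means, lrt_q, pq)
  expect_equal(cls[1:4], c("blue", "purple", "gray", "gray"))
  expect_equal(attr(cls, "anomalies"), 3L)
  # row 5: exact tie for the minimum resolved fibroid < myeloid < lymphoid,
  # so the reference is myeloid and fibroid's q column alone makes it green
  expect_equal(attr(cls, "ref_group")[5], "myeloid")
  expect_equal(cls[5], "green")
})

test_that("upregulation requires a positive fold change, not just a small q", {
  means <- rbind(c(1, 5, 5))
  colnames(means) <- c("lymphoid", "myeloid", "fibroid")
  pq <- matrix(0.001, 1, 3,
               dimnames = list(NULL, c("lymphoid.myeloid", "myeloid.fibroid",
                                       "lymphoid.fibroid")))
  cls <- assign_color_class(means, 0.001, pq)
  expect_equal(as.character(cls), "yellow")    # M and F up vs reference L
})

test_that("clustering of DE genes recovers planted blocks and validates k", {
  set.seed(6)
  block1 <- matrix(rnorm(200, 5), 20, 10)
  block2 <- matrix(rnorm(200, -5), 20, 10)
  x <- rbind(cbind(block1, block2), cbind(block2, block1))
  rownames(x) <- sprintf("g%02d", 1:40)
  res <- cluster_de_genes(x, k = 2)
  truth <- rep(1:2, each = 20)
  expect_equal(mclust::adjustedRandIndex(res$labels, truth), 1)
  expect_error(cluster_de_genes(x, k = 41), "exceeds")
  expect_error(cluster_de_genes(x[1, , drop = FALSE], k = 1), "2 genes")
})

test_that("group mean Z rows are centred weighted combinations of group signals", {
  co <- generate_cohort(cohort_spec(
    n_per_group = c(lymphoid = 5, myeloid = 5, fibroid = 5), n_genes = 100,
    de_class_sizes = c(L = 0, M = 0, F = 0, LM = 0, MF = 0, LF = 0),
    ungraded_frac = 0, seed = 4))
  z <- group_mean_z(co$counts, co$annotations$pathotype)
  # group means of a per-gene Z with equal group sizes average to ~0
  expect_equal(max(abs(rowMeans(z))), 0, tolerance = 1e-10)
  expect_equal(colnames(z), c("fibroid", "lymphoid", "myeloid"))
})
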