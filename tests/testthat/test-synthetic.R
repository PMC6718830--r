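test_that("atlas generation respects sizes, invariants and determinism", {
  spec <- atlas_spec(n_tissues = 20, n_genes = 1000, n_markers_per_tissue = 10,
                     marker_effect = 8, n_broad_genes = 0, seed = 1)
  res <- generate_atlas(spec)
  expect_equal(dim(res$atlas), c(1000, 20))
  expect_equal(length(res$truth$marker_genes), 200)
  expect_equal(length(res$truth$marker_map), 20)
  expect_true(all(res$atlas >= 0))

  res2 <- generate_atlas(spec)
  expect_identical(res$atlas, res2$atlas)

  expect_error(atlas_spec(marker_effect = 0), "marker_effect")
  expect_error(atlas_spec(n_tissues = 10, n_genes = 50,
                          n_markers_per_tissue = 10), "n_genes")
})

test_that("planted markers carry recoverable Z scores in their home tissue", {
  res <- generate_atlas(atlas_spec(seed = 5))
  z <- zscore_tissues(res$atlas)
  home_z <- mapply(function(tissue, genes) mean(z[genes, tissue]),
                   names(res$truth$marker_map), res$truth$marker_map)
  expect_gt(mean(home_z), 5)
  broad_count <- rowSums(z[res$truth$broad_genes, ] > 3)
  expect_gt(mean(broad_count >= 10), 0.9)
})

test_that("cohort generation plants classes, obeys the histology rules, and is deterministic", {
  spec <- cohort_spec(seed = 8)
  co <- generate_cohort(spec)
  expect_equal(dim(co$counts), c(2000, 65))
  expect_equal(length(co$truth$de_class_map), 300)
  expect_equal(as.integer(table(co$truth$de_class_map)[c("L", "MF")]),
               c(50L, 50L))
  expect_true(all(co$counts == round(co$counts)) && all(co$counts >= 0))

  calls <- classify_pathotype(co$histology)
  graded <- co$truth$histology_label != "ungraded"
  expect_equal(calls$pathotype[graded],
               unname(co$truth$histology_label[graded]))
  expect_equal(calls$pathotype[graded], co$annotations$pathotype[graded])

  co2 <- generate_cohort(spec)
  expect_identical(co, co2)

  expect_error(
    generate_cohort(spec, modules = list(list(label = "x", genes = "g99999"))),
    "g99999")
  expect_error(cohort_spec(n_per_group = c(2, 3, 3)), "group sizes")
  expect_error(cohort_spec(n_genes = 100,
                           de_class_sizes = c(L = 50, M = 50, F = 0, LM = 0,
                                              MF = 0, LF = 0)), "below n_genes")
})

test_that("a planted fibroid sample satisfies the fibroid score region", {
  spec <- cohort_spec(n_per_group = c(lymphoid = 3, myeloid = 3, fibroid = 20),
                      n_genes = 30,
                      de_class_sizes = c(L = 0, M = 0, F = 0, LM = 0, MF = 0,
                                         LF = 0),
                      ungraded_frac = 0, seed = 3)
  co <- generate_cohort(spec)
  fib <- co$histology[co$annotations$pathotype == "fibroid", ]
  expect_true(all(fib$CD68SL < 2))
  expect_true(all(fib$CD3 < 1 & fib$CD20 < 1 & fib$CD138 < 1))
})

test_that("planted clinical correlations are recovered from the true activity", {
  mods <- list(list(label = "plasma", genes = sprintf("g%05d", 1:10)))
  rhos <- sapply(1:5, function(s) {
    spec <- cohort_spec(
      n_per_group = c(lymphoid = 25, myeloid = 20, fibroid = 20),
      n_genes = 200,
      de_class_sizes = c(L = 0, M = 0, F = 0, LM = 0, MF = 0, LF = 0),
      clinical_effect_map = data.frame(module = "plasma", trait = "CCP_titer",
                                       rho = 0.5), seed = s)
    co <- generate_cohort(spec, mods)
    cor(co$truth$module_activity[, "plasma"], co$clinical$CCP_titer,
        method = "spearman")
  })
  expect_true(all(rhos > 0.30 & rhos < 0.70))
  expect_gt(mean(rhos), 0.4)
})

test_that("follow-up generation plants the response relation and a clean null", {
  spec <- cohort_spec(n_per_group = c(lymphoid = 30, myeloid = 30,
                                      fibroid = 30),
                      n_genes = 20,
                      de_class_sizes = c(L = 0, M = 0, F = 0, LM = 0, MF = 0,
                                         LF = 0), ungraded_frac = 0, seed = 1)
  co <- generate_cohort(spec)
  base_calls <- classify_pathotype(co$histology)

  r1 <- sapply(1:10, function(s) {
    fu <- generate_followup(co$histology, response_strength = 1, seed = s)
    shift_vs_response(base_calls, fu$calls, fu$delta_das28)$r
  })
  expect_gt(mean(r1), 0.25)

  r0 <- sapply(1:10, function(s) {
    fu <- generate_followup(co$histology, response_strength = 0, seed = s)
    shift_vs_response(base_calls, fu$calls, fu$delta_das28)$r
  })
  expect_lt(mean(abs(r0)), 0.2)

  fu <- generate_followup(co$histology, response_strength = 1, seed = 4)
  fu2 <- generate_followup(co$histology, response_strength = 1, seed = 4)
  expect_identical(fu, fu2)
  # shifts recomputed from the follow-up calls agree with the planted ones
  ord_b <- inflammation_ordinal(base_calls$pathotype)
  ord_f <- inflammation_ordinal(fu$calls$pathotype)
  expect_equal(unname(fu$shift), ord_b - ord_f)
})
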