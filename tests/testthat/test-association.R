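make_scores <- function(n = 60, mods = c("plasma", "bcell"), seed = 15) {
  set.seed(seed)
  s <- matrix(rnorm(length(mods) * n), length(mods), n,
              dimnames = list(mods, sprintf("S%03d", 1:n)))
  s
}

test_that("spearman module-trait association recovers perfect and null relations", {
  s <- make_scores()
  clin <- data.frame(sample_id = colnames(s),
                     CCP_titer = exp(s["plasma", ]),   # monotone transform
                     noise = rnorm(60))
  res <- spearman_module_trait(s, clin)
  row <- res[res$module == "plasma" & res$trait == "CCP_titer", ]
  expect_equal(row$rho, 1)
  expect_lt(row$p, 1e-10)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
  # invariance under a strictly monotone transform of the trait
  clin2 <- clin
  clin2$CCP_titer <- log(clin2$CCP_titer + 1)^3
  res2 <- spearman_module_trait(s, clin2)
  expect_equal(res2$rho, res$rho)
})

test_that("association families, missing data and degenerate vectors are handled", {
  s <- make_scores(n = 40)
  clin <- data.frame(sample_id = colnames(s), trait_a = rnorm(40),
                     flat = rep(2.5, 40))
  clin$trait_a[1:36] <- NA      # 4 complete pairs only
  res <- spearman_module_trait(s, clin)
  expect_equal(res$flag[res$trait == "trait_a"], rep("insufficient", 2))
  expect_equal(res$flag[res$trait == "flat"], rep("degenerate", 2))
  expect_true(all(is.na(res$q)))
  expect_error(spearman_module_trait(s, data.frame(sample_id = "x", y = 1)),
               "lacks sample")
})

test_that("null spearman associations reject at the nominal rate", {
  set.seed(16)
  rej <- replicate(500, {
    ct <- suppressWarnings(cor.test(rnorm(50), rnorm(50),
                                    method = "spearman", exact = FALSE))
    ct$p.value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})

test_that("concordance labels require dual significance with matching sign", {
  syn <- data.frame(module = c("m1", "m2", "m3", "m4"), trait = "DAS28",
                    rho = c(0.6, 0.5, 0.4, 0.5), q = c(0.01, 0.01, 0.5, 0.01))
  bld <- data.frame(module = c("m1", "m2", "m3", "m4"), trait = "DAS28",
                    rho = c(0.5, -0.4, 0.3, 0.2), q = c(0.01, 0.01, 0.01, 0.5))
  lab <- concordance_classify(syn, bld)
  expect_equal(lab$concordance, c("both", "neither", "blood_only",
                                  "synovium_only"))
  expect_error(concordance_classify(syn, bld[1:3, ]), "both compartments")
})

test_that("hypergeometric annotation matches the exact-sum oracle", {
  universe <- sprintf("g%04d", 1:1000)
  marker <- universe[1:20]
  res <- hypergeom_annotate(marker, list(hit = marker,
                                         none = universe[900:950]), universe)
  hit <- res[res$label == "hit", ]
  expect_equal(hit$overlap, 20)
  expect_equal(log(hit$p), -lchoose(1000, 20), tolerance = 1e-8)
  expect_gt(res$p[res$label == "none"], 0.3)
  expect_equal(attr(res, "best_label"), "hit")

  # module = universe forces every overlap; all p collapse to 1
  res_all <- hypergeom_annotate(universe, list(a = marker), universe)
  expect_equal(res_all$p, 1)

  set.seed(17)
  for (i in 1:25) {
    N <- sample(10:60, 1)
    uni <- sprintf("u%02d", 1:N)
    mod <- sample(uni, sample(2:(N - 1), 1))
    set1 <- sample(uni, sample(2:(N - 1), 1))
    got <- hypergeom_annotate(mod, list(s = set1), uni)
    want <- oracle_hyper_upper(got$overlap, length(set1), N, length(mod))
    expect_equal(got$p, want, tolerance = 1e-10)
  }
  expect_error(hypergeom_annotate(c("zzz"), list(a = marker), universe),
               "outside")
  expect_error(hypergeom_annotate(character(0), list(a = marker), universe),
               "empty")
})

test_that("group module test finds a planted shift and is calibrated under permutation", {
  set.seed(18)
  grp <- rep(c("yes", "no"), each = 30)
  s <- make_scores(n = 60, mods = c("plasma", "other"), seed = 18)
  s["plasma", grp == "yes"] <- s["plasma", grp == "yes"] + 1
  res <- group_module_test(s, grp)
  expect_lt(res$q[res$module == "plasma"], 0.05)
  expect_gt(abs(res$effect[res$module == "plasma"]), 0.5)

  perm_rej <- replicate(400, {
    g <- sample(grp)
    min(group_module_test(s["other", , drop = FALSE], g)$p) < 0.05
  })
  expect_gt(mean(perm_rej), 0.02)
  expect_lt(mean(perm_rej), 0.09)

  same <- matrix(rep(1:10, 2), 1, 20, dimnames = list("m", NULL))
  res_same <- group_module_test(same, rep(c("a", "b"), each = 10))
  expect_equal(res_same$p, 1)
  expect_error(group_module_test(s, rep(c("a", "b"), c(58, 2))), "3 samples")
})
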