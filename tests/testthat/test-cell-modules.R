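test_that("collapse keeps the dominant feature per gene with lexicographic ties", {
  vals <- rbind(p1 = c(4, 6), p2 = c(6, 8), p3 = c(1, 1), p4 = c(5, 7),
                p0 = c(5, 7))
  colnames(vals) <- c("t1", "t2")
  fm <- data.frame(feature_id = c("p1", "p2", "p3", "p4", "p0"),
                   gene_id = c("gA", "gA", "gB", "gC", "gC"))
  out <- collapse_to_dominant_feature(vals, fm)
  expect_equal(rownames(out), c("gA", "gB", "gC"))
  expect_equal(out["gA", ], vals["p2", ])          # higher mean wins
  expect_equal(out["gB", ], vals["p3", ])          # single feature unchanged
  used <- attr(out, "feature_used")
  expect_equal(unname(used["gC"]), "p0")           # exact tie -> lexicographic
  expect_error(collapse_to_dominant_feature(
    vals, data.frame(feature_id = c("p1", "p1"), gene_id = c("gA", "gB"))),
    "exactly one")
  expect_warning(collapse_to_dominant_feature(
    vals, rbind(fm, data.frame(feature_id = "missing", gene_id = "gZ"))),
    "no measured feature")
})

test_that("Z scoring is exact, flags constant genes, and is idempotent", {
  a <- rbind(spike = c(10, rep(0, 19)), flat = rep(3, 20))
  colnames(a) <- sprintf("T%02d", 1:20)
  z <- zscore_tissues(a)
  # closed form: mean 0.5, sample SD sqrt(5)
  expect_equal(max(z["spike", ]), (10 - 0.5) / sqrt(5), tolerance = 1e-12)
  expect_equal(unname(z["flat", ]), rep(0, 20))
  expect_identical(attr(z, "zero_variance"), "flat")
  z2 <- zscore_tissues(z[, , drop = FALSE])
  expect_equal(z2["spike", ], z["spike", ], tolerance = 1e-12)
  expect_error(zscore_tissues(a[, 1, drop = FALSE]), "2 tissues")
})

test_that("module criteria include planted markers and exclude broad and low-rank genes", {
  nt <- 200
  tissues <- sprintf("T%03d", 1:nt)
  a <- matrix(5, 4, nt, dimnames = list(c("marker", "broad", "rank4", "weak"),
                                        tissues))
  a["marker", 1] <- 12
  a["broad", 1:12] <- 17                       # elevated in 12 tissues
  a["rank4", 1:4] <- c(30, 29, 28, 27)         # target T004 has rank 4
  a["weak", ] <- rep(c(4, 6), nt / 2)          # within-row spread ~1
  a["weak", 1] <- 8                            # spike too small for Z > 5
  z <- zscore_tissues(a)
  m1 <- derive_module(z, "T001")
  expect_true("marker" %in% m1$genes)
  expect_false("broad" %in% m1$genes)          # specificity score >= 10
  expect_true(sum(z["broad", ] > 3) >= 10)
  expect_false("weak" %in% m1$genes)           # Z below 5
  m4 <- derive_module(z, "T004")
  expect_true(z["rank4", "T004"] > 5)
  expect_false("rank4" %in% m4$genes)          # rank 4 despite Z > 5
  expect_error(derive_module(z, "nope"), "unknown tissue")
})

test_that("derive_module matches the brute-force filter oracle on random atlases", {
  for (seed in 1:5) {
    set.seed(seed)
    nt <- 25; ng <- 80
    a <- matrix(rexp(ng * nt), ng, nt,
                dimnames = list(sprintf("g%02d", 1:ng), sprintf("T%02d", 1:nt)))
    a[sample(ng, 10), sample(nt, 1)] <- a[sample(ng, 10), sample(nt, 1)] + 30
    z <- zscore_tissues(a)
    for (tissue in sample(colnames(a), 3)) {
      got <- derive_module(z, tissue, z_min = 1.5, rank_max = 3,
                           spec_max = 5, z_spec = 1)$genes
      want <- oracle_derive(z, tissue, z_min = 1.5, rank_max = 3,
                            spec_max = 5, z_spec = 1,
                            excluded = attr(z, "zero_variance"))
      expect_identical(got, want)
    }
  }
})

test_that("criteria are monotone in their thresholds", {
  set.seed(9)
  a <- matrix(rexp(50 * 20), 50, 20,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("T%02d", 1:20)))
  z <- zscore_tissues(a)
  base <- derive_module(z, "T01", z_min = 1, rank_max = 5, spec_max = 10,
                        z_spec = 1)$genes
  tighter_z <- derive_module(z, "T01", z_min = 2, rank_max = 5,
                             spec_max = 10, z_spec = 1)$genes
  tighter_rank <- derive_module(z, "T01", z_min = 1, rank_max = 2,
                                spec_max = 10, z_spec = 1)$genes
  tighter_spec <- derive_module(z, "T01", z_min = 1, rank_max = 5,
                                spec_max = 3, z_spec = 1)$genes
  expect_true(all(tighter_z %in% base))
  expect_true(all(tighter_rank %in% base))
  expect_true(all(tighter_spec %in% base))
})

test_that("GMT round trip preserves derived modules", {
  sets <- list(mA = c("g1", "g2", "g3"), mB = c("g9", "g2"))
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(lapply(back, as.character), sets)
})
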