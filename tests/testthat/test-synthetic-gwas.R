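test_that("truth model enforces its invariants", {
  expect_error(truth_model(matrix(1, 2, 1), matrix(c(1, 0.5, 0.6, 1), 2, 2),
                           c(0.3, 0.3), c(1e4, 1e4)),
               "symmetric")
  expect_error(truth_model(matrix(1.2, 2, 1), matrix(1, 1, 1),
                           c(0.3, 0.3), c(1e4, 1e4)),
               "communality")
  tr <- truth10()
  G <- implied_gcov(tr)
  expect_equal(diag(G), tr$trait_h2, ignore_attr = TRUE)
  expect_true(isSymmetric(G))
  expect_gt(min(eigen(G, only.values = TRUE)$values), 0)
})

test_that("LD structure has valid blocks, scores and coordinates", {
  ld <- ld_structure(n_snps_per_chr = 200, block_size = 20, within_r2 = 0.2)
  expect_true(all(ld$snps$l2 >= 1))
  expect_equal(ld$snps$l2, 1 + (ld$block_sizes[ld$snps$block] - 1) * 0.2)
  # blocks never span a chromosome boundary
  expect_true(all(tapply(ld$snps$chr, ld$snps$block,
                         function(x) length(unique(x))) == 1))
  # positions strictly increasing within chromosomes
  for (cc in unique(ld$snps$chr)) {
    bp <- ld$snps$bp[ld$snps$chr == cc]
    expect_true(all(diff(bp) > 0))
  }
  expect_equal(length(unique(ld$snps$chr)), 22L)
})

test_that("forced rg = 1 yields perfectly correlated true effects", {
  tr <- truth_model(matrix(1, 2, 1), matrix(1, 1, 1), c(0.3, 0.3),
                    c(2e4, 2e4))
  ld <- ld_structure(n_snps_per_chr = 4546, block_size = 50)
  eff <- simulate_true_effects(tr, ld, 1, seed = 1)
  expect_gt(nrow(eff), 1e5 - 100)
  expect_equal(stats::cor(eff[, 1], eff[, 2]), 1, tolerance = 1e-6)
})

test_that("zero-heritability traits get exactly zero effects", {
  tr <- truth_model(matrix(c(1, 0), 2, 1), matrix(1, 1, 1), c(0.3, 0),
                    c(2e4, 2e4))
  ld <- ld_structure(n_snps_per_chr = 100)
  eff <- simulate_true_effects(tr, ld, 1, seed = 2)
  expect_true(all(eff[, 2] == 0))
})

test_that("empirical genetic covariance matches the truth product at M = 50k", {
  tr <- truth10()
  ld <- ld50k()
  eff <- simulate_true_effects(tr, ld, 1, seed = 3)
  emp <- crossprod(eff)
  G <- implied_gcov(tr)
  expect_lt(max(abs(emp - G)), 0.02)
})

test_that("true-effect simulation is deterministic and rejects bad input", {
  tr <- truth10()
  ld <- ld_structure(n_snps_per_chr = 100)
  e1 <- simulate_true_effects(tr, ld, 0.5, seed = 9)
  e2 <- simulate_true_effects(tr, ld, 0.5, seed = 9)
  expect_identical(e1, e2)
  expect_error(simulate_true_effects(tr, ld, 0, seed = 1), "polygenicity")
  expect_error(simulate_true_effects(tr, ld, 1), "seed")
})

test_that("huge N makes estimated effects converge to LD-smoothed truth", {
  tr <- truth_model(matrix(sqrt(0.5), 1, 1), matrix(1, 1, 1), 0.5, 1e9,
                    trait_names = "t1")
  ld <- ld_structure(n_snps_per_chr = 100)
  eff <- simulate_true_effects(tr, ld, 1, seed = 4)
  tabs <- simulate_sumstats(eff, tr, ld, seed = 5)
  smooth <- ld_smooth_effects(eff, ld)
  expect_lt(max(abs(tabs[[1]]$BETA - smooth[, 1])), 1e-3)
})

test_that("no sample overlap leaves cross-trait noise uncorrelated", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0, 0), c(2e4, 2e4))
  ld <- ld50k()
  eff <- simulate_true_effects(tr, ld, 1, seed = 6)
  tabs <- simulate_sumstats(eff, tr, ld, seed = 7)
  z1 <- tabs[[1]]$BETA / tabs[[1]]$SE
  z2 <- tabs[[2]]$BETA / tabs[[2]]$SE
  expect_lt(abs(stats::cor(z1, z2)), 0.02)
})

test_that("full overlap with phenotypic correlation 0.5 gives mean z1*z2 near 0.5", {
  ov <- matrix(c(1, 1, 1, 1), 2, 2)
  pc <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0, 0), c(2e4, 2e4),
                    overlap_frac = ov, phenotypic_corr_overlap = pc)
  ld <- ld50k()
  eff <- simulate_true_effects(tr, ld, 1, seed = 8)
  tabs <- simulate_sumstats(eff, tr, ld, seed = 9)
  z1 <- tabs[[1]]$BETA / tabs[[1]]$SE
  z2 <- tabs[[2]]$BETA / tabs[[2]]$SE
  expect_equal(mean(z1 * z2), 0.5, tolerance = 0.03)
})

test_that("sumstats simulation refuses to run without a seed", {
  tr <- truth10()
  ld <- ld_structure(n_snps_per_chr = 50)
  eff <- simulate_true_effects(tr, ld, 1, seed = 1)
  expect_error(simulate_sumstats(eff, tr, ld), "seed")
})

test_that("simulated tables are byte-identical under identical seeds", {
  tr <- truth10()
  ld <- ld_structure(n_snps_per_chr = 50)
  eff <- simulate_true_effects(tr, ld, 1, seed = 1)
  t1 <- simulate_sumstats(eff, tr, ld, seed = 2)
  t2 <- simulate_sumstats(eff, tr, ld, seed = 2)
  expect_identical(t1, t2)
  d1 <- tempfile(); d2 <- tempfile()
  write_sumstats(t1[1], d1); write_sumstats(t2[1], d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted instruments have exactly proportional outcome effects", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0.1, 0.1),
                    c(1e5, 1e5), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 100)
  eff <- simulate_true_effects(tr, ld, 1, seed = 1)
  pl <- plant_instruments(eff, tr, ld, n_instruments = 10,
                          effect_size = 0.06, seed = 2,
                          exposure = "a", outcome = "b",
                          causal_effect = 0.5)
  reg <- pl$registry
  idx <- match(reg$snp, ld$snps$snp)
  expect_equal(unname(pl$effects[idx, "b"] / pl$effects[idx, "a"]),
               rep(0.5, 10))
  # null causal model: outcome effects exactly zero
  pl0 <- plant_instruments(eff, tr, ld, n_instruments = 10,
                           effect_size = 0.06, seed = 2,
                           exposure = "a", outcome = "b", causal_effect = 0)
  expect_true(all(pl0$effects[match(pl0$registry$snp, ld$snps$snp), "b"] == 0))
  # one instrument per block
  expect_equal(length(unique(reg$block)), 10L)
})

test_that("planting warns when the effect cannot reach genome-wide significance", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0.1, 0.1),
                    c(1e3, 1e3), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 100)
  eff <- simulate_true_effects(tr, ld, 1, seed = 1)
  expect_warning(plant_instruments(eff, tr, ld, 5, effect_size = 0.01,
                                   seed = 3, exposure = "a", outcome = "b"),
                 "minimum detectable")
})

test_that("written artifacts round-trip through the text formats", {
  tr <- truth10()
  ld <- ld_structure(n_snps_per_chr = 30)
  eff <- simulate_true_effects(tr, ld, 1, seed = 1)
  tabs <- simulate_sumstats(eff, tr, ld, seed = 2)
  d <- tempfile()
  write_sumstats(tabs, d)
  write_ld_scores(ld, d)
  write_ld_blocks(ld, d)
  write_truth(tr, d)
  rd <- read_sumstats(file.path(d, "mdd.sumstats.tsv"))
  # per-allele scaling preserves Z-scores exactly
  expect_equal(rd$z, tabs$mdd$BETA / tabs$mdd$SE, tolerance = 1e-6)
  blocks <- read_ld_blocks(file.path(d, "ldblocks.tsv"))
  expect_equal(blocks$BLOCK, ld$snps$block)
  ty <- yaml::read_yaml(file.path(d, "truth.yaml"))
  expect_equal(ty$trait_h2, tr$trait_h2)
})
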