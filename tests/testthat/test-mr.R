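test_that("clumping keeps the best SNP per LD-correlated pair", {
  exposure <- data.frame(
    snp = c("rs1", "rs2"), chr = c(1L, 1L), bp = c(1e6, 1e6 + 5000 * 1000),
    a1 = "A", a2 = "G", beta = c(0.1, 0.09), se = 0.005,
    p = c(1e-10, 1e-9), n = 1e5, stringsAsFactors = FALSE)
  ld_ref <- data.frame(SNP = c("rs1", "rs2"), CHR = 1L,
                       BP = c(1e6, 1e6 + 5e6), BLOCK = 1L, R2_WITHIN = 0.2)
  out <- select_instruments(exposure, ld_ref)
  expect_equal(out$snp, "rs1")
  # same pair on different chromosomes: both kept
  exposure2 <- exposure; exposure2$chr <- c(1L, 2L)
  ld_ref2 <- ld_ref; ld_ref2$CHR <- c(1L, 2L); ld_ref2$BLOCK <- c(1L, 2L)
  out2 <- select_instruments(exposure2, ld_ref2)
  expect_equal(sort(out2$snp), c("rs1", "rs2"))
  # r2 at or below the cap: both kept even within the window
  ld_ref3 <- ld_ref; ld_ref3$R2_WITHIN <- 0.001
  out3 <- select_instruments(exposure, ld_ref3)
  expect_equal(sort(out3$snp), c("rs1", "rs2"))
})

test_that("zero significant SNPs give an explicit empty set, not an error", {
  exposure <- data.frame(snp = "rs1", chr = 1L, bp = 1e6, a1 = "A", a2 = "G",
                         beta = 0.01, se = 0.01, p = 0.3, n = 1e5)
  out <- select_instruments(exposure, data.frame(SNP = "rs1", CHR = 1L,
                                                 BP = 1e6, BLOCK = 1L,
                                                 R2_WITHIN = 0.1))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "status"), "empty")
})

test_that("all planted instruments in distinct blocks survive clumping", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0.05, 0.05),
                    c(1e5, 1e5), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 500)
  eff <- simulate_true_effects(tr, ld, 1, seed = 51)
  pl <- plant_instruments(eff, tr, ld, n_instruments = 11,
                          effect_size = 0.06, seed = 52,
                          exposure = "a", outcome = "b", causal_effect = 0.5)
  tabs <- lapply(simulate_sumstats(pl$effects, tr, ld, seed = 53),
                 as_internal)
  sel <- select_instruments(tabs$a, ld_ref_table(ld))
  expect_true(all(pl$registry$snp %in% sel$snp))
})

test_that("harmonization flips swapped outcome alleles and logs absences", {
  iset <- make_iset(c(0.1, 0.2), c(0, 0))[, c("snp", "chr", "bp", "a1", "a2",
                                              "beta_exp", "se_exp", "p_exp",
                                              "n_exp")]
  class(iset) <- c("instrument_set", "data.frame")
  outcome <- data.frame(snp = c("s1", "s2", "s3"),
                        a1 = c("G", "A", "A"), a2 = c("A", "G", "G"),
                        beta = c(0.05, 0.07, 0.1), se = 0.01, p = 0.01,
                        n = 1e5, stringsAsFactors = FALSE)
  suppressMessages(h <- harmonize_io(iset, outcome))
  expect_equal(h$beta_out, c(-0.05, 0.07))
  # palindromic instruments are dropped
  iset$a1 <- c("A", "C"); iset$a2 <- c("T", "G")
  outcome$a1 <- c("A", "C", "A"); outcome$a2 <- c("T", "G", "G")
  expect_error(suppressMessages(harmonize_io(iset, outcome)), "fewer than 2")
})

test_that("IVW equals its closed form and flags exact proportionality", {
  iset <- make_iset(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                    se_out = c(0.01, 0.01, 0.02))
  res <- mr_ivw(iset)
  w <- 1 / iset$se_out^2
  closed <- sum(w * iset$beta_exp * iset$beta_out) /
    sum(w * iset$beta_exp^2)
  expect_equal(res$beta, closed, tolerance = 1e-12)
  expect_equal(res$beta, 0.5, tolerance = 1e-12)
  expect_lt(res$q, 1e-20)
  expect_equal(res$q_df, 2)
  # random-effects SE never undercuts fixed effects
  set.seed(7)
  iset2 <- make_iset(runif(10, 0.05, 0.3), rnorm(10, 0.1, 0.05))
  fe <- mr_ivw(iset2, random_effects = FALSE)
  re <- mr_ivw(iset2, random_effects = TRUE)
  expect_gte(re$se, fe$se)
})

test_that("the Wald ratio handles the single-instrument case", {
  r <- wald_ratio(0.5, 0.2, 0.01)
  expect_equal(r$beta, 0.4)
  expect_equal(r$n_snp, 1L)
})

test_that("Egger recovers slope and zero intercept under proportionality", {
  iset <- make_iset(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                    se_out = c(0.01, 0.01, 0.02))
  res <- mr_egger(iset)
  expect_equal(res$beta, 0.5, tolerance = 1e-10)
  expect_equal(res$egger_intercept, 0, tolerance = 1e-10)
  # vanishing exposure error drives I2_GX to 1
  expect_gt(res$i2_gx, 0.999)
})

test_that("estimators are invariant to ordering and allele-sign flips", {
  set.seed(11)
  bx <- runif(8, 0.05, 0.3)
  by <- 0.4 * bx + rnorm(8, 0, 0.01)
  iset <- make_iset(bx, by, se_exp = 0.005)
  perm <- sample(8)
  iset_perm <- iset[perm, ]
  class(iset_perm) <- c("instrument_set", "data.frame")
  flip <- iset
  flip$beta_exp[1:4] <- -flip$beta_exp[1:4]
  flip$beta_out[1:4] <- -flip$beta_out[1:4]
  # orientation convention: estimators internally use |beta_exp|
  flip$beta_out <- sign(flip$beta_exp) * flip$beta_out
  flip$beta_exp <- abs(flip$beta_exp)
  for (f in list(mr_ivw, mr_egger)) {
    expect_equal(f(iset)$beta, f(iset_perm)$beta, tolerance = 1e-12)
    expect_equal(f(iset)$beta, f(flip)$beta, tolerance = 1e-12)
  }
  expect_equal(mr_weighted_median(iset, 50, 1)$beta,
               mr_weighted_median(iset_perm, 50, 1)$beta, tolerance = 1e-12)
})

test_that("the weighted median resists a minority of invalid instruments", {
  iset <- make_iset(rep(1, 7), c(rep(0.5, 5), 5, 5), se_out = 0.1)
  expect_equal(mr_weighted_median(iset, 200, 1)$beta, 0.5, tolerance = 0.02)
  # odd symmetric ratio set
  iset2 <- make_iset(rep(1, 3), c(0.4, 0.5, 0.6), se_out = 0.1)
  expect_equal(mr_weighted_median(iset2, 200, 1)$beta, 0.5, tolerance = 1e-10)
})

test_that("the weighted mode finds the majority cluster", {
  iset <- make_iset(rep(1, 10), c(rep(0.5, 7), rep(2, 3)), se_out = 0.1)
  est <- mr_weighted_mode(iset, 1, 200, 1)
  expect_equal(est$beta, 0.5, tolerance = 0.05)
  # bandwidth to infinity approaches the weighted mean of ratios
  big <- mr_weighted_mode(iset, 1e6, 50, 1)
  rs <- iset$beta_out / iset$beta_exp
  v <- iset$se_out^2 / iset$beta_exp^2 +
    iset$beta_out^2 * iset$se_exp^2 / iset$beta_exp^4
  expect_equal(big$beta, sum(rs / v) / sum(1 / v), tolerance = 0.05)
})

test_that("RAPS collapses to IVW without measurement error", {
  set.seed(13)
  bx <- runif(10, 0.1, 0.3)
  by <- 0.5 * bx + rnorm(10, 0, 0.01)
  iset <- make_iset(bx, by, se_exp = 1e-9)
  ivw <- mr_ivw(iset)
  raps <- mr_raps(iset, overdispersion = FALSE)
  expect_equal(raps$beta, ivw$beta, tolerance = 1e-3)
})

test_that("RAPS is less biased than IVW with weak instruments", {
  # weak-instrument regime: exposure z around 3-5
  n_seeds <- 50
  bias_ivw <- bias_raps <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(1000 + s)
    n <- 20
    bx_true <- stats::rnorm(n, 0, 0.02)
    se_x <- rep(0.005, n)
    se_y <- rep(0.005, n)
    bx <- stats::rnorm(n, bx_true, se_x)
    by <- stats::rnorm(n, 0.5 * bx_true, se_y)
    iset <- make_iset(bx, by, se_exp = se_x, se_out = se_y)
    bias_ivw[s] <- mr_ivw(iset)$beta - 0.5
    bias_raps[s] <- mr_raps(iset, overdispersion = FALSE)$beta - 0.5
  }
  expect_lt(abs(mean(bias_raps)), abs(mean(bias_ivw)))
})

test_that("RAPS absorbs balanced pleiotropy in its overdispersion term", {
  set.seed(17)
  n <- 30
  bx <- runif(n, 0.1, 0.3)
  by <- 0.5 * bx + rnorm(n, 0, 0.05)  # pleiotropy beyond se_out = 0.01
  iset <- make_iset(bx, by, se_exp = 1e-6, se_out = 0.01)
  raps <- mr_raps(iset, overdispersion = TRUE)
  expect_gt(raps$overdispersion, 0.0005)
  expect_lt(abs(raps$beta - 0.5), 2 * raps$se + 0.05)
})

test_that("Cochran's Q is zero under proportionality and matches hand math", {
  iset <- make_iset(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20),
                    se_out = c(0.01, 0.01, 0.02))
  q <- cochran_q(iset, mr_ivw(iset)$beta)
  expect_lt(q$q, 1e-20)
  expect_equal(q$p, 1)
  # n = 2: Q equals the squared standardized difference of the ratios
  is2 <- make_iset(c(0.2, 0.2), c(0.08, 0.12), se_out = 0.01)
  q2 <- cochran_q(is2, mr_ivw(is2)$beta)
  expect_equal(q2$df, 1L)
  expect_equal(q2$q, 8, tolerance = 1e-10)
  # df <= 0 flagged
  q1 <- cochran_q(is2, 0.5, with_intercept = TRUE)
  expect_true(is.na(q1$p))
})

test_that("Cochran's Q detects planted heterogeneous outliers", {
  hits <- 0
  for (s in 1:50) {
    set.seed(2000 + s)
    n <- 12
    bx <- runif(n, 0.1, 0.3)
    by <- 0.5 * bx + rnorm(n, 0, 0.01)
    by[1:3] <- by[1:3] + c(0.15, -0.12, 0.18)   # invalid instruments
    iset <- make_iset(bx, by, se_out = 0.01)
    q <- cochran_q(iset, mr_ivw(iset)$beta)
    hits <- hits + (q$p < 0.05)
  }
  expect_gte(hits / 50, 0.9)
})

test_that("Steiger filtering drops reverse-causal instruments", {
  # exposure r2 larger: kept
  iset <- make_iset(0.1 * c(1, 1), c(0.01, 0.1), se_exp = 0.01,
                    se_out = 0.01)
  out <- steiger_filter(iset)
  expect_true(out$steiger_keep[1])
  expect_false(out$steiger_keep[2])  # equal r2 dropped (strict >)
  # reverse-causal SNPs planted at N = 1e5: dropped in >= 95% of seeds
  dropped <- 0
  for (s in 1:50) {
    set.seed(3000 + s)
    e <- 0.06                      # SNP acts on the outcome first
    bx <- stats::rnorm(1, 0.3 * e, 1 / sqrt(1e5))
    by <- stats::rnorm(1, e, 1 / sqrt(1e5))
    iset <- make_iset(c(bx, 0.2), c(by, 0.1), se_exp = 1 / sqrt(1e5),
                      se_out = 1 / sqrt(1e5))
    out <- steiger_filter(iset)
    dropped <- dropped + !out$steiger_keep[1]
  }
  expect_gte(dropped / 50, 0.95)
})

test_that("relaxing the p-value threshold never loses instruments", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0.05, 0.05),
                    c(1e5, 1e5), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 500)
  eff <- simulate_true_effects(tr, ld, 1, seed = 61)
  pl <- plant_instruments(eff, tr, ld, n_instruments = 8,
                          effect_size = 0.04, seed = 62,
                          exposure = "a", outcome = "b", causal_effect = 0.3)
  tabs <- lapply(simulate_sumstats(pl$effects, tr, ld, seed = 63),
                 as_internal)
  strict <- select_instruments(tabs$a, ld_ref_table(ld), p_threshold = 5e-8)
  relaxed <- select_instruments(tabs$a, ld_ref_table(ld), p_threshold = 5e-7)
  expect_gte(nrow(relaxed), nrow(strict))
  expect_true(all(strict$snp %in% relaxed$snp))
})

test_that("bidirectional MR recovers planted asymmetric causal effects", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0.05, 0.05),
                    c(1e5, 1e5), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 1000)
  eff <- simulate_true_effects(tr, ld, 1, seed = 71)
  fwd <- plant_instruments(eff, tr, ld, n_instruments = 11,
                           effect_size = 0.05, seed = 72,
                           exposure = "a", outcome = "b", causal_effect = 0.5)
  rev <- plant_instruments(fwd$effects, tr, ld, n_instruments = 11,
                           effect_size = 0.05, seed = 73,
                           exposure = "b", outcome = "a", causal_effect = 0,
                           exclude_blocks = fwd$registry$block)
  tabs <- lapply(simulate_sumstats(rev$effects, tr, ld, seed = 74),
                 as_internal)
  res <- suppressWarnings(
    bidirectional_mr(tabs$a, tabs$b, ld_ref_table(ld), seed = 1,
                     n_boot = 100, name_a = "a", name_b = "b"))
  ivw_ab <- res$forward$methods$ivw
  ivw_ba <- res$reverse$methods$ivw
  expect_lt(abs(ivw_ab$beta - 0.5), 2 * ivw_ab$se)
  expect_lt(abs(ivw_ba$beta - 0), 2.5 * ivw_ba$se + 0.02)
  expect_true(all(c("IVW", "Egger", "WeightedMedian", "WeightedMode",
                    "RAPS") %in% res$table$method))
})

test_that("a direction without instruments reports itself not estimable", {
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0.0, 0.05),
                    c(1e3, 1e5), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 300)
  eff <- simulate_true_effects(tr, ld, 1, seed = 81)
  pl <- plant_instruments(eff, tr, ld, n_instruments = 10,
                          effect_size = 0.08, seed = 82,
                          exposure = "b", outcome = "a", causal_effect = 0)
  tabs <- lapply(simulate_sumstats(pl$effects, tr, ld, seed = 83),
                 as_internal)
  res <- suppressWarnings(
    bidirectional_mr(tabs$a, tabs$b, ld_ref_table(ld), seed = 1,
                     n_boot = 50, name_a = "a", name_b = "b"))
  expect_match(res$forward$status, "not estimable")
  expect_equal(res$reverse$status, "ok")
})

test_that("planted directional pleiotropy is recovered by the Egger intercept", {
  # null polygenic background so the planted SNPs are the only candidates
  tr <- truth_model(matrix(0, 2, 1), matrix(1, 1, 1), c(0, 0),
                    c(1e5, 1e5), trait_names = c("a", "b"))
  ld <- ld_structure(n_snps_per_chr = 1000)
  eff <- simulate_true_effects(tr, ld, 1, seed = 91)
  pl <- plant_instruments(eff, tr, ld, n_instruments = 10,
                          effect_size = seq(0.04, 0.12, length.out = 10),
                          seed = 92, exposure = "a", outcome = "b",
                          causal_effect = 0.5, pleiotropy_shift = 0.05)
  expect_true(all(!pl$registry$valid))
  tabs <- lapply(simulate_sumstats(pl$effects, tr, ld, seed = 93),
                 as_internal)
  sel <- select_instruments(tabs$a, ld_ref_table(ld))
  iset <- harmonize_io(sel, tabs$b)
  eg <- mr_egger(iset)
  expect_lt(abs(eg$egger_intercept - 0.05), 2 * eg$intercept_se)
  expect_lt(abs(eg$beta - 0.5), 2.5 * eg$se)
})
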