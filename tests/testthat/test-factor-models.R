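test_that("PD smoothing is the identity on PD matrices and fixes indefinite ones", {
  S <- diag(3)
  expect_equal(attr(smooth_to_pd(S), "max_change"), 0)
  S2 <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  out <- smooth_to_pd(S2)
  expect_lt(out[1, 2], 1)
  expect_gte(min(eigen(out, only.values = TRUE)$values), 0)
  set.seed(5)
  A <- matrix(rnorm(100), 10, 10); A <- (A + t(A)) / 2
  out3 <- smooth_to_pd(A)
  expect_gte(min(eigen(out3, only.values = TRUE)$values), 1e-6 * 0.9)
})

test_that("Kaiser's criterion counts eigenvalues strictly above one", {
  expect_equal(pca_scree(diag(10))$n_retained, 0L)
  ev <- c(2.1, 1.3, 1.05, 0.4, 0.35, 0.3, 0.25, 0.25)
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  S <- Q %*% diag(ev) %*% t(Q)
  d <- sqrt(diag(S)); S <- S / outer(d, d)  # correlation scale
  sc <- pca_scree(S)
  expect_equal(sc$n_retained, sum(sc$eigenvalues > 1))
  expect_equal(length(sc$eigenvalues), 8L)
})

test_that("PCA on the generator's 3-cluster truth retains three components", {
  fx <- fx_factor10()
  expect_equal(pca_scree(fx$gc_odd)$n_retained, 3L)
  expect_warning(pca_scree(fx$gc_even), "odd-chromosome")
})

test_that("EFA recovers a one-factor structure with loadings 0.7", {
  L <- matrix(0.7, 6, 1)
  R <- L %*% t(L); diag(R) <- 1
  ef <- efa_fit(fake_gc(R), 1)
  expect_equal(unname(ef$loadings[, 1]), rep(0.7, 6), tolerance = 0.05)
})

test_that("EFA keeps cross-loadings small for orthogonal blocks", {
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- 0.8; L[4:6, 2] <- 0.8
  R <- L %*% t(L); diag(R) <- 1
  ef <- efa_fit(fake_gc(R), 2)
  cross <- pmin(abs(ef$loadings[, 1]), abs(ef$loadings[, 2]))
  expect_lt(max(cross), 0.1)
})

test_that("oblique EFA recovers correlated factors from the truth matrix", {
  tr <- truth10()
  R <- stats::cov2cor(implied_gcov(tr))
  ef <- efa_fit(fake_gc(R), 3)
  # factor correlations (up to permutation) near the generating 0.35-0.5
  phis <- sort(abs(ef$factor_corr[lower.tri(ef$factor_corr)]))
  expect_equal(phis, sort(c(0.45, 0.50, 0.35)), tolerance = 0.15)
  expect_gt(ef$total_var_explained, 0.4)
})

test_that("EFA rejects a saturated factor count", {
  expect_error(efa_fit(fake_gc(diag(4)), 4), "smaller")
})

test_that("model parser builds identified templates and catches errors", {
  spec <- parse_model(cfa3_syntax, truth10()$trait_names)
  expect_equal(length(spec$latents), 3L)
  expect_equal(spec$df, 32)
  expect_error(parse_model("F1 =~ nosuch + mdd", truth10()$trait_names),
               "nosuch")
  # more free parameters than moments
  expect_error(parse_model("F1 =~ a + b\nF2 =~ a + b\nF1 ~~ F2",
                           c("a", "b")), "not identified")
})

test_that("a just-identified model reproduces S exactly", {
  fx <- fx_factor10()
  fit <- cfa_fit(fx$gc_even, "F1 =~ mdd + anx + ptsd")
  expect_equal(fit$df, 0)
  expect_identical(fit$chi2, 0)
  expect_lt(fit$srmr, 1e-6)
  expect_equal(fit$cfi, 1)
  expect_lt(max(abs(fit$implied - fit$S)), 1e-8)
})

test_that("CFA on the generator truth recovers covariance-scale loadings", {
  fx <- fx_factor10()
  fit <- cfa_fit(fx$gc_even, cfa3_syntax)
  expect_true(fit$converged)
  est <- fit$params$est[fit$params$mat == "lam"]
  expect_lt(stats::median(abs(est - truth10_lambda())), 0.05)
  # factor correlations recovered
  phi <- fit$params$est[fit$params$type == "factor_cov"]
  expect_equal(sort(phi), sort(c(0.45, 0.50, 0.35)), tolerance = 0.2)
})

test_that("fixing a loading away from its optimum cannot improve fit", {
  fx <- fx_factor10()
  free_fit <- cfa_fit(fx$gc_even, cfa3_syntax)
  fixed_syntax <- sub("F3 =~ scz", "F3 =~ 0.4*scz", cfa3_syntax, fixed = TRUE)
  fixed_fit <- cfa_fit(fx$gc_even, fixed_syntax)
  expect_gte(fixed_fit$objective, free_fit$objective - 1e-10)
  expect_gte(fixed_fit$chi2, free_fit$chi2 - 1e-6)
})

test_that("an identity covariance yields near-zero loadings", {
  gc <- fake_gc(diag(6))
  fit <- cfa_fit(gc, paste("F1 =~", paste(gc$traits[1:4], collapse = " + ")))
  expect_lt(max(abs(fit$params$est[fit$params$mat == "lam"])), 0.05)
})

test_that("fit indices hit their definitional anchors", {
  fx <- fx_factor10()
  sat <- cfa_fit(fx$gc_even, "F1 =~ mdd + anx + ptsd")
  fi <- fit_indices(sat, fx$gc_even)
  expect_identical(fi$chi2, 0)
  expect_lt(fi$srmr, 1e-6)
  expect_equal(fi$cfi, 1)
  # a model implying zero covariances IS the baseline: CFI = 0
  null_fit <- cfa_fit(fx$gc_even, "F1 =~ 0*mdd + 0*anx + 0*ptsd + 0*adhd")
  fi0 <- fit_indices(null_fit, fx$gc_even)
  expect_equal(fi0$cfi, 0, tolerance = 1e-6)
})

test_that("misspecified one-factor fits have worse SRMR than the true pattern", {
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- 0.8; L[4:6, 2] <- 0.8
  R <- L %*% t(L); diag(R) <- 1
  gc <- fake_gc(R)
  good <- cfa_fit(gc, paste0("F1 =~ t1 + t2 + t3\nF2 =~ t4 + t5 + t6"))
  bad <- cfa_fit(gc, paste0("F1 =~ t1 + t2 + t3 + t4 + t5 + t6"))
  expect_gt(bad$srmr, good$srmr)
})

test_that("correlation-scale fits give matching raw and standardized loadings", {
  L <- matrix(c(0.8, 0.7, 0.6, 0.5), 4, 1)
  R <- L %*% t(L); diag(R) <- 1
  fit <- cfa_fit(fake_gc(R), "F1 =~ t1 + t2 + t3 + t4")
  lam_rows <- fit$params$mat == "lam"
  expect_equal(fit$std_params$est[lam_rows], fit$params$est[lam_rows],
               tolerance = 1e-3)
  expect_equal(sort(fit$params$est[lam_rows]), sort(c(0.5, 0.6, 0.7, 0.8)),
               tolerance = 1e-6)
  # standardized residual variances equal 1 - communality
  th_rows <- fit$params$type == "residual"
  expect_equal(sort(fit$std_params$est[th_rows]),
               sort(1 - c(0.5, 0.6, 0.7, 0.8)^2), tolerance = 1e-6)
})

test_that("the three loneliness structural models behave as specified", {
  # population matrix: 10 indicators + single-indicator loneliness latent
  tr <- truth10()
  lone_load <- 0.66
  R10 <- tr$loadings %*% tr$factor_corr %*% t(tr$loadings)
  diag(R10) <- 1
  lone_row <- as.numeric(tr$loadings %*% tr$factor_corr[, 1]) * lone_load
  R <- rbind(cbind(R10, lone_row), c(lone_row, 1))
  traits <- c(tr$trait_names, "lone")
  dimnames(R) <- list(traits, traits)
  gc <- fake_gc(R)
  fits <- loneliness_models(gc, list(NMD = traits[1:5], SUT = traits[6:8],
                                     DPF = traits[9:10]), "lone")
  # constrained model recovers the single true path
  bc <- fits$constrained$params
  expect_equal(bc$est[bc$label == "LONE~NMD"], lone_load, tolerance = 0.02)
  # adjusted model: nuisance paths near zero on population input
  ba <- fits$adjusted$params
  expect_lt(abs(ba$est[ba$label == "LONE~SUT"]), 0.05)
  expect_lt(abs(ba$est[ba$label == "LONE~DPF"]), 0.05)
  # unadjusted bivariate betas equal the marginal factor correlations
  b1 <- fits$unadjusted$NMD$params
  expect_equal(b1$est[b1$label == "LONE~NMD"], lone_load, tolerance = 0.02)
  b2 <- fits$unadjusted$SUT$params
  expect_equal(b2$est[b2$label == "LONE~SUT"],
               lone_load * tr$factor_corr[1, 2], tolerance = 0.03)
})
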