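# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fx_cache)) assign(name, build(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# raw simulated table (upper-case writer columns) -> internal sumstats
as_internal <- function(tab) {
  out <- data.frame(snp = tab$SNP, chr = tab$CHR, bp = tab$BP,
                    a1 = tab$A1, a2 = tab$A2, beta = tab$BETA, se = tab$SE,
                    p = tab$P, n = tab$N, info = tab$INFO, frq = tab$FRQ,
                    stringsAsFactors = FALSE)
  out$z <- out$beta / out$se
  class(out) <- c("sumstats", "data.frame")
  out
}

ld_scores_of <- function(ld) data.frame(SNP = ld$snps$snp, L2 = ld$snps$l2)

# 10-trait, 3-cluster architecture used by the factor-recovery tests
truth10 <- function(n = 50000) {
  traits <- c("mdd", "anx", "ptsd", "adhd", "asd", "alc", "can", "smk",
              "scz", "bip")
  L <- matrix(0, 10, 3, dimnames = list(traits, NULL))
  L[1:5, 1] <- c(0.8, 0.75, 0.70, 0.60, 0.50)
  L[6:8, 2] <- c(0.60, 0.70, 0.75)
  L[9:10, 3] <- c(0.85, 0.80)
  Phi <- matrix(c(1, 0.45, 0.50, 0.45, 1, 0.35, 0.50, 0.35, 1), 3, 3)
  h2 <- c(0.089, 0.079, 0.050, 0.236, 0.118, 0.050, 0.070, 0.090,
          0.412, 0.170)
  truth_model(L, Phi, h2, rep(n, 10), trait_names = traits)
}

# covariance-scale loadings implied by truth10 (the CFA recovery oracle)
truth10_lambda <- function(tr = truth10()) {
  lam <- numeric(10)
  for (i in 1:10) {
    f <- which(tr$loadings[i, ] != 0)
    lam[i] <- tr$loadings[i, f] * sqrt(tr$trait_h2[i])
  }
  lam
}

cfa3_syntax <- paste(
  "F1 =~ mdd + anx + ptsd + adhd + asd",
  "F2 =~ alc + can + smk",
  "F3 =~ scz + bip", sep = "\n")

# medium genome: ~50k SNPs over 22 chromosomes
ld50k <- function() fixture("ld50k", function()
  ld_structure(n_snps_per_chr = 2273, block_size = 50, within_r2 = 0.1))

# one realized 10-trait dataset at M ~ 50k, N = 50k with its S/V matrices
fx_factor10 <- function() fixture("fx_factor10", function() {
  tr <- truth10()
  ld <- ld50k()
  eff <- simulate_true_effects(tr, ld, 1, seed = 101)
  tabs <- lapply(simulate_sumstats(eff, tr, ld, seed = 102), as_internal)
  lsc <- ld_scores_of(ld)
  lb <- ld_ref_table(ld)
  list(truth = tr, ld = ld, tabs = tabs,
       gc_all = build_S_V(tabs, lsc, subset = "all", n_blocks = 200,
                          ld_blocks = lb),
       gc_odd = build_S_V(tabs, lsc, subset = "odd_chr", n_blocks = 200,
                          ld_blocks = lb),
       gc_even = build_S_V(tabs, lsc, subset = "even_chr", n_blocks = 200,
                           ld_blocks = lb))
})

# synthetic genetic_covariance wrapper for analytic (population) matrices
fake_gc <- function(S, v_diag = 1e-4, traits = NULL) {
  k <- ncol(S)
  if (is.null(traits)) traits <- colnames(S)
  if (is.null(traits)) traits <- paste0("t", seq_len(k))
  dimnames(S) <- list(traits, traits)
  pairs <- gsemr:::.vech_pairs(k)
  np <- nrow(pairs)
  V <- diag(rep(v_diag, np))
  structure(list(traits = traits, S = S, V = V,
                 intercepts = diag(k), n_blocks = 2, subset = "all",
                 delete = matrix(0, 2, np), M = 1000, vech_pairs = pairs),
            class = "genetic_covariance")
}

# quick two-trait instrument set for estimator tests
make_iset <- function(beta_exp, beta_out, se_exp = 1e-8, se_out = 0.01,
                      n_exp = 1e5, n_out = 1e5) {
  n <- length(beta_exp)
  out <- data.frame(snp = paste0("s", seq_len(n)), chr = 1L,
                    bp = seq_len(n) * 1e6, a1 = "A", a2 = "G",
                    beta_exp = beta_exp, se_exp = rep_len(se_exp, n),
                    p_exp = 1e-10, n_exp = rep_len(n_exp, n),
                    beta_out = beta_out, se_out = rep_len(se_out, n),
                    p_out = 0.01, n_out = rep_len(n_out, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("instrument_set", "data.frame")
  out
}

# common-pathway architecture: 5 indicators, all genetic signal through
# one factor, the calibration regime for Q_SNP
fx_common <- function() fixture("fx_common", function() {
  traits <- paste0("t", 1:5)
  tr <- truth_model(matrix(1, 5, 1, dimnames = list(traits, NULL)),
                    matrix(1, 1, 1), rep(0.05, 5), rep(1e5, 5),
                    trait_names = traits)
  ld <- ld50k()
  eff <- simulate_true_effects(tr, ld, 1, seed = 201)
  # one heterogeneous SNP (acts on a single indicator) in a cleared block
  het_block <- max(ld$snps$block)
  het_snp <- which(ld$snps$block == het_block)[1]
  eff[ld$snps$block == het_block, ] <- 0
  eff[het_snp, ] <- c(0.05, 0, 0, 0, 0)
  pl <- plant_instruments(eff, tr, ld, n_instruments = 10,
                          effect_size = 0.05, seed = 202,
                          exposure = list(factor = 1), outcome = "t1",
                          causal_effect = 0,
                          exclude_blocks = het_block)
  tabs <- lapply(simulate_sumstats(pl$effects, tr, ld, seed = 203),
                 as_internal)
  gc <- build_S_V(tabs, ld_scores_of(ld), subset = "even_chr",
                  n_blocks = 200, ld_blocks = ld_ref_table(ld))
  lg <- latent_gwas(tabs, gc, traits, "F")
  list(truth = tr, ld = ld, tabs = tabs, gc = gc, lg = lg,
       het_snp = ld$snps$snp[het_snp], het_block = het_block,
       registry = pl$registry)
})

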