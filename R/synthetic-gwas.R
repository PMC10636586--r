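#' Define the ground-truth latent genetic architecture for simulation
#'
#' A truth model describes how a set of traits share genetic signal through
#' latent factors: standardized loadings on the genetic-correlation scale,
#' factor intercorrelations, per-trait SNP heritabilities, sample sizes, and
#' the sample-overlap structure that induces correlated estimation error
#' (the source of nonzero cross-trait LDSC intercepts).
#'
#' Loadings are on the genetic correlation scale, so the implied genetic
#' correlation matrix is \eqn{\Lambda \Phi \Lambda' + \Psi} with
#' \eqn{\Psi = diag(1 - communality)}, and the implied genetic covariance is
#' that matrix rescaled by \eqn{\sqrt{h^2_i h^2_j}}; its diagonal equals
#' `trait_h2` by construction.
#'
#' @param loadings trait x factor matrix of standardized loadings; row names
#'   are trait names.
#' @param factor_corr factor x factor correlation matrix (symmetric, unit
#'   diagonal, positive definite).
#' @param trait_h2 per-trait SNP heritability in `[0, 1]`.
#' @param sample_sizes per-trait GWAS sample size (effective N for binary
#'   traits).
#' @param overlap_frac trait x trait matrix of pairwise sample-overlap
#'   fractions in `[0, 1]` (unit diagonal). Default: no overlap.
#' @param phenotypic_corr_overlap trait x trait phenotypic correlation used
#'   together with `overlap_frac` to set the correlation of estimation
#'   errors across traits. Default: zero off-diagonal.
#' @param causal_effect scalar structural effect from a designated exposure
#'   to an outcome, used by [plant_instruments()] defaults.
#' @param trait_names optional trait labels (otherwise taken from
#'   `rownames(loadings)` or auto-generated).
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(loadings, factor_corr, trait_h2, sample_sizes,
                        overlap_frac = NULL, phenotypic_corr_overlap = NULL,
                        causal_effect = 0, trait_names = NULL) {
  loadings <- as.matrix(loadings)
  k <- nrow(loadings)
  if (is.null(trait_names)) {
    trait_names <- rownames(loadings)
    if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(k))
  }
  rownames(loadings) <- trait_names
  factor_corr <- as.matrix(factor_corr)
  if (!isSymmetric(unname(factor_corr), tol = 1e-8))
    stop("factor_corr must be symmetric")
  if (any(abs(diag(factor_corr) - 1) > 1e-8))
    stop("factor_corr must have unit diagonal")
  if (min(eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor_corr must be positive definite")
  if (length(trait_h2) != k || any(trait_h2 < 0 | trait_h2 > 1))
    stop("trait_h2 must be length ", k, " within [0, 1]")
  if (length(sample_sizes) != k || any(sample_sizes <= 0))
    stop("sample_sizes must be positive, one per trait")
  communality <- diag(loadings %*% factor_corr %*% t(loadings))
  if (any(communality > 1 + 1e-8))
    stop("communality exceeds 1 for trait(s): ",
         paste(trait_names[communality > 1 + 1e-8], collapse = ", "))
  if (is.null(overlap_frac)) overlap_frac <- diag(k)
  if (is.null(phenotypic_corr_overlap)) phenotypic_corr_overlap <- diag(k)
  overlap_frac <- as.matrix(overlap_frac)
  phenotypic_corr_overlap <- as.matrix(phenotypic_corr_overlap)
  if (!isSymmetric(unname(overlap_frac), tol = 1e-8) ||
      any(abs(diag(overlap_frac) - 1) > 1e-8))
    stop("overlap_frac must be symmetric with unit diagonal")
  if (any(overlap_frac < 0 | overlap_frac > 1))
    stop("overlap_frac entries must lie in [0, 1]")
  structure(list(
    n_traits = k,
    n_factors = ncol(loadings),
    trait_names = trait_names,
    loadings = loadings,
    factor_corr = factor_corr,
    residual_var = trait_h2 * pmax(1 - communality, 0),
    trait_h2 = as.numeric(trait_h2),
    sample_sizes = as.numeric(sample_sizes),
    overlap_frac = overlap_frac,
    phenotypic_corr_overlap = phenotypic_corr_overlap,
    causal_effect = causal_effect
  ), class = "truth_model")
}

#' @export
print.truth_model <- function(x, ...) {
  cat("Truth model:", x$n_traits, "traits,", x$n_factors, "latent factors\n")
  cat("  h2 range:", paste(range(x$trait_h2), collapse = " - "), "\n")
  cat("  N range:", paste(format(range(x$sample_sizes), big.mark = ","),
                          collapse = " - "), "\n")
  invisible(x)
}

#' Implied genetic covariance matrix of a truth model
#'
#' \eqn{G = D^{1/2} (\Lambda \Phi \Lambda' + \Psi) D^{1/2}} with
#' \eqn{D = diag(h^2)}. The diagonal equals `trait_h2` exactly.
#'
#' @param truth a [truth_model()].
#' @return trait x trait genetic covariance matrix.
#' @export
implied_gcov <- function(truth) {
  R <- truth$loadings %*% truth$factor_corr %*% t(truth$loadings)
  diag(R) <- 1  # residual tops communality up to unit genetic correlation
  d <- sqrt(truth$trait_h2)
  G <- outer(d, d) * R
  dimnames(G) <- list(truth$trait_names, truth$trait_names)
  G
}

#' Block-diagonal LD structure over 22 autosomes
#'
#' Builds an exchangeable-within-block LD reference: SNPs are grouped into
#' contiguous blocks, every pair within a block shares squared correlation
#' `within_r2`, and between-block r2 is exactly zero. Blocks never span a
#' chromosome boundary. The LD score of a SNP in a block of size `m` is
#' `1 + (m - 1) * within_r2` in closed form; block sizes cycle
#' deterministically over `block_size * size_profile` so that LD scores
#' vary across the genome (LD score regression needs regressor variation).
#'
#' @param n_snps_per_chr SNPs per chromosome (scalar or length 22).
#' @param block_size mean SNPs per LD block.
#' @param within_r2 pairwise r2 within a block, in `[0, 1)`.
#' @param spacing_bp base pairs between adjacent SNPs.
#' @param size_profile multipliers cycled to produce the block-size
#'   sequence (mean 1 keeps `block_size` the average).
#' @return An object of class `ld_structure`: data frame of per-SNP
#'   annotation (`snp`, `chr`, `bp`, `block`, `l2`) plus block metadata.
#' @export
ld_structure <- function(n_snps_per_chr = 1000, block_size = 50,
                         within_r2 = 0.1, spacing_bp = 10000,
                         size_profile = c(0.2, 0.6, 1, 1.4, 1.8)) {
  if (within_r2 < 0 || within_r2 >= 1) stop("within_r2 must lie in [0, 1)")
  n_chr <- 22L
  if (length(n_snps_per_chr) == 1) n_snps_per_chr <- rep(n_snps_per_chr, n_chr)
  sizes_cycle <- pmax(2L, as.integer(round(block_size * size_profile)))
  chr <- integer(0); block <- integer(0)
  next_block <- 1L
  for (cc in seq_len(n_chr)) {
    n <- n_snps_per_chr[cc]
    got <- 0L
    prof_i <- 1L
    while (got < n) {
      take <- min(sizes_cycle[prof_i], n - got)
      chr <- c(chr, rep(cc, take))
      block <- c(block, rep(next_block, take))
      next_block <- next_block + 1L
      got <- got + take
      prof_i <- prof_i %% length(sizes_cycle) + 1L
    }
  }
  idx_in_chr <- unlist(lapply(n_snps_per_chr, seq_len), use.names = FALSE)
  bp <- idx_in_chr * spacing_bp
  n_snps <- length(chr)
  snp <- paste0("rs", seq_len(n_snps))
  bsizes <- tabulate(block)
  l2 <- 1 + (bsizes[block] - 1) * within_r2
  structure(list(
    snps = data.frame(snp = snp, chr = chr, bp = bp, block = block, l2 = l2,
                      stringsAsFactors = FALSE),
    n_snps = n_snps,
    block_sizes = bsizes,
    within_r2 = within_r2,
    within_r = sqrt(within_r2)
  ), class = "ld_structure")
}

#' @export
print.ld_structure <- function(x, ...) {
  cat("LD structure:", x$n_snps, "SNPs on 22 chromosomes,",
      length(x$block_sizes), "blocks, within-block r2 =", x$within_r2, "\n")
  invisible(x)
}

#' Draw per-SNP true genetic effects from a truth model
#'
#' A random `polygenicity` fraction of SNPs is causal; each causal SNP's
#' standardized effect vector across traits is drawn from
#' \eqn{N(0, G / m_c)} where `G` is the implied genetic covariance and
#' `m_c` the number of causal SNPs, so summed across SNPs the effects
#' reproduce `G` in expectation.
#'
#' @param truth a [truth_model()].
#' @param ld an [ld_structure()].
#' @param polygenicity fraction of SNPs that are causal, in `(0, 1]`.
#' @param seed integer seed (mandatory; identical seed gives identical
#'   output).
#' @return SNP x trait matrix of true standardized effects, with a logical
#'   attribute `causal` marking causal SNPs.
#' @export
simulate_true_effects <- function(truth, ld, polygenicity = 1, seed) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (polygenicity <= 0 || polygenicity > 1)
    stop("polygenicity must lie in (0, 1]")
  G <- implied_gcov(truth)
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("implied genetic covariance is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(ev$values)), ")")
  lam <- pmax(ev$values, 0)
  M <- ld$n_snps
  k <- truth$n_traits
  set.seed(as.integer(seed))
  m_c <- max(1L, round(polygenicity * M))
  causal <- rep(FALSE, M)
  causal[sample.int(M, m_c)] <- TRUE
  beta <- matrix(0, M, k, dimnames = list(ld$snps$snp, truth$trait_names))
  # G^{1/2} via eigen so zero-heritability traits get exactly zero effects
  root <- ev$vectors %*% (sqrt(lam / m_c) * t(ev$vectors))
  beta[causal, ] <- matrix(stats::rnorm(m_c * k), m_c, k) %*% root
  beta[, truth$trait_h2 == 0] <- 0
  attr(beta, "causal") <- causal
  beta
}

#' LD-smooth true effects into expected marginal GWAS effects
#'
#' Marginal (single-SNP regression) effects are LD-weighted sums of causal
#' effects; with exchangeable within-block correlation r this is
#' \eqn{(1 - r)\beta_j + r T_b} where `T_b` is the block total.
#'
#' @param beta SNP x trait matrix of true effects.
#' @param ld an [ld_structure()].
#' @return SNP x trait matrix of LD-smoothed marginal effects.
#' @export
ld_smooth_effects <- function(beta, ld) {
  r <- ld$within_r
  if (r == 0) return(beta)
  tot <- rowsum(beta, ld$snps$block, reorder = TRUE)
  (1 - r) * beta + r * tot[ld$snps$block, , drop = FALSE]
}

#' Simulate GWAS summary statistics from true effects
#'
#' Estimated standardized effects are LD-smoothed true effects plus
#' estimation noise with standard error \eqn{1/\sqrt{N}}. The noise is
#' correlated across traits with correlation
#' `overlap_frac * phenotypic_corr_overlap`, which induces the cross-trait
#' LDSC intercept \eqn{\rho N_s / \sqrt{N_1 N_2}} expected under sample
#' overlap. INFO and allele-frequency columns are populated, with small
#' deliberate fractions below the standard QC thresholds so that filters
#' can be exercised.
#'
#' @param true_effects SNP x trait matrix from [simulate_true_effects()].
#' @param truth the [truth_model()] that produced it.
#' @param ld the [ld_structure()].
#' @param seed integer seed (mandatory).
#' @param info_low_frac fraction of rows given INFO below 0.9.
#' @param maf_low_frac fraction of rows given minor allele frequency below
#'   0.01.
#' @return Named list of per-trait summary-statistics data frames with
#'   columns `SNP, CHR, BP, A1, A2, BETA, SE, P, N, INFO, FRQ` (BETA/SE in
#'   standardized per-SD units; see [write_sumstats()] for per-allele
#'   scaling).
#' @export
simulate_sumstats <- function(true_effects, truth, ld, seed,
                              info_low_frac = 0.01, maf_low_frac = 0.01) {
  if (missing(seed)) stop("seed is required for reproducibility")
  set.seed(as.integer(seed))
  M <- ld$n_snps
  k <- truth$n_traits
  stopifnot(nrow(true_effects) == M, ncol(true_effects) == k)
  smooth <- ld_smooth_effects(true_effects, ld)
  C <- truth$overlap_frac * truth$phenotypic_corr_overlap
  diag(C) <- 1
  noise <- MASS::mvrnorm(M, mu = rep(0, k), Sigma = C)
  if (k == 1) noise <- matrix(noise, ncol = 1)
  N <- truth$sample_sizes
  # shared annotation so all traits harmonize on identical variants
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(pairs), M, replace = TRUE)
  a1 <- pairs[pick, 1]; a2 <- pairs[pick, 2]
  frq <- stats::runif(M, 0.05, 0.95)
  n_maf_low <- round(maf_low_frac * M)
  if (n_maf_low > 0) {
    idx <- sample.int(M, n_maf_low)
    frq[idx] <- stats::runif(n_maf_low, 0.0005, 0.0095)
  }
  info <- stats::runif(M, 0.92, 1)
  n_info_low <- round(info_low_frac * M)
  if (n_info_low > 0) {
    idx <- sample.int(M, n_info_low)
    info[idx] <- stats::runif(n_info_low, 0.5, 0.89)
  }
  out <- vector("list", k)
  names(out) <- truth$trait_names
  for (i in seq_len(k)) {
    se <- 1 / sqrt(N[i])
    bhat <- smooth[, i] + noise[, i] * se
    z <- bhat / se
    out[[i]] <- data.frame(
      SNP = ld$snps$snp, CHR = ld$snps$chr, BP = ld$snps$bp,
      A1 = a1, A2 = a2,
      BETA = bhat, SE = se, P = 2 * stats::pnorm(-abs(z)),
      N = N[i], INFO = info, FRQ = frq,
      stringsAsFactors = FALSE
    )
  }
  out
}

#' Plant genome-wide-significant instruments for MR recovery tests
#'
#' Overwrites the true effects of one designated SNP in each of
#' `n_instruments` distinct LD blocks: the exposure receives a large direct
#' effect, and the outcome receives `causal_effect * effect + pleiotropy`.
#' Exposure and outcome may each be a trait (by name) or a latent factor
#' (`factor = j`), in which case effects propagate through the factor
#' loadings, so a latent-factor GWAS sees a factor-level signal.
#'
#' @param true_effects SNP x trait matrix to modify.
#' @param truth the [truth_model()].
#' @param ld the [ld_structure()].
#' @param n_instruments number of instruments (at most the number of LD
#'   blocks).
#' @param effect_size standardized exposure effect, scalar or one value
#'   per instrument (varying effects keep the Egger regression
#'   identified).
#' @param seed integer seed for block selection.
#' @param exposure trait name, or `list(factor = j)` for latent factor j.
#' @param outcome trait name, or `list(factor = j)`.
#' @param causal_effect structural exposure-to-outcome effect (default from
#'   `truth$causal_effect`).
#' @param pleiotropy_shift scalar or per-instrument direct effect on the
#'   outcome, bypassing the exposure (0 = valid instrument).
#' @param exclude_blocks LD blocks not to plant in (e.g. blocks already
#'   carrying instruments for the other direction).
#' @return List with `effects` (modified matrix) and `registry` (data frame:
#'   `snp`, `block`, `exposure_effect`, `outcome_effect`, `pleiotropy`,
#'   `valid`).
#' @export
plant_instruments <- function(true_effects, truth, ld, n_instruments,
                              effect_size, seed, exposure, outcome,
                              causal_effect = truth$causal_effect,
                              pleiotropy_shift = 0, exclude_blocks = NULL) {
  if (missing(seed)) stop("seed is required for reproducibility")
  avail <- setdiff(seq_along(ld$block_sizes), exclude_blocks)
  n_blocks <- length(avail)
  if (n_instruments > n_blocks)
    stop("n_instruments (", n_instruments, ") exceeds number of available ",
         "LD blocks (", n_blocks, ")")
  pleio <- rep_len(pleiotropy_shift, n_instruments)
  effect_size <- rep_len(effect_size, n_instruments)
  # direct-effect direction vectors across traits
  dir_vec <- function(which) {
    v <- numeric(truth$n_traits)
    if (is.list(which) && !is.null(which$factor)) {
      v <- truth$loadings[, which$factor] * sqrt(truth$trait_h2)
    } else {
      i <- match(which, truth$trait_names)
      if (is.na(i)) stop("unknown trait: ", which)
      v[i] <- 1
    }
    v
  }
  v_exp <- dir_vec(exposure)
  v_out <- dir_vec(outcome)
  # detectability of the combined exposure signal (factor-level for a
  # latent exposure, single-trait otherwise)
  z_needed <- stats::qnorm(1 - 2.5e-8, lower.tail = TRUE)
  min_eff <- z_needed / sqrt(sum(v_exp^2 * truth$sample_sizes))
  if (min(abs(effect_size)) < min_eff)
    warning("effect_size ", min(abs(effect_size)),
            " may not reach p < 5e-8; minimum detectable effect is about ",
            signif(min_eff, 3))
  set.seed(as.integer(seed))
  blocks <- sort(avail[sample.int(n_blocks, n_instruments)])
  # first SNP of each chosen block carries the instrument; the block's
  # polygenic background is cleared so the instrument's LD-smoothed effect
  # stays exactly proportional across traits (valid-instrument contract)
  first_of_block <- match(blocks, ld$snps$block)
  eff <- true_effects
  eff[ld$snps$block %in% blocks, ] <- 0
  for (j in seq_len(n_instruments)) {
    row <- v_exp * effect_size[j] +
      v_out * (causal_effect * effect_size[j] + pleio[j])
    eff[first_of_block[j], ] <- row
  }
  registry <- data.frame(
    snp = ld$snps$snp[first_of_block],
    block = blocks,
    exposure_effect = effect_size,
    outcome_effect = causal_effect * effect_size + pleio,
    pleiotropy = pleio,
    valid = pleio == 0,
    stringsAsFactors = FALSE
  )
  list(effects = eff, registry = registry)
}

#' Write summary statistics, LD scores, LD blocks and truth to text files
#'
#' Summary statistics are written as TSV with the conventional header
#' `SNP CHR BP A1 A2 BETA SE P N INFO FRQ`. Effects are converted from
#' standardized (per-SD) to per-allele units by dividing by
#' \eqn{\sqrt{2 p (1 - p)}} unless `per_allele = FALSE`; Z-scores (and
#' hence every downstream statistic) are unchanged by the scaling.
#'
#' @param sumstats named list of per-trait data frames from
#'   [simulate_sumstats()].
#' @param dir output directory (created if needed).
#' @param per_allele convert BETA/SE to per-allele units at write-out.
#' @return Invisibly, the vector of file paths written.
#' @export
write_sumstats <- function(sumstats, dir, per_allele = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(sumstats)) {
    tab <- sumstats[[nm]]
    if (per_allele) {
      sc <- sqrt(2 * tab$FRQ * (1 - tab$FRQ))
      tab$BETA <- tab$BETA / sc
      tab$SE <- tab$SE / sc
    }
    p <- file.path(dir, paste0(nm, ".sumstats.tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_sumstats
#' @param ld an [ld_structure()].
#' @export
write_ld_scores <- function(ld, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "ldscores.tsv")
  utils::write.table(
    data.frame(SNP = ld$snps$snp, CHR = ld$snps$chr, L2 = ld$snps$l2),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' @rdname write_sumstats
#' @export
write_ld_blocks <- function(ld, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "ldblocks.tsv")
  utils::write.table(
    data.frame(SNP = ld$snps$snp, CHR = ld$snps$chr, BP = ld$snps$bp,
               BLOCK = ld$snps$block, R2_WITHIN = ld$within_r2),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' @rdname write_sumstats
#' @param truth a [truth_model()].
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "truth.yaml")
  yaml::write_yaml(list(
    trait_names = truth$trait_names,
    n_factors = truth$n_factors,
    loadings = apply(truth$loadings, 1, as.numeric, simplify = FALSE),
    factor_corr = apply(truth$factor_corr, 1, as.numeric, simplify = FALSE),
    trait_h2 = truth$trait_h2,
    sample_sizes = truth$sample_sizes,
    causal_effect = truth$causal_effect
  ), p)
  invisible(p)
}

#' Read an LD reference block file written by [write_ld_blocks()]
#'
#' @param path TSV with columns `SNP, CHR, BP, BLOCK, R2_WITHIN`.
#' @return Data frame usable as the `ld_ref` argument of the MR functions.
#' @export
read_ld_blocks <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("SNP", "CHR", "BP", "BLOCK", "R2_WITHIN")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("LD block file missing column(s): ",
                         paste(miss, collapse = ", "))
  tab
}

#' Convert an ld_structure to the MR ld_ref table
#' @param ld an [ld_structure()].
#' @return Data frame with columns `SNP, CHR, BP, BLOCK, R2_WITHIN`.
#' @export
ld_ref_table <- function(ld) {
  data.frame(SNP = ld$snps$snp, CHR = ld$snps$chr, BP = ld$snps$bp,
             BLOCK = ld$snps$block, R2_WITHIN = ld$within_r2,
             stringsAsFactors = FALSE)
}
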