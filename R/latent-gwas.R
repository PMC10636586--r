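# Latent-factor GWAS.
#
# With the measurement model held fixed at its no-SNP estimates (two-stage
# approach), the common-pathway model for one SNP says the vector of
# standardized SNP-trait effects is beta * lambda, where lambda holds the
# covariance-scale loadings and beta is the SNP effect on the factor
# (factor variance 1, SNP variance 1). beta is estimated by DWLS across
# indicators; its sampling variance uses the full per-SNP sampling
# covariance, whose off-diagonal terms come from the cross-trait LDSC
# intercepts (sample overlap). Q_SNP contrasts this common-pathway model
# with the saturated independent-pathways model: it is the residual
# quadratic form with df = n_indicators - 1.

#' Augment a genetic covariance matrix with one SNP as an observed variable
#'
#' The SNP enters with unit variance (per-SD genotype units); its
#' covariances with the traits are the standardized per-SNP effects. The
#' expanded sampling covariance V gets the per-SNP sampling variances
#' (`se^2`) on the SNP rows, cross-trait terms implied by the
#' sample-overlap intercepts, and zero cross terms to the LDSC block.
#'
#' @param gc a `genetic_covariance` for the indicator traits.
#' @param beta_std per-trait standardized SNP effect (length = traits).
#' @param se_std per-trait standardized SE.
#' @return List of class `snp_augmented`: `S` ((k+1) x (k+1), SNP last),
#'   `V` (expanded, vech order), `traits`, `snp_idx`.
#' @export
snp_augmented_covariance <- function(gc, beta_std, se_std) {
  k <- length(gc$traits)
  if (length(beta_std) != k || length(se_std) != k)
    stop("need one standardized beta and SE per trait (", k, ")")
  if (anyNA(beta_std) || anyNA(se_std))
    stop("SNP missing in at least one trait; skip this SNP")
  S2 <- rbind(cbind(gc$S, beta_std), c(beta_std, 1))
  nm <- c(gc$traits, "SNP")
  dimnames(S2) <- list(nm, nm)
  pairs2 <- .vech_pairs(k + 1)
  n2 <- nrow(pairs2)
  V2 <- matrix(0, n2, n2)
  # map old vech positions into the expanded ordering
  old_pairs <- gc$vech_pairs
  pos2 <- function(i, j) which(pairs2[, "i"] == max(i, j) &
                                 pairs2[, "j"] == min(i, j))
  old_in_new <- mapply(pos2, old_pairs[, "i"], old_pairs[, "j"])
  V2[old_in_new, old_in_new] <- gc$V
  Rint <- .error_corr(gc$intercepts)
  snp_rows <- vapply(seq_len(k), function(i) pos2(k + 1, i), 1L)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    V2[snp_rows[i], snp_rows[j]] <-
      if (i == j) se_std[i]^2 else Rint[i, j] * se_std[i] * se_std[j]
  }
  structure(list(S = S2, V = V2, traits = gc$traits, snp_idx = k + 1,
                 vech_pairs = pairs2),
            class = "snp_augmented")
}

# The estimation-error covariance across traits for one SNP is
# intercept_ij * se_i * se_j (LDSC intercept theory). Intercept estimates
# are noisy, but the matrix they imply is a correlation-like matrix:
# clamp the diagonal near 1, bound off-diagonal correlations, and
# PD-smooth, so per-SNP sampling covariances are always valid.
.error_corr <- function(Rint) {
  d <- pmin(pmax(diag(Rint), 0.9), 1.1)
  R <- Rint / sqrt(outer(d, d))
  R[R > 0.9] <- 0.9
  R[R < -0.9] <- -0.9
  diag(R) <- d
  sm <- smooth_to_pd(R)
  attributes(sm) <- attributes(sm)["dim"]
  dimnames(sm) <- dimnames(Rint)
  sm
}

# core single-SNP estimator given loadings and per-SNP sampling covariance
.latent_beta_core <- function(beta_std, lambda, V_snp) {
  Dinv <- 1 / pmax(diag(V_snp), 1e-300)
  denom <- sum(lambda^2 * Dinv)
  w <- (lambda * Dinv) / denom
  b <- sum(w * beta_std)
  se <- sqrt(as.numeric(t(w) %*% V_snp %*% w))
  k <- length(lambda)
  IP <- diag(k) - outer(lambda, w)
  Omega <- IP %*% V_snp %*% t(IP)
  e <- beta_std - b * lambda
  q <- max(0, as.numeric(e %*% .pinv_rank(Omega, k - 1) %*% e))
  list(beta = b, se = se, q = q, df = k - 1)
}

#' SNP effect on a latent factor from an augmented covariance matrix
#'
#' Fits the common-pathway model (SNP acts on the factor only) with the
#' measurement model held fixed, returning the factor-level effect, its
#' sandwich SE, Wald p-value, and the Q_SNP heterogeneity statistic
#' contrasting common- versus independent-pathways (df = indicators - 1).
#'
#' @param aug a `snp_augmented` from [snp_augmented_covariance()].
#' @param lambda fixed covariance-scale loadings of the indicators on the
#'   factor (from the no-SNP measurement fit).
#' @return One-row data frame: `beta_latent, se_latent, p_latent, q_snp,
#'   q_snp_df, q_snp_p`.
#' @export
latent_snp_effect <- function(aug, lambda) {
  k <- length(aug$traits)
  stopifnot(length(lambda) == k)
  beta_std <- aug$S[aug$snp_idx, seq_len(k)]
  pairs <- aug$vech_pairs
  snp_rows <- vapply(seq_len(k), function(i)
    which(pairs[, "i"] == aug$snp_idx & pairs[, "j"] == i), 1L)
  V_snp <- aug$V[snp_rows, snp_rows, drop = FALSE]
  r <- .latent_beta_core(beta_std, lambda, V_snp)
  data.frame(beta_latent = r$beta, se_latent = r$se,
             p_latent = 2 * stats::pnorm(-abs(r$beta / r$se)),
             q_snp = r$q, q_snp_df = r$df,
             q_snp_p = stats::pchisq(r$q, r$df, lower.tail = FALSE))
}

#' Latent-factor GWAS across all SNPs of harmonized summary statistics
#'
#' Two-stage multivariate GWAS: the measurement model (a single factor
#' over the given indicator traits) is fit once to `gc`, then each SNP's
#' standardized effects are regressed on the fixed loadings. Output is a
#' summary-statistics-shaped table directly consumable by the MR module,
#' with per-SNP effective N = 1/se^2.
#'
#' @param tables named list of harmonized sumstats (must include every
#'   indicator).
#' @param gc `genetic_covariance` used for the measurement model
#'   (conventionally the even-chromosome subset) and for the
#'   sample-overlap intercepts.
#' @param indicators trait names loading on the factor.
#' @param factor_name label for the output trait.
#' @param measurement_fit optionally, a pre-computed `gsem_fit` for the
#'   single-factor measurement model.
#' @return Data frame of class `sumstats` with columns
#'   `snp, chr, bp, a1, a2, beta, se, p, n, info, frq, z, q_snp, q_snp_df,
#'   q_snp_p`.
#' @export
latent_gwas <- function(tables, gc, indicators, factor_name = "FACTOR",
                        measurement_fit = NULL) {
  miss <- setdiff(indicators, names(tables))
  if (length(miss)) stop("tables missing indicator(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(measurement_fit)) {
    txt <- paste0("F1 =~ ", paste(indicators, collapse = " + "))
    measurement_fit <- cfa_fit(gc, txt)
  }
  lam_tab <- measurement_fit$params
  lam <- numeric(length(indicators))
  for (i in seq_along(indicators)) {
    row <- lam_tab[lam_tab$mat == "lam" &
                     measurement_fit$spec$observed[lam_tab$i] == indicators[i], ]
    if (nrow(row) != 1) stop("no unique loading for ", indicators[i])
    lam[i] <- row$est
  }
  tabs <- tables[indicators]
  snps <- tabs[[1]]$snp
  k <- length(indicators)
  B <- vapply(tabs, function(t) t$z / sqrt(t$n), numeric(length(snps)))
  SE <- vapply(tabs, function(t) 1 / sqrt(t$n), numeric(length(snps)))
  Rint <- .error_corr(gc$intercepts[indicators, indicators, drop = FALSE])
  n_pattern <- apply(SE, 1, paste, collapse = ",")
  out_beta <- numeric(length(snps)); out_se <- numeric(length(snps))
  out_q <- numeric(length(snps))
  for (pat in unique(n_pattern)) {
    idx <- which(n_pattern == pat)
    se_i <- SE[idx[1], ]
    V_snp <- Rint * outer(se_i, se_i)
    diag(V_snp) <- se_i^2 * diag(Rint)
    Dinv <- 1 / pmax(diag(V_snp), 1e-300)
    denom <- sum(lam^2 * Dinv)
    w <- (lam * Dinv) / denom
    se_b <- sqrt(as.numeric(t(w) %*% V_snp %*% w))
    IP <- diag(k) - outer(lam, w)
    Omega_p <- .pinv_rank(IP %*% V_snp %*% t(IP), k - 1)
    Bi <- B[idx, , drop = FALSE]
    bhat <- as.numeric(Bi %*% w)
    E <- Bi - outer(bhat, lam)
    out_beta[idx] <- bhat
    out_se[idx] <- se_b
    out_q[idx] <- pmax(0, rowSums((E %*% Omega_p) * E))
  }
  z <- out_beta / out_se
  ref <- tabs[[1]]
  res <- data.frame(
    snp = snps, chr = ref$chr, bp = ref$bp, a1 = ref$a1, a2 = ref$a2,
    beta = out_beta, se = out_se, p = 2 * stats::pnorm(-abs(z)),
    n = 1 / out_se^2, info = ref$info, frq = ref$frq, z = z,
    q_snp = out_q, q_snp_df = k - 1,
    q_snp_p = stats::pchisq(out_q, k - 1, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  attr(res, "factor_name") <- factor_name
  attr(res, "loadings") <- stats::setNames(lam, indicators)
  class(res) <- c("sumstats", "data.frame")
  res
}

#' Filter latent-factor SNP effects on the Q_SNP statistic
#'
#' Retains SNPs whose Q_SNP p-value is at or above `threshold`; SNPs below
#' it show heterogeneous indicator effects inconsistent with action
#' through the factor and are excluded.
#'
#' @param effects data frame with columns `q_snp_p` (e.g. from
#'   [latent_gwas()]).
#' @param threshold exclusion p-value threshold.
#' @return Retained rows; attribute `excluded` holds the excluded SNP ids.
#' @export
qsnp_filter <- function(effects, threshold = 5e-8) {
  if (nrow(effects) == 0) return(effects)
  drop <- effects$q_snp_p < threshold
  out <- effects[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- effects$snp[drop]
  out
}
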