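# LD score regression.
#
# Univariate: E[chi2_j] = 1 + N h2 l_j / M, estimated by weighted regression
# of z^2 on the LD score l_j. Bivariate: E[z1j z2j] = sqrt(N1 N2) cov_g l_j /
# M + intercept, the intercept absorbing sample-overlap-induced error
# correlation. Standard errors and the sampling covariance V of the genetic
# covariance matrix S come from a delete-one block jackknife over contiguous
# genomic blocks, shared across all trait pairs so that covariances between
# S elements are estimated from the same pseudovalues.

# Weighted 2-parameter regression of y on x with delete-one-block jackknife.
# Returns full-sample (intercept, slope) and the n_blocks x 2 delete-block
# estimates. Weights are held fixed across jackknife deletions.
.jk_wls <- function(x, y, w, block_id, n_blocks) {
  X <- cbind(1, x)
  wX <- X * w
  A_full <- crossprod(wX, X)          # 2x2
  c_full <- crossprod(wX, y)          # 2x1
  est <- solve(A_full, c_full)
  # per-block sufficient statistics
  a11 <- rowsum(w, block_id)
  a12 <- rowsum(w * x, block_id)
  a22 <- rowsum(w * x * x, block_id)
  c1 <- rowsum(w * y, block_id)
  c2 <- rowsum(w * x * y, block_id)
  del <- matrix(0, n_blocks, 2)
  for (b in seq_len(n_blocks)) {
    A <- A_full - matrix(c(a11[b], a12[b], a12[b], a22[b]), 2, 2)
    cc <- c_full - c(c1[b], c2[b])
    del[b, ] <- solve(A, cc)
  }
  list(est = as.numeric(est), delete = del)
}

.jk_se <- function(delete_vals) {
  nb <- NROW(delete_vals)
  m <- colMeans(as.matrix(delete_vals))
  sqrt((nb - 1) / nb *
         colSums(sweep(as.matrix(delete_vals), 2, m)^2))
}

# Merge a sumstats table with LD scores and assign contiguous jackknife
# blocks in genome order. When an LD reference (per-SNP LD-block id) is
# supplied, jackknife boundaries snap to LD-block boundaries so that the
# delete-one blocks are genuinely independent; otherwise an LD block
# straddling a boundary correlates adjacent jackknife blocks and the
# variance is underestimated.
.ldsc_prepare <- function(tabs, ld_scores, n_blocks, ld_blocks = NULL) {
  ls <- data.frame(snp = as.character(ld_scores$SNP), l2 = ld_scores$L2,
                   stringsAsFactors = FALSE)
  common <- Reduce(intersect, c(list(ls$snp), lapply(tabs, `[[`, "snp")))
  if (length(common) < 50 * n_blocks)
    stop("too few SNPs merged with LD scores (", length(common),
         ") for ", n_blocks, " jackknife blocks")
  tabs <- lapply(tabs, function(t) t[match(common, t$snp), , drop = FALSE])
  ord <- order(tabs[[1]]$chr, tabs[[1]]$bp)
  tabs <- lapply(tabs, function(t) t[ord, , drop = FALSE])
  l2 <- ls$l2[match(tabs[[1]]$snp, ls$snp)]
  M <- length(l2)
  block_id <- NULL
  if (!is.null(ld_blocks)) {
    lb <- ld_blocks$BLOCK[match(tabs[[1]]$snp, ld_blocks$SNP)]
    if (!anyNA(lb)) {
      runs <- rle(lb)
      mid <- cumsum(runs$lengths) - runs$lengths / 2
      run_block <- pmin(ceiling(mid / (M / n_blocks)), n_blocks)
      block_id <- rep.int(run_block, runs$lengths)
      block_id <- match(block_id, sort(unique(block_id)))
    }
  }
  if (is.null(block_id))
    block_id <- ceiling(seq_len(M) / (M / n_blocks))
  list(tabs = tabs, l2 = l2, M = M, block_id = block_id,
       n_blocks = max(block_id))
}

#' Univariate LD score regression
#'
#' Estimates SNP heritability (observed scale) and the LDSC intercept by
#' regressing per-SNP chi-square statistics on LD scores, with
#' heteroskedasticity weights updated from an initial unweighted fit
#' (two-step: `w_j = 1 / (l_j * fitted_j^2)`), and delete-one-block
#' jackknife standard errors over contiguous genomic blocks.
#'
#' @param t a sumstats data frame (needs `snp, chr, bp, z, n`).
#' @param ld_scores data frame with columns `SNP`, `L2`.
#' @param n_blocks number of jackknife blocks.
#' @param ld_blocks optional LD reference (columns `SNP`, `BLOCK`): when
#'   given, jackknife boundaries are snapped to LD-block boundaries so
#'   delete-one blocks are independent.
#' @param M_ref SNP count used to convert the regression slope to a
#'   heritability. Defaults to the number of regression SNPs; pass the
#'   genome-wide count when regressing on a chromosome subset so the
#'   estimate remains genome-wide (under a uniform per-SNP architecture).
#' @return List: `h2`, `h2_se`, `intercept`, `intercept_se`, `mean_chi2`,
#'   `M`, `n_bar`, `h2_delete` (per-block estimates), `flag` (set when
#'   h2 < 0).
#' @export
univariate_ldsc <- function(t, ld_scores, n_blocks = 200, M_ref = NULL,
                            ld_blocks = NULL) {
  prep <- .ldsc_prepare(list(t), ld_scores, n_blocks, ld_blocks)
  n_blocks <- prep$n_blocks
  tt <- prep$tabs[[1]]
  l2 <- prep$l2
  M <- if (is.null(M_ref)) prep$M else M_ref
  n_bar <- mean(tt$n)
  y <- tt$z^2
  if (all(y == 0)) {
    return(list(h2 = 0, h2_se = 0, intercept = 0, intercept_se = 0,
                mean_chi2 = 0, M = M, n_bar = n_bar,
                h2_delete = rep(0, n_blocks), intercept_delete = rep(0, n_blocks),
                flag = "degenerate: all z = 0"))
  }
  fit0 <- stats::lm.fit(cbind(1, l2), y)
  fitted <- pmax(fit0$fitted.values, 0.5)
  w <- 1 / (l2 * fitted^2)
  jk <- .jk_wls(l2, y, w, prep$block_id, n_blocks)
  scale <- M / n_bar
  h2 <- jk$est[2] * scale
  h2_del <- jk$delete[, 2] * scale
  int_del <- jk$delete[, 1]
  se <- .jk_se(cbind(h2_del, int_del))
  flag <- if (h2 < 0) "negative h2" else NULL
  list(h2 = h2, h2_se = se[1], intercept = jk$est[1], intercept_se = se[2],
       mean_chi2 = mean(y), M = M, n_bar = n_bar,
       h2_delete = h2_del, intercept_delete = int_del, flag = flag)
}

#' Bivariate (cross-trait) LD score regression
#'
#' Regresses the product `z1 * z2` on LD scores: the slope estimates the
#' genetic covariance (scaled by `sqrt(N1 N2) / M`) and the intercept the
#' sample-overlap term. Weights derive from the univariate fitted values,
#' `w_j = 1 / (l_j * (f1_j f2_j + f12_j^2))`.
#'
#' @param t1,t2 harmonized sumstats data frames (same SNPs, same order
#'   after internal merge).
#' @param ld_scores data frame with `SNP`, `L2`.
#' @param n_blocks jackknife blocks.
#' @param ld_blocks optional LD reference for boundary-aligned jackknife
#'   blocks (see [univariate_ldsc()]).
#' @param M_ref SNP count for slope-to-covariance conversion (see
#'   [univariate_ldsc()]).
#' @return List: `cov`, `cov_se`, `intercept`, `intercept_se`,
#'   `cov_delete`, `M`.
#' @export
bivariate_ldsc <- function(t1, t2, ld_scores, n_blocks = 200, M_ref = NULL,
                           ld_blocks = NULL) {
  prep <- .ldsc_prepare(list(t1, t2), ld_scores, n_blocks, ld_blocks)
  n_blocks <- prep$n_blocks
  a <- prep$tabs[[1]]; b <- prep$tabs[[2]]
  l2 <- prep$l2; M <- if (is.null(M_ref)) prep$M else M_ref
  y <- a$z * b$z
  n_geo <- sqrt(mean(a$n) * mean(b$n))
  f1 <- pmax(stats::lm.fit(cbind(1, l2), a$z^2)$fitted.values, 0.5)
  f2 <- pmax(stats::lm.fit(cbind(1, l2), b$z^2)$fitted.values, 0.5)
  f12 <- stats::lm.fit(cbind(1, l2), y)$fitted.values
  w <- 1 / (l2 * (f1 * f2 + f12^2))
  jk <- .jk_wls(l2, y, w, prep$block_id, n_blocks)
  scale <- M / n_geo
  cov_del <- jk$delete[, 2] * scale
  int_del <- jk$delete[, 1]
  se <- .jk_se(cbind(cov_del, int_del))
  list(cov = jk$est[2] * scale, cov_se = se[1],
       intercept = jk$est[1], intercept_se = se[2],
       cov_delete = cov_del, intercept_delete = int_del, M = M)
}

# lower-triangle (column-major) index pairs for a k x k symmetric matrix
.vech_pairs <- function(k) {
  ii <- jj <- integer(0)
  for (j in seq_len(k)) {
    ii <- c(ii, j:k)
    jj <- c(jj, rep(j, k - j + 1))
  }
  cbind(i = ii, j = jj)
}

#' Multi-trait genetic covariance matrix S with sampling covariance V
#'
#' Runs univariate and all pairwise bivariate LD score regressions on a
#' shared SNP set and shared jackknife blocks, optionally restricted to
#' odd or even chromosomes, and assembles: S (genetic covariance, diagonal
#' = h2), V (jackknife sampling covariance of vech(S), lower triangle
#' column-major), and the intercept matrix.
#'
#' @param tables named list of >= 1 harmonized sumstats data frames.
#' @param ld_scores data frame with `SNP`, `L2`.
#' @param subset one of `"all"`, `"odd_chr"`, `"even_chr"`. With a parity
#'   subset the regression runs on those chromosomes but the slope is
#'   converted with the genome-wide SNP count, so S stays a genome-wide
#'   genetic covariance (uniform per-SNP architecture assumption) and the
#'   odd/even matrices are directly comparable to the all-chromosome one.
#' @param n_blocks jackknife blocks.
#' @param ld_blocks optional LD reference for boundary-aligned jackknife
#'   blocks (see [univariate_ldsc()]).
#' @return An object of class `genetic_covariance`: list with `traits`,
#'   `S`, `V`, `intercepts`, `n_blocks`, `subset`, `delete` (n_blocks x
#'   n_param delete-block estimates of vech(S)), `M`.
#' @export
build_S_V <- function(tables, ld_scores, subset = c("all", "odd_chr", "even_chr"),
                      n_blocks = 200, ld_blocks = NULL) {
  subset <- match.arg(subset)
  if (is.null(names(tables)))
    names(tables) <- paste0("trait", seq_along(tables))
  traits <- names(tables)
  k <- length(tables)
  M_genome <- length(intersect(as.character(ld_scores$SNP), tables[[1]]$snp))
  tables <- lapply(tables, function(t) {
    if (subset == "odd_chr") t[t$chr %% 2 == 1, , drop = FALSE]
    else if (subset == "even_chr") t[t$chr %% 2 == 0, , drop = FALSE]
    else t
  })
  if (nrow(tables[[1]]) < 50 * n_blocks)
    stop("chromosome subset '", subset, "' leaves too few SNPs (",
         nrow(tables[[1]]), ") for ", n_blocks, " blocks")
  prep <- .ldsc_prepare(tables, ld_scores, n_blocks, ld_blocks)
  n_blocks <- prep$n_blocks
  tabs <- prep$tabs; l2 <- prep$l2; block_id <- prep$block_id
  M <- if (subset == "all") prep$M else M_genome
  pairs <- .vech_pairs(k)
  n_par <- nrow(pairs)
  S <- matrix(0, k, k, dimnames = list(traits, traits))
  intercepts <- matrix(0, k, k, dimnames = list(traits, traits))
  delete <- matrix(0, n_blocks, n_par)
  # univariate fitted values for the weight formula, computed once
  fit_uni <- lapply(tabs, function(t)
    pmax(stats::lm.fit(cbind(1, l2), t$z^2)$fitted.values, 0.5))
  for (p in seq_len(n_par)) {
    i <- pairs[p, "i"]; j <- pairs[p, "j"]
    y <- tabs[[i]]$z * tabs[[j]]$z
    n_geo <- sqrt(mean(tabs[[i]]$n) * mean(tabs[[j]]$n))
    if (i == j) {
      w <- 1 / (l2 * fit_uni[[i]]^2)
    } else {
      f12 <- stats::lm.fit(cbind(1, l2), y)$fitted.values
      w <- 1 / (l2 * (fit_uni[[i]] * fit_uni[[j]] + f12^2))
    }
    jk <- .jk_wls(l2, y, w, block_id, n_blocks)
    scale <- M / n_geo
    S[i, j] <- S[j, i] <- jk$est[2] * scale
    intercepts[i, j] <- intercepts[j, i] <- jk$est[1]
    delete[, p] <- jk$delete[, 2] * scale
  }
  dm <- sweep(delete, 2, colMeans(delete))
  V <- (n_blocks - 1) / n_blocks * crossprod(dm)
  structure(list(traits = traits, S = S, V = V, intercepts = intercepts,
                 n_blocks = n_blocks, subset = subset, delete = delete,
                 M = M, vech_pairs = pairs),
            class = "genetic_covariance")
}

#' @export
print.genetic_covariance <- function(x, ...) {
  cat("Genetic covariance (", x$subset, "): ", length(x$traits),
      " traits, ", x$M, " SNPs, ", x$n_blocks, " jackknife blocks\n", sep = "")
  print(round(x$S, 4))
  invisible(x)
}

#' Genetic correlations with jackknife SEs and FDR-corrected p-values
#'
#' `rg_ij = S_ij / sqrt(S_ii S_jj)`, with standard errors from the shared
#' block jackknife applied to the ratio, two-sided normal p-values, and
#' Benjamini-Hochberg adjustment across the trait pairs.
#'
#' @param gc a `genetic_covariance` from [build_S_V()].
#' @return An object of class `correlation_report`: list of matrices `rg`,
#'   `se`, `p`, `p_fdr`.
#' @export
correlation_report <- function(gc) {
  k <- length(gc$traits)
  if (any(diag(gc$S) <= 0))
    stop("non-positive heritability for trait(s): ",
         paste(gc$traits[diag(gc$S) <= 0], collapse = ", "))
  pairs <- gc$vech_pairs
  diag_idx <- which(pairs[, "i"] == pairs[, "j"])
  col_of <- function(i, j) which((pairs[, "i"] == max(i, j)) &
                                   (pairs[, "j"] == min(i, j)))
  rg <- diag(1, k); se <- matrix(0, k, k); p <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i > j) {
    sij <- gc$S[i, j]
    rg_hat <- sij / sqrt(gc$S[i, i] * gc$S[j, j])
    del <- gc$delete[, col_of(i, j)] /
      sqrt(gc$delete[, col_of(i, i)] * gc$delete[, col_of(j, j)])
    ok <- is.finite(del)
    rg_se <- .jk_se(del[ok])
    zstat <- rg_hat / rg_se
    rg[i, j] <- rg[j, i] <- rg_hat
    se[i, j] <- se[j, i] <- rg_se
    p[i, j] <- p[j, i] <- 2 * stats::pnorm(-abs(zstat))
  }
  lower <- lower.tri(p)
  p_adj <- matrix(NA_real_, k, k)
  p_adj[lower] <- stats::p.adjust(p[lower], method = "BH")
  p_adj[upper.tri(p_adj)] <- t(p_adj)[upper.tri(p_adj)]
  dimnames(rg) <- dimnames(se) <- dimnames(p) <- dimnames(p_adj) <-
    list(gc$traits, gc$traits)
  structure(list(rg = rg, se = se, p = p, p_fdr = p_adj),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("Genetic correlations (FDR-corrected p-values in attr):\n")
  print(round(x$rg, 3))
  invisible(x)
}
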