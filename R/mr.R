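# Two-sample Mendelian randomization.
#
# Instruments are LD-independent genome-wide significant SNPs for the
# exposure; per-SNP Wald ratios beta_Y / beta_X are combined by five
# estimators with different robustness to invalid instruments. All inputs
# are sumstats-shaped data frames (the latent-factor GWAS output
# qualifies), so the same machinery runs trait-trait, trait-factor and
# factor-factor analyses in either direction.

#' Select LD-independent genome-wide significant instruments
#'
#' Greedy clumping: candidates with exposure p below `p_threshold` are
#' sorted by ascending p (ties broken by position, then id); each index
#' SNP is accepted, and remaining candidates within `window_kb` of an
#' accepted SNP on the same chromosome with reference r-squared above
#' `r2_cap` are discarded. SNPs absent from the LD reference are treated
#' as independent and logged.
#'
#' @param exposure a sumstats data frame.
#' @param ld_ref data frame with columns `SNP`, `BLOCK`, `R2_WITHIN`
#'   (block-diagonal LD reference: same block = `R2_WITHIN`, different
#'   block = 0), e.g. from [ld_ref_table()].
#' @param p_threshold genome-wide significance threshold.
#' @param window_kb clump window, kilobases each side of the index SNP.
#' @param r2_cap r-squared above which a SNP is clumped away.
#' @return An `instrument_set` data frame (exposure side): columns
#'   `snp, chr, bp, a1, a2, beta_exp, se_exp, p_exp, n_exp`; attribute
#'   `provenance` records the thresholds; `status` is `"ok"` or
#'   `"empty"`.
#' @export
select_instruments <- function(exposure, ld_ref, p_threshold = 5e-8,
                               window_kb = 10000, r2_cap = 0.001) {
  cand <- exposure[exposure$p < p_threshold, , drop = FALSE]
  prov <- list(p_threshold = p_threshold, window_kb = window_kb,
               r2_cap = r2_cap)
  if (nrow(cand) == 0) {
    out <- data.frame(snp = character(0), chr = integer(0), bp = numeric(0),
                      a1 = character(0), a2 = character(0),
                      beta_exp = numeric(0), se_exp = numeric(0),
                      p_exp = numeric(0), n_exp = numeric(0))
    attr(out, "provenance") <- prov
    attr(out, "status") <- "empty"
    class(out) <- c("instrument_set", "data.frame")
    return(out)
  }
  cand <- cand[order(cand$p, cand$bp, cand$snp), , drop = FALSE]
  block <- ld_ref$BLOCK[match(cand$snp, ld_ref$SNP)]
  r2w <- ld_ref$R2_WITHIN[match(cand$snp, ld_ref$SNP)]
  n_uncovered <- sum(is.na(block))
  if (n_uncovered > 0)
    message("select_instruments: ", n_uncovered,
            " candidate SNP(s) absent from LD reference, treated as ",
            "independent")
  accepted <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(accepted)) {
      acc <- which(accepted)
      same_chr <- cand$chr[acc] == cand$chr[i]
      near <- same_chr & abs(cand$bp[acc] - cand$bp[i]) < window_kb * 1000
      if (any(near)) {
        r2 <- ifelse(!is.na(block[i]) & !is.na(block[acc[near]]) &
                       block[acc[near]] == block[i],
                     pmax(r2w[i], r2w[acc[near]]), 0)
        if (any(r2 > r2_cap)) ok <- FALSE
      }
    }
    accepted[i] <- ok
  }
  kept <- cand[accepted, , drop = FALSE]
  out <- data.frame(snp = kept$snp, chr = kept$chr, bp = kept$bp,
                    a1 = kept$a1, a2 = kept$a2,
                    beta_exp = kept$beta, se_exp = kept$se,
                    p_exp = kept$p, n_exp = kept$n,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "provenance") <- prov
  attr(out, "status") <- "ok"
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Harmonize instruments with the outcome GWAS
#'
#' Joins outcome effects onto the instrument set, aligning the outcome
#' effect allele to the exposure's (sign-flipping beta when a1/a2 are
#' swapped), dropping palindromic (A/T, C/G) and allele-mismatched SNPs,
#' then orienting every exposure beta positive (flipping the outcome in
#' tandem), the convention required by the Egger and mode estimators.
#'
#' @param instruments an `instrument_set` from [select_instruments()].
#' @param outcome a sumstats data frame.
#' @return The instrument set with `beta_out, se_out, p_out, n_out`
#'   appended; attribute `log` records drops.
#' @export
harmonize_io <- function(instruments, outcome) {
  m <- match(instruments$snp, outcome$snp)
  absent <- is.na(m)
  if (any(absent))
    message("harmonize_io: ", sum(absent),
            " instrument(s) absent from outcome, dropped")
  iset <- instruments[!absent, , drop = FALSE]
  om <- outcome[m[!absent], , drop = FALSE]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- iset$a2 == comp[iset$a1]
  same <- om$a1 == iset$a1 & om$a2 == iset$a2
  swapped <- om$a1 == iset$a2 & om$a2 == iset$a1
  flip_same <- om$a1 == comp[iset$a1] & om$a2 == comp[iset$a2] & !palindromic
  flip_swap <- om$a1 == comp[iset$a2] & om$a2 == comp[iset$a1] & !palindromic
  ok <- (same | swapped | flip_same | flip_swap) & !palindromic
  do_swap <- (swapped | flip_swap) & !(same | flip_same)
  beta_out <- ifelse(do_swap, -om$beta, om$beta)
  iset$beta_out <- beta_out
  iset$se_out <- om$se
  iset$p_out <- om$p
  iset$n_out <- om$n
  n_palin <- sum(palindromic)
  n_mismatch <- sum(!ok) - n_palin
  iset <- iset[ok, , drop = FALSE]
  # orient exposure effects positive
  neg <- iset$beta_exp < 0
  iset$beta_exp[neg] <- -iset$beta_exp[neg]
  iset$beta_out[neg] <- -iset$beta_out[neg]
  rownames(iset) <- NULL
  if (nrow(iset) < 2)
    stop("fewer than 2 instruments survive harmonization (",
         nrow(iset), ")")
  attr(iset, "provenance") <- attr(instruments, "provenance")
  attr(iset, "log") <- list(n_absent = sum(absent),
                            n_palindromic = n_palin,
                            n_mismatch = n_mismatch,
                            n_final = nrow(iset))
  class(iset) <- c("instrument_set", "data.frame")
  iset
}

.mr_result <- function(method, beta, se, n_snp, extra = list()) {
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = beta - stats::qnorm(0.975) * se,
                ci_high = beta + stats::qnorm(0.975) * se,
                p = 2 * stats::pnorm(-abs(beta / se)),
                n_snp = n_snp), extra)
  class(out) <- "mr_result"
  out
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$p, x$n_snp))
  invisible(x)
}

#' Wald ratio for a single instrument
#' @param beta_exp,beta_out,se_out exposure/outcome effects and outcome SE.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out) {
  .mr_result("WaldRatio", beta_out / beta_exp, se_out / abs(beta_exp), 1L)
}

#' Inverse-variance weighted MR
#'
#' Weighted regression of outcome on exposure betas through the origin
#' with weights `1/se_out^2`; equivalently the closed form
#' `sum(w bX bY) / sum(w bX^2)`. The standard error uses multiplicative
#' random effects: the fixed-effects SE scaled by `max(1, sqrt(Q/df))`.
#'
#' @param iset a harmonized `instrument_set`.
#' @param random_effects use the multiplicative random-effects SE
#'   (default) or plain fixed effects.
#' @return An `mr_result` with `q`, `q_df`, `q_p` appended.
#' @export
mr_ivw <- function(iset, random_effects = TRUE) {
  n <- nrow(iset)
  if (n < 2) stop("IVW needs at least 2 instruments (got ", n, ")")
  w <- 1 / iset$se_out^2
  bx <- iset$beta_exp; by <- iset$beta_out
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fe <- sqrt(1 / sum(w * bx^2))
  q <- sum(w * (by - beta * bx)^2)
  df <- n - 1
  scale <- if (random_effects) max(1, sqrt(q / df)) else 1
  .mr_result("IVW", beta, se_fe * scale, n,
             list(q = q, q_df = df,
                  q_p = stats::pchisq(q, df, lower.tail = FALSE)))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure betas with a free intercept
#' (exposure betas must be orientation-positive, as [harmonize_io()]
#' ensures). The intercept estimates average directional pleiotropy; the
#' I2_GX statistic gauges NOME violation (regression-dilution risk) from
#' the exposure-beta measurement error.
#'
#' @param iset a harmonized `instrument_set`.
#' @return An `mr_result` with `egger_intercept`, `intercept_se`,
#'   `intercept_p`, `q`, `q_df`, `q_p`, `i2_gx`.
#' @export
mr_egger <- function(iset) {
  n <- nrow(iset)
  if (n < 3) stop("MR-Egger needs at least 3 instruments (got ", n, ")")
  w <- 1 / iset$se_out^2
  bx <- abs(iset$beta_exp); by <- sign(iset$beta_exp) * iset$beta_out
  fit <- stats::lm(by ~ bx, weights = w)
  beta <- stats::coef(fit)[["bx"]]
  a <- stats::coef(fit)[["(Intercept)"]]
  q <- sum(w * stats::residuals(fit)^2)
  df <- n - 2
  scale <- max(1, sqrt(q / df))
  # unscaled (sigma = 1) weighted-LS covariance, then multiplicative RE
  XtWX <- crossprod(cbind(1, bx) * sqrt(w))
  cov_u <- solve(XtWX)
  se_beta <- sqrt(cov_u[2, 2]) * scale
  se_a <- sqrt(cov_u[1, 1]) * scale
  wx <- 1 / iset$se_exp^2
  xbar <- sum(wx * bx) / sum(wx)
  q_gx <- sum(wx * (bx - xbar)^2)
  i2_gx <- max(0, (q_gx - (n - 1)) / q_gx)
  .mr_result("Egger", beta, se_beta, n,
             list(egger_intercept = a, intercept_se = se_a,
                  intercept_p = 2 * stats::pnorm(-abs(a / se_a)),
                  q = q, q_df = df,
                  q_p = stats::pchisq(q, df, lower.tail = FALSE),
                  i2_gx = i2_gx))
}

.ratio_stats <- function(iset) {
  r <- iset$beta_out / iset$beta_exp
  # delta-method variance of the Wald ratio
  v <- iset$se_out^2 / iset$beta_exp^2 +
    iset$beta_out^2 * iset$se_exp^2 / iset$beta_exp^4
  list(ratio = r, var = v, w = 1 / v)
}

.weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(r[1])
  if (cs[length(cs)] <= 0.5) return(r[length(r)])
  below <- max(which(cs < 0.5))
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted-median MR
#'
#' The inverse-variance-weighted median of per-SNP Wald ratios: consistent
#' when instruments contributing at least half the weight are valid. SE by
#' parametric bootstrap under a fixed seed.
#'
#' @param iset a harmonized `instrument_set`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(iset, n_boot = 1000, seed = 1) {
  n <- nrow(iset)
  if (n < 3) stop("weighted median needs at least 3 instruments (got ", n, ")")
  rs <- .ratio_stats(iset)
  est <- .weighted_median(rs$ratio, rs$w)
  set.seed(as.integer(seed))
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(n, iset$beta_exp, iset$se_exp)
    by <- stats::rnorm(n, iset$beta_out, iset$se_out)
    r <- by / bx
    v <- iset$se_out^2 / bx^2 + by^2 * iset$se_exp^2 / bx^4
    boots[b] <- .weighted_median(r, 1 / v)
  }
  .mr_result("WeightedMedian", est, stats::sd(boots), n)
}

.weighted_mode_est <- function(r, w, bandwidth_factor) {
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) s <- stats::sd(r) * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) return(stats::median(r))
  h <- bandwidth_factor * s
  # the maximum of a Gaussian mixture lies within the convex hull of its
  # centres, so the data range suffices whatever the bandwidth
  grid <- seq(min(r), max(r), length.out = 512)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - r) / h)), 0)
  grid[which.max(dens)]
}

#' Weighted-mode MR
#'
#' The mode of the inverse-variance-weighted kernel density of per-SNP
#' Wald ratios (Gaussian kernel, modified-Silverman bandwidth scaled by
#' `bandwidth_factor`): consistent when the largest group of instruments
#' sharing a ratio is valid. SE by parametric bootstrap.
#'
#' @param iset a harmonized `instrument_set`.
#' @param bandwidth_factor multiplier on the modified-Silverman bandwidth.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return An `mr_result`.
#' @export
mr_weighted_mode <- function(iset, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1) {
  n <- nrow(iset)
  if (n < 3) stop("weighted mode needs at least 3 instruments (got ", n, ")")
  rs <- .ratio_stats(iset)
  if (stats::sd(rs$ratio) == 0) {
    est <- rs$ratio[1]
    return(.mr_result("WeightedMode", est, 0, n))
  }
  est <- .weighted_mode_est(rs$ratio, rs$w, bandwidth_factor)
  set.seed(as.integer(seed))
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(n, iset$beta_exp, iset$se_exp)
    by <- stats::rnorm(n, iset$beta_out, iset$se_out)
    r <- by / bx
    v <- iset$se_out^2 / bx^2 + by^2 * iset$se_exp^2 / bx^4
    boots[b] <- .weighted_mode_est(r, 1 / v, bandwidth_factor)
  }
  .mr_result("WeightedMode", est, stats::sd(boots), n)
}

#' MR robust adjusted profile score (RAPS)
#'
#' Estimates the causal effect from the profile likelihood that accounts
#' for measurement error in the exposure betas: profiling out the true
#' per-SNP exposure effects leaves the standardized residuals
#' `t_j = (bY_j - b bX_j) / sqrt(seY_j^2 + b^2 seX_j^2 + tau^2)`, and the
#' estimate minimizes `sum(rho(t_j))` (squared-error or Huber loss). The
#' overdispersion variance `tau^2`, absorbing systematic balanced
#' pleiotropy, is profiled by the method of moments (`mean(t^2) = 1`),
#' alternating with the slope until joint convergence. With negligible
#' exposure error and no overdispersion the estimate collapses to IVW.
#' The standard error is a sandwich estimate from the profile score.
#'
#' @param iset a harmonized `instrument_set`.
#' @param overdispersion estimate an additive overdispersion variance.
#' @param loss `"l2"` (default) or `"huber"`.
#' @param huber_k Huber tuning constant.
#' @return An `mr_result` with `overdispersion` appended; `flag` is set on
#'   optimizer failure.
#' @export
mr_raps <- function(iset, overdispersion = TRUE, loss = c("l2", "huber"),
                    huber_k = 1.345) {
  loss <- match.arg(loss)
  n <- nrow(iset)
  if (n < 3) stop("RAPS needs at least 3 instruments (got ", n, ")")
  bx <- iset$beta_exp; by <- iset$beta_out
  sx2 <- iset$se_exp^2; sy2 <- iset$se_out^2
  rho <- function(t) {
    if (loss == "l2") t^2 / 2
    else ifelse(abs(t) <= huber_k, t^2 / 2,
                huber_k * abs(t) - huber_k^2 / 2)
  }
  tval <- function(b, tau2) (by - b * bx) / sqrt(sy2 + b^2 * sx2 + tau2)
  b_hat <- sum(bx * by / sy2) / sum(bx^2 / sy2)
  tau2_hat <- 0
  flag <- NULL
  ok <- TRUE
  for (it in 1:100) {
    opt <- tryCatch(
      stats::optim(b_hat, function(b) sum(rho(tval(b, tau2_hat))),
                   method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) { ok <- FALSE; break }
    b_new <- opt$par
    tau2_new <- tau2_hat
    if (overdispersion) {
      mom <- function(t2) sum((by - b_new * bx)^2 /
                                (sy2 + b_new^2 * sx2 + t2)) - (n - 1)
      tau2_new <- if (mom(0) <= 0) 0 else {
        upper <- stats::var(by - b_new * bx) * 10 + 1e-6
        tryCatch(stats::uniroot(mom, c(0, upper))$root,
                 error = function(e) tau2_hat)
      }
    }
    done <- abs(b_new - b_hat) < 1e-12 && abs(tau2_new - tau2_hat) < 1e-14
    b_hat <- b_new
    tau2_hat <- tau2_new
    if (done) break
  }
  if (!ok) flag <- "optimizer failure; returning IVW-like start values"
  # sandwich SE from the profile score sum_j psi(t_j) dt_j/db
  h <- 1e-6 * max(abs(b_hat), 1)
  dt <- (tval(b_hat + h, tau2_hat) - tval(b_hat - h, tau2_hat)) / (2 * h)
  psi <- function(t) {
    if (loss == "l2") t
    else pmin(pmax(t, -huber_k), huber_k)
  }
  t0 <- tval(b_hat, tau2_hat)
  H <- sum(dt^2)
  se <- sqrt(sum((psi(t0) * dt)^2)) / H
  if (!is.finite(se) || se <= 0) {
    v <- sy2 + b_hat^2 * sx2 + tau2_hat
    se <- sqrt(1 / sum(bx^2 / v))
    flag <- c(flag, "score-based SE unavailable; IVW-style SE used")
  }
  res <- .mr_result("RAPS", b_hat, se, n,
                    list(overdispersion = tau2_hat))
  if (!is.null(flag)) res$flag <- paste(flag, collapse = "; ")
  res
}

#' Cochran's Q heterogeneity statistic for an MR fit
#'
#' `Q = sum w_j (bY_j - intercept - beta bX_j)^2` with `w = 1/se_out^2`;
#' df = n - 1 without an intercept (IVW) or n - 2 with one (Egger).
#'
#' @param iset a harmonized `instrument_set`.
#' @param fitted_beta the causal estimate whose residuals to test.
#' @param with_intercept Egger-style (df = n - 2); the intercept is then
#'   re-estimated as the weighted mean residual.
#' @return List: `q`, `df`, `p` (`p` is `NA` with a flag when df <= 0).
#' @export
cochran_q <- function(iset, fitted_beta, with_intercept = FALSE) {
  w <- 1 / iset$se_out^2
  bx <- iset$beta_exp; by <- iset$beta_out
  a <- 0
  if (with_intercept) a <- sum(w * (by - fitted_beta * bx)) / sum(w)
  q <- sum(w * (by - a - fitted_beta * bx)^2)
  df <- nrow(iset) - 1L - as.integer(with_intercept)
  if (df <= 0)
    return(list(q = q, df = df, p = NA_real_,
                flag = "df <= 0: heterogeneity undefined"))
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Steiger directionality filter
#'
#' Per SNP, the variance explained in each trait is approximated by
#' `r2 = z^2 / (z^2 + N)`; instruments explaining no more variance in the
#' exposure than in the outcome likely act in the reverse direction and
#' are flagged for removal.
#'
#' @param iset a harmonized `instrument_set` (needs `n_exp`, `n_out`).
#' @return The instrument set with `r2_exposure`, `r2_outcome`,
#'   `steiger_keep` columns; attribute `filtered` holds the retained
#'   subset.
#' @export
steiger_filter <- function(iset) {
  if (any(is.na(iset$n_exp)) || any(is.na(iset$n_out)))
    stop("per-SNP sample sizes required on both sides for Steiger filtering")
  z_exp <- iset$beta_exp / iset$se_exp
  z_out <- iset$beta_out / iset$se_out
  iset$r2_exposure <- z_exp^2 / (z_exp^2 + iset$n_exp)
  iset$r2_outcome <- z_out^2 / (z_out^2 + iset$n_out)
  iset$steiger_keep <- iset$r2_exposure > iset$r2_outcome
  kept <- iset[iset$steiger_keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "provenance") <- attr(iset, "provenance")
  class(kept) <- c("instrument_set", "data.frame")
  attr(iset, "filtered") <- kept
  iset
}

#' Run all five MR estimators plus diagnostics on one instrument set
#'
#' @param iset a harmonized `instrument_set`.
#' @param seed integer seed for the bootstrap estimators.
#' @param n_boot bootstrap replicates for median/mode SEs.
#' @return List of `mr_result`s (`ivw`, `egger`, `wmedian`, `wmode`,
#'   `raps`) plus `q_ivw` and `q_egger`.
#' @export
mr_all_methods <- function(iset, seed = 1, n_boot = 1000) {
  ivw <- mr_ivw(iset)
  egger <- if (nrow(iset) >= 3) mr_egger(iset) else NULL
  res <- list(
    ivw = ivw,
    egger = egger,
    wmedian = if (nrow(iset) >= 3) mr_weighted_median(iset, n_boot, seed)
    else NULL,
    wmode = if (nrow(iset) >= 3) mr_weighted_mode(iset, 1, n_boot, seed)
    else NULL,
    raps = if (nrow(iset) >= 3) mr_raps(iset) else NULL
  )
  res$q_ivw <- cochran_q(iset, ivw$beta, with_intercept = FALSE)
  res$q_egger <- if (!is.null(egger)) cochran_q(iset, egger$beta,
                                                with_intercept = TRUE)
  else NULL
  res
}

.mr_table_rows <- function(exposure_name, outcome_name, methods) {
  rows <- list()
  for (m in methods) {
    if (is.null(m)) next
    rows[[length(rows) + 1]] <- data.frame(
      exposure = exposure_name, outcome = outcome_name,
      method = m$method, n_snp = m$n_snp,
      beta = m$beta, se = m$se, ci_low = m$ci_low, ci_high = m$ci_high,
      p = m$p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Bidirectional two-sample MR between two summary-statistics tables
#'
#' For each direction: instrument selection with LD clumping, outcome
#' harmonization, optional Steiger directionality filtering, the five
#' estimators, and heterogeneity/pleiotropy diagnostics. A direction
#' without enough instruments is reported as not estimable without
#' blocking the other direction.
#'
#' @param a,b sumstats data frames (names taken from
#'   `attr(., "factor_name")` or the arguments).
#' @param ld_ref LD reference table (see [select_instruments()]).
#' @param p_threshold,window_kb,r2_cap instrument-selection parameters.
#' @param steiger apply Steiger filtering before estimation.
#' @param seed integer seed for bootstrap SEs.
#' @param n_boot bootstrap replicates.
#' @param name_a,name_b labels for the report.
#' @return List of class `bidirectional_mr`: per direction a list with
#'   `status`, `instruments`, `methods`, and a combined results `table`
#'   (one row per method and direction) plus `forest` data
#'   (per-instrument Wald ratios).
#' @export
bidirectional_mr <- function(a, b, ld_ref, p_threshold = 5e-8,
                             window_kb = 10000, r2_cap = 0.001,
                             steiger = TRUE, seed = 1, n_boot = 1000,
                             name_a = "A", name_b = "B") {
  run_direction <- function(exp_tab, out_tab, exp_name, out_name) {
    sel <- select_instruments(exp_tab, ld_ref, p_threshold, window_kb, r2_cap)
    if (attr(sel, "status") == "empty" || nrow(sel) < 2)
      return(list(status = "not estimable: no instruments",
                  instruments = sel, methods = NULL))
    iset <- tryCatch(harmonize_io(sel, out_tab), error = function(e) NULL)
    if (is.null(iset))
      return(list(status = "not estimable: harmonization failed",
                  instruments = sel, methods = NULL))
    if (steiger) {
      flagged <- steiger_filter(iset)
      iset2 <- attr(flagged, "filtered")
      if (nrow(iset2) >= 2) iset <- iset2
    }
    if (nrow(iset) < 10)
      warning("direction ", exp_name, " -> ", out_name, ": only ",
              nrow(iset), " instruments; estimates may be unstable")
    methods <- mr_all_methods(iset, seed = seed, n_boot = n_boot)
    list(status = "ok", instruments = iset, methods = methods)
  }
  fwd <- run_direction(a, b, name_a, name_b)
  rev <- run_direction(b, a, name_b, name_a)
  tab <- rbind(
    if (!is.null(fwd$methods))
      .mr_table_rows(name_a, name_b,
                     fwd$methods[c("ivw", "egger", "wmedian", "wmode", "raps")]),
    if (!is.null(rev$methods))
      .mr_table_rows(name_b, name_a,
                     rev$methods[c("ivw", "egger", "wmedian", "wmode", "raps")])
  )
  forest <- function(dirres, en, on) {
    if (is.null(dirres$methods)) return(NULL)
    is <- dirres$instruments
    data.frame(exposure = en, outcome = on, snp = is$snp,
               ratio = is$beta_out / is$beta_exp,
               se = sqrt(is$se_out^2 / is$beta_exp^2 +
                           is$beta_out^2 * is$se_exp^2 / is$beta_exp^4),
               stringsAsFactors = FALSE)
  }
  structure(list(forward = fwd, reverse = rev, table = tab,
                 forest = rbind(forest(fwd, name_a, name_b),
                                forest(rev, name_b, name_a)),
                 name_a = name_a, name_b = name_b),
            class = "bidirectional_mr")
}

#' @export
print.bidirectional_mr <- function(x, ...) {
  cat("Bidirectional MR:", x$name_a, "<->", x$name_b, "\n")
  if (!is.null(x$table))
    print(x$table, digits = 3, row.names = FALSE)
  else cat("  no direction estimable\n")
  invisible(x)
}
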