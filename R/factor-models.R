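# Genomic factor analysis on LDSC covariance matrices.
#
# Models are fit to the genetic covariance matrix S by diagonally weighted
# least squares (DWLS): minimize (s - sigma(theta))' D^-1 (s - sigma(theta))
# with D = diag(V), where s = vech(S) and V is the block-jackknife sampling
# covariance of s. Standard errors are sandwich estimates using the full V;
# the model chi-square is the residual-based statistic
# e' U^+ e, U = (I - P) V (I - P)', which is exactly zero for a saturated
# model and asymptotically chi-square with p(p+1)/2 - n_free df.

#' Nearest positive-definite smoothing of a covariance matrix
#'
#' Eigenvalue clipping at `eps` followed by rescaling to preserve the
#' original diagonal. Positive-definite input is returned unchanged.
#'
#' @param S symmetric matrix.
#' @param eps smallest permitted eigenvalue.
#' @return Smoothed matrix; attribute `max_change` records the largest
#'   elementwise absolute change.
#' @export
smooth_to_pd <- function(S, eps = 1e-6) {
  if (!isSymmetric(unname(S), tol = 1e-8)) stop("input must be symmetric")
  if (min(eigen((S + t(S)) / 2, symmetric = TRUE,
                only.values = TRUE)$values) >= eps) {
    attr(S, "max_change") <- 0
    return(S)
  }
  d_old <- diag(S)
  S3 <- (S + t(S)) / 2
  # clip-and-rescale can undo each other slightly; iterate to a fixpoint
  for (it in 1:50) {
    ev <- eigen(S3, symmetric = TRUE)
    if (min(ev$values) >= eps * (1 - 1e-6)) break
    S3 <- ev$vectors %*% (pmax(ev$values, eps) * t(ev$vectors))
    d_new <- diag(S3)
    ok <- d_old > 0 & d_new > 0
    scale <- rep(1, length(d_old))
    scale[ok] <- sqrt(d_old[ok] / d_new[ok])
    S3 <- S3 * outer(scale, scale)
  }
  dimnames(S3) <- dimnames(S)
  attr(S3, "max_change") <- max(abs(S3 - S))
  S3
}

#' PCA scree of a genetic covariance matrix with Kaiser's criterion
#'
#' Eigen-decomposes the smoothed correlation-scale matrix and counts
#' components with eigenvalue strictly greater than one.
#'
#' @param gc a `genetic_covariance` (warns unless `subset == "odd_chr"`,
#'   the overfitting-avoidance convention) or a plain covariance matrix.
#' @return List: `eigenvalues`, `var_explained`, `n_retained`, `scree`
#'   (data frame for plotting).
#' @export
pca_scree <- function(gc) {
  S <- if (inherits(gc, "genetic_covariance")) {
    if (gc$subset != "odd_chr")
      warning("PCA/EFA are conventionally run on the odd-chromosome subset; ",
              "got '", gc$subset, "'")
    gc$S
  } else as.matrix(gc)
  if (any(!is.finite(S))) stop("non-finite entries in S")
  R <- stats::cov2cor(smooth_to_pd(S))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  list(eigenvalues = ev,
       var_explained = ev / length(ev),
       n_retained = sum(ev > 1),
       scree = data.frame(component = seq_along(ev), eigenvalue = ev))
}

#' Exploratory factor analysis of a genetic covariance matrix
#'
#' Maximum-likelihood factor extraction on the smoothed correlation-scale
#' matrix followed by oblique (promax) rotation; factor correlations are
#' derived from the rotation matrix and the loading pattern thresholded at
#' `salience` to propose a confirmatory structure.
#'
#' @param gc a `genetic_covariance` or plain covariance matrix.
#' @param n_factors number of factors to extract.
#' @param rotation `"promax"` (oblique, default) or `"none"`.
#' @param salience absolute loading threshold for the proposed pattern.
#' @return List: `loadings`, `factor_corr`, `var_explained` (per factor),
#'   `total_var_explained`, `pattern` (logical), `heywood` flag.
#' @export
efa_fit <- function(gc, n_factors, rotation = c("promax", "none"),
                    salience = 0.25) {
  rotation <- match.arg(rotation)
  S <- if (inherits(gc, "genetic_covariance")) gc$S else as.matrix(gc)
  R <- stats::cov2cor(smooth_to_pd(S))
  k <- ncol(R)
  if (n_factors < 1) stop("n_factors must be >= 1")
  if (n_factors >= k)
    stop("n_factors must be smaller than the number of traits")
  fa <- stats::factanal(covmat = R, factors = n_factors, rotation = "none")
  L <- unclass(fa$loadings)
  Phi <- diag(n_factors)
  if (rotation == "promax" && n_factors > 1) {
    pro <- stats::promax(L)
    L <- unclass(pro$loadings)
    U <- pro$rotmat
    Phi_raw <- solve(crossprod(U))
    d <- sqrt(diag(Phi_raw))
    Phi <- Phi_raw / outer(d, d)
    L <- sweep(L, 2, d, `*`)  # keep L Phi L' invariant after renormalizing
  }
  heywood <- any(fa$uniquenesses <= 0.005 + 1e-12)
  if (heywood)
    warning("Heywood case: communality at or above 1 for some trait(s)")
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(n_factors))
  dimnames(Phi) <- list(colnames(L), colnames(L))
  ve <- colSums(L^2) / k
  list(loadings = L, factor_corr = Phi, var_explained = ve,
       total_var_explained = sum(ve), pattern = abs(L) >= salience,
       heywood = heywood)
}

# ---------------------------------------------------------------------------
# Model specification parser
#
# A small declarative syntax, one statement per line (or ';'-separated):
#   F1 =~ x1 + x2 + 0.5*x3     measurement (fixed loading via value*name)
#   LONE =~ 1*lone             single-indicator latent, marker loading
#   LONE ~ F1 + 0*F2           structural regression (fixed path via value*)
#   F1 ~~ F2                   free (co)variance; value* fixes it
#   lone ~~ 0*lone             fixed observed residual
# Identification defaults: exogenous latents without a fixed marker loading
# get unit variance; marker-identified and endogenous latents get a free
# (disturbance) variance; exogenous factor covariances are free.

#' Parse a factor-model specification
#'
#' @param text model syntax (see Details in [cfa_fit()]).
#' @param traits character vector of observed variable names available.
#' @return An object of class `factor_model_spec`.
#' @export
parse_model <- function(text, traits) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "[\n;]"))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parse_term <- function(term) {
    term <- trimws(term)
    m <- regmatches(term, regexec("^([-+]?[0-9.]+(?:[eE][-+]?[0-9]+)?)\\*(.+)$",
                                  term))[[1]]
    if (length(m) == 3) list(name = trimws(m[3]), fixed = as.numeric(m[2]))
    else list(name = term, fixed = NA_real_)
  }
  stmts <- list()
  for (ln in lines) {
    op <- if (grepl("=~", ln, fixed = TRUE)) "=~"
    else if (grepl("~~", ln, fixed = TRUE)) "~~"
    else if (grepl("~", ln, fixed = TRUE)) "~"
    else stop("cannot parse model line: ", ln)
    parts <- strsplit(ln, op, fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("cannot parse model line: ", ln)
    lhs <- trimws(parts[1])
    rhs <- lapply(strsplit(parts[2], "+", fixed = TRUE)[[1]], parse_term)
    stmts[[length(stmts) + 1]] <- list(op = op, lhs = lhs, rhs = rhs)
  }
  latents <- unique(vapply(stmts[vapply(stmts, function(s) s$op == "=~",
                                        TRUE)], `[[`, "", "lhs"))
  observed <- unique(unlist(lapply(stmts, function(s) {
    if (s$op != "=~") return(NULL)
    vapply(s$rhs, `[[`, "", "name")
  })))
  unknown <- setdiff(observed, traits)
  if (length(unknown))
    stop("indicator(s) not among available traits: ",
         paste(unknown, collapse = ", "))
  m <- length(latents); p <- length(observed)
  if (m == 0) stop("model defines no latent factors")
  # templates: NA value = free, number = fixed
  Lam <- matrix(0, p, m, dimnames = list(observed, latents))
  Bmat <- matrix(0, m, m, dimnames = list(latents, latents))
  Psi <- matrix(0, m, m, dimnames = list(latents, latents))
  Theta <- matrix(0, p, p, dimnames = list(observed, observed))
  free_lam <- matrix(FALSE, p, m); free_B <- matrix(FALSE, m, m)
  free_psi <- matrix(FALSE, m, m); free_theta <- matrix(FALSE, p, p)
  psi_explicit <- matrix(FALSE, m, m); theta_explicit <- matrix(FALSE, p, p)
  marker <- rep(FALSE, m)
  for (s in stmts) {
    if (s$op == "=~") {
      f <- match(s$lhs, latents)
      for (tm in s$rhs) {
        i <- match(tm$name, observed)
        if (is.na(tm$fixed)) free_lam[i, f] <- TRUE
        else {
          Lam[i, f] <- tm$fixed
          if (tm$fixed != 0) marker[f] <- TRUE
        }
      }
    } else if (s$op == "~") {
      if (!(s$lhs %in% latents))
        stop("regression target must be a latent factor: ", s$lhs,
             " (wrap observed variables in a single-indicator latent)")
      j <- match(s$lhs, latents)
      for (tm in s$rhs) {
        if (!(tm$name %in% latents))
          stop("regression predictor must be a latent factor: ", tm$name)
        kdx <- match(tm$name, latents)
        if (is.na(tm$fixed)) free_B[j, kdx] <- TRUE
        else Bmat[j, kdx] <- tm$fixed
      }
    } else {  # ~~
      a <- s$lhs
      for (tm in s$rhs) {
        b <- tm$name
        if (a %in% latents && b %in% latents) {
          i <- match(a, latents); j <- match(b, latents)
          psi_explicit[i, j] <- psi_explicit[j, i] <- TRUE
          if (is.na(tm$fixed)) free_psi[i, j] <- free_psi[j, i] <- TRUE
          else Psi[i, j] <- Psi[j, i] <- tm$fixed
        } else if (a %in% observed && b %in% observed) {
          i <- match(a, observed); j <- match(b, observed)
          theta_explicit[i, j] <- theta_explicit[j, i] <- TRUE
          if (is.na(tm$fixed)) free_theta[i, j] <- free_theta[j, i] <- TRUE
          else Theta[i, j] <- Theta[j, i] <- tm$fixed
        } else stop("covariance between a latent and an observed variable ",
                    "is not supported: ", a, " ~~ ", b)
      }
    }
  }
  endogenous <- rowSums(free_B | Bmat != 0) > 0
  for (f in seq_len(m)) {
    if (psi_explicit[f, f]) next
    if (endogenous[f] || marker[f]) free_psi[f, f] <- TRUE  # free (dist.) var
    else Psi[f, f] <- 1                                     # unit variance
  }
  exo <- which(!endogenous)
  if (length(exo) > 1) {
    for (a in exo) for (b in exo) if (a < b && !psi_explicit[a, b])
      free_psi[a, b] <- free_psi[b, a] <- TRUE
  }
  for (i in seq_len(p)) if (!theta_explicit[i, i]) free_theta[i, i] <- TRUE
  n_free <- sum(free_lam) + sum(free_B) +
    sum(free_psi[upper.tri(free_psi, diag = TRUE)]) +
    sum(free_theta[upper.tri(free_theta, diag = TRUE)])
  df <- p * (p + 1) / 2 - n_free
  if (df < 0)
    stop("model is not identified: ", n_free, " free parameters for ",
         p * (p + 1) / 2, " unique covariance elements")
  structure(list(latents = latents, observed = observed,
                 Lam = Lam, B = Bmat, Psi = Psi, Theta = Theta,
                 free_lam = free_lam, free_B = free_B, free_psi = free_psi,
                 free_theta = free_theta, n_free = n_free, df = df),
            class = "factor_model_spec")
}

#' @export
print.factor_model_spec <- function(x, ...) {
  cat("Factor model:", length(x$latents), "latent(s),",
      length(x$observed), "indicator(s),", x$n_free, "free parameter(s), df =",
      x$df, "\n")
  invisible(x)
}

# free-parameter bookkeeping: data frame of (matrix, i, j, label)
.param_table <- function(spec) {
  out <- list()
  add <- function(mat, i, j, label, type)
    out[[length(out) + 1]] <<- data.frame(mat = mat, i = i, j = j,
                                          label = label, type = type,
                                          stringsAsFactors = FALSE)
  for (f in seq_along(spec$latents)) for (i in seq_along(spec$observed))
    if (spec$free_lam[i, f])
      add("lam", i, f, paste0(spec$latents[f], "=~", spec$observed[i]),
          "loading")
  for (j in seq_along(spec$latents)) for (kk in seq_along(spec$latents))
    if (spec$free_B[j, kk])
      add("B", j, kk, paste0(spec$latents[j], "~", spec$latents[kk]), "beta")
  for (i in seq_along(spec$latents)) for (j in seq_along(spec$latents))
    if (i <= j && spec$free_psi[i, j])
      add("psi", i, j, paste0(spec$latents[i], "~~", spec$latents[j]),
          if (i == j) "factor_var" else "factor_cov")
  for (i in seq_along(spec$observed)) for (j in seq_along(spec$observed))
    if (i <= j && spec$free_theta[i, j])
      add("theta", i, j, paste0(spec$observed[i], "~~", spec$observed[j]),
          if (i == j) "residual" else "residual_cov")
  do.call(rbind, out)
}

.fill_matrices <- function(spec, theta, ptab) {
  Lam <- spec$Lam; B <- spec$B; Psi <- spec$Psi; Th <- spec$Theta
  for (r in seq_len(nrow(ptab))) {
    v <- theta[r]; i <- ptab$i[r]; j <- ptab$j[r]
    switch(ptab$mat[r],
           lam = { Lam[i, j] <- v },
           B = { B[i, j] <- v },
           psi = { Psi[i, j] <- v; Psi[j, i] <- v },
           theta = { Th[i, j] <- v; Th[j, i] <- v })
  }
  list(Lam = Lam, B = B, Psi = Psi, Theta = Th)
}

.implied_sigma <- function(mats) {
  m <- ncol(mats$Lam)
  IB <- diag(m) - mats$B
  IBi <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(IBi)) return(NULL)
  Seta <- IBi %*% mats$Psi %*% t(IBi)
  mats$Lam %*% Seta %*% t(mats$Lam) + mats$Theta
}

.vech <- function(M) M[lower.tri(M, diag = TRUE)]

# subset a genetic_covariance to a trait subset (S, V, delete, intercepts)
#' Restrict a genetic covariance object to a subset of traits
#' @param gc a `genetic_covariance`.
#' @param traits trait names to keep (order respected).
#' @return A `genetic_covariance` on the subset.
#' @export
subset_gc <- function(gc, traits) {
  idx <- match(traits, gc$traits)
  if (anyNA(idx)) stop("unknown trait(s): ",
                       paste(traits[is.na(idx)], collapse = ", "))
  k_new <- length(idx)
  pairs_new <- .vech_pairs(k_new)
  old_col <- function(i, j) {
    a <- max(idx[i], idx[j]); b <- min(idx[i], idx[j])
    which(gc$vech_pairs[, "i"] == a & gc$vech_pairs[, "j"] == b)
  }
  cols <- mapply(old_col, pairs_new[, "i"], pairs_new[, "j"])
  structure(list(traits = traits,
                 S = gc$S[idx, idx, drop = FALSE],
                 V = gc$V[cols, cols, drop = FALSE],
                 intercepts = gc$intercepts[idx, idx, drop = FALSE],
                 n_blocks = gc$n_blocks, subset = gc$subset,
                 delete = gc$delete[, cols, drop = FALSE],
                 M = gc$M, vech_pairs = pairs_new),
            class = "genetic_covariance")
}

# Moore-Penrose pseudoinverse keeping the top `rank` eigenvalues
.pinv_rank <- function(M, rank) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (rank <= 0) return(matrix(0, nrow(M), ncol(M)))
  keep <- seq_len(min(rank, ncol(M)))
  lam <- ev$values[keep]
  lam[lam < 1e-14 * max(abs(ev$values))] <- Inf  # effectively zero directions
  ev$vectors[, keep, drop = FALSE] %*%
    ((1 / lam) * t(ev$vectors[, keep, drop = FALSE]))
}

#' Fit a confirmatory / structural factor model by DWLS
#'
#' Minimizes the diagonally weighted least-squares discrepancy between the
#' model-implied covariance and the (smoothed) genetic covariance matrix,
#' with weights `1/diag(V)`. Sandwich standard errors use the full
#' sampling covariance V; the chi-square is the residual-based statistic
#' (exactly zero for a saturated model). Three quasi-Newton starts (one
#' default, two jittered under fixed seeds) guard against local minima.
#'
#' @param gc a `genetic_covariance` (will be subset to the indicators
#'   named in the model and PD-smoothed).
#' @param spec a `factor_model_spec` from [parse_model()], or model syntax
#'   text.
#' @param max_iter maximum optimizer iterations.
#' @return An object of class `gsem_fit`: parameter table with estimates,
#'   sandwich SEs, z and p; model matrices; implied covariance;
#'   standardized solution; fit indices (`chi2`, `df`, `p`, `srmr`,
#'   `cfi`); `converged`; `n_iterations`.
#' @export
cfa_fit <- function(gc, spec, max_iter = 1000) {
  if (is.character(spec)) spec <- parse_model(spec, gc$traits)
  gcs <- subset_gc(gc, spec$observed)
  S <- smooth_to_pd(gcs$S)
  V <- gcs$V
  s <- .vech(S)
  D <- pmax(diag(V), 1e-12)
  ptab <- .param_table(spec)
  n_free <- nrow(ptab)
  # scale-aware starting values
  sdg <- sqrt(pmax(diag(S), 1e-4))
  start <- numeric(n_free)
  for (r in seq_len(n_free)) {
    start[r] <- switch(ptab$type[r],
                       loading = 0.7 * sdg[ptab$i[r]],
                       beta = 0,
                       factor_var = 0.5,
                       factor_cov = 0.2,
                       residual = 0.5 * diag(S)[ptab$i[r]],
                       residual_cov = 0)
  }
  objective <- function(theta) {
    mats <- .fill_matrices(spec, theta, ptab)
    Sig <- .implied_sigma(mats)
    if (is.null(Sig) || any(!is.finite(Sig))) return(1e10)
    r <- s - .vech(Sig)
    sum(r^2 / D)
  }
  best <- NULL
  starts <- list(start)
  for (js in 1:2) {
    set.seed(1000 + js)
    starts[[js + 1]] <- start * (1 + 0.25 * stats::rnorm(n_free)) +
      0.05 * stats::rnorm(n_free)
  }
  struct_idx <- ptab$mat %in% c("lam", "B")
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, objective, method = "BFGS",
                   control = list(maxit = max_iter, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(opt)) next
    opt$snorm <- sum(opt$par[struct_idx]^2)
    # near-ties (flat ridges of equally fitting solutions) are broken
    # toward the smallest structural-parameter norm
    tie_tol <- 1e-7 * max(1, abs(opt$value))
    if (is.null(best) || opt$value < best$value - tie_tol ||
        (abs(opt$value - best$value) <= tie_tol && opt$snorm < best$snorm))
      best <- opt
  }
  if (is.null(best)) stop("optimization failed from every start")
  theta_hat <- best$par
  sig_fun <- function(theta) {
    m2 <- .fill_matrices(spec, theta, ptab)
    .vech(.implied_sigma(m2))
  }
  W <- 1 / D
  # Gauss-Newton polish: drives the DWLS gradient to machine precision so
  # just-identified models reproduce S exactly
  f_cur <- objective(theta_hat)
  for (it in 1:20) {
    Dl <- pracma::jacobian(sig_fun, theta_hat)
    r <- s - sig_fun(theta_hat)
    A <- crossprod(Dl, Dl * W)
    step <- tryCatch(solve(A, crossprod(Dl * W, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    cand <- theta_hat + as.numeric(step)
    f_new <- objective(cand)
    # strict-improvement rule: never drift along flat (unidentified) ridges
    if (!is.finite(f_new) || f_cur - f_new <= 1e-15) break
    theta_hat <- cand
    f_cur <- f_new
    if (max(abs(step)) < 1e-12) break
  }
  # canonicalize factor signs: largest-|loading| per factor made positive
  mats0 <- .fill_matrices(spec, theta_hat, ptab)
  flip <- rep(FALSE, length(spec$latents))
  for (f in seq_along(spec$latents)) {
    col <- mats0$Lam[, f]
    if (all(col == 0)) next
    if (any(spec$Lam[, f] != 0)) next  # fixed nonzero loading pins the sign
    if (col[which.max(abs(col))] < 0) flip[f] <- TRUE
  }
  if (any(flip)) {
    for (r in seq_len(nrow(ptab))) {
      i <- ptab$i[r]; j <- ptab$j[r]
      do_flip <- switch(ptab$mat[r],
                        lam = flip[j],
                        B = xor(flip[i], flip[j]),
                        psi = i != j && xor(flip[i], flip[j]),
                        theta = FALSE)
      if (do_flip) theta_hat[r] <- -theta_hat[r]
    }
  }
  grad_norm <- tryCatch(max(abs(pracma::grad(objective, theta_hat))),
                        error = function(e) NA_real_)
  converged <- best$convergence == 0 ||
    (is.finite(grad_norm) && grad_norm < 1e-5)
  mats <- .fill_matrices(spec, theta_hat, ptab)
  Sig <- .implied_sigma(mats)
  resid <- s - .vech(Sig)
  # sandwich covariance of theta_hat
  Delta <- pracma::jacobian(sig_fun, theta_hat)
  A <- crossprod(Delta, Delta * W)
  Ainv <- tryCatch(solve(A), error = function(e) MASS::ginv(A))
  mid <- crossprod(Delta * W, V %*% (Delta * W))
  Vtheta <- Ainv %*% mid %*% Ainv
  se <- sqrt(pmax(diag(Vtheta), 0))
  ptab$est <- theta_hat
  ptab$se <- se
  ptab$z <- ifelse(se > 0, theta_hat / se, NA_real_)
  ptab$p <- 2 * stats::pnorm(-abs(ptab$z))
  # residual-based chi-square
  df <- spec$df
  if (df > 0) {
    P <- Delta %*% Ainv %*% t(Delta * W)
    IP <- diag(length(s)) - P
    U <- IP %*% V %*% t(IP)
    chi2 <- max(0, as.numeric(resid %*% .pinv_rank(U, df) %*% resid))
    p_chi2 <- stats::pchisq(chi2, df, lower.tail = FALSE)
  } else {
    chi2 <- 0; p_chi2 <- NA_real_
  }
  # standardized solution
  m <- length(spec$latents)
  IBi <- solve(diag(m) - mats$B)
  Seta <- IBi %*% mats$Psi %*% t(IBi)
  sd_eta <- sqrt(pmax(diag(Seta), 1e-12))
  sd_y <- sqrt(pmax(diag(Sig), 1e-12))
  std <- ptab
  for (r in seq_len(nrow(std))) {
    i <- std$i[r]; j <- std$j[r]
    std$est[r] <- switch(std$mat[r],
      lam = mats$Lam[i, j] * sd_eta[j] / sd_y[i],
      B = mats$B[i, j] * sd_eta[j] / sd_eta[i],
      psi = mats$Psi[i, j] / (sd_eta[i] * sd_eta[j]),
      theta = mats$Theta[i, j] / (sd_y[i] * sd_y[j]))
    std$se[r] <- std$se[r] * abs(std$est[r] /
                                   ifelse(ptab$est[r] != 0, ptab$est[r], 1))
  }
  fit <- structure(list(
    spec = spec, params = ptab, std_params = std,
    matrices = mats, implied = Sig, S = S, V = V,
    chi2 = chi2, df = df, p = p_chi2,
    srmr = NA_real_, cfi = NA_real_,
    converged = converged, n_iterations = best$counts[["function"]],
    objective = best$value, grad_norm = grad_norm,
    Delta = Delta, D = D
  ), class = "gsem_fit")
  fi <- fit_indices(fit, gcs)
  fit$srmr <- fi$srmr
  fit$cfi <- fi$cfi
  fit$cfi_flag <- fi$cfi_flag
  fit
}

#' @export
print.gsem_fit <- function(x, ...) {
  cat("DWLS factor model fit (", ifelse(x$converged, "converged",
                                        "NOT converged"), ")\n", sep = "")
  cat(sprintf("  chi2(%d) = %.3f, p = %.3g, SRMR = %.4f, CFI = %.4f\n",
              x$df, x$chi2, x$p, x$srmr, x$cfi))
  print(x$params[, c("label", "est", "se", "z", "p")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' Fit indices for a DWLS factor model
#'
#' Chi-square (residual-based, V-weighted), SRMR (root mean square of
#' correlation-scale residuals over unique elements including the
#' diagonal) and CFI against the no-covariance baseline model, whose
#' chi-square has closed form because the baseline reproduces the
#' diagonal exactly.
#'
#' @param fit a `gsem_fit`.
#' @param gc the `genetic_covariance` it was fit to (any superset of its
#'   indicators).
#' @return List: `chi2`, `df`, `p`, `srmr`, `cfi`, `cfi_flag`.
#' @export
fit_indices <- function(fit, gc) {
  if (!fit$converged)
    warning("fit indices computed on a non-converged fit")
  gcs <- if (identical(gc$traits, fit$spec$observed)) gc
  else subset_gc(gc, fit$spec$observed)
  S <- fit$S
  Sig <- fit$implied
  dS <- sqrt(diag(S))
  res_std <- (S - Sig) / outer(dS, dS)
  srmr <- sqrt(mean(.vech(res_std)^2))
  # baseline: implied = diag(diag(S)); off-diagonal residuals vs their V
  p <- ncol(S)
  off <- which(.vech(row(S)) != .vech(col(S)))
  e_off <- .vech(S)[off]
  V_off <- gcs$V[off, off, drop = FALSE]
  chi2_b <- tryCatch(as.numeric(e_off %*% solve(V_off, e_off)),
                     error = function(e)
                       as.numeric(e_off %*% MASS::ginv(V_off) %*% e_off))
  df_b <- p * (p + 1) / 2 - p
  cfi_flag <- NULL
  num <- max(fit$chi2 - fit$df, 0)
  den <- chi2_b - df_b
  if (den <= 0) {
    cfi <- 1
    cfi_flag <- "baseline chi2 <= its df; CFI reported as 1"
  } else {
    cfi <- 1 - num / den
  }
  list(chi2 = fit$chi2, df = fit$df, p = fit$p, srmr = srmr, cfi = cfi,
       cfi_flag = cfi_flag)
}

#' The three structural models regressing a single-indicator loneliness
#' factor on latent psychopathology factors
#'
#' Model 1 ("unadjusted"): a separate bivariate regression of the
#' loneliness latent on each factor. Model 2 ("adjusted"): a joint
#' regression on all factors with free factor intercorrelations, whose
#' paths are partial genetic correlations. Model 3 ("constrained"):
#' model 2 with the paths from all but `keep_factor` fixed to zero, a
#' guard against multicollinearity-driven sign reversal (the reversal
#' paradox) among highly intercorrelated factors.
#'
#' The loneliness trait is wrapped in a single-indicator latent with its
#' loading fixed to 1 and its indicator residual fixed to 0.
#'
#' @param gc a `genetic_covariance` including the loneliness trait and all
#'   indicators.
#' @param factors named list mapping factor names to indicator trait
#'   vectors.
#' @param loneliness_trait name of the loneliness trait in `gc`.
#' @param keep_factor the factor whose path stays free in model 3.
#' @return List of class `loneliness_models`: `unadjusted` (list of
#'   per-factor `gsem_fit`s), `adjusted`, `constrained`.
#' @export
loneliness_models <- function(gc, factors, loneliness_trait,
                              keep_factor = names(factors)[1]) {
  stopifnot(loneliness_trait %in% gc$traits,
            keep_factor %in% names(factors))
  meas <- vapply(names(factors), function(f)
    paste0(f, " =~ ", paste(factors[[f]], collapse = " + ")), "")
  lone <- c(paste0("LONE =~ 1*", loneliness_trait),
            paste0(loneliness_trait, " ~~ 0*", loneliness_trait))
  unadjusted <- lapply(names(factors), function(f) {
    txt <- c(meas[[f]], lone, paste0("LONE ~ ", f))
    cfa_fit(gc, paste(txt, collapse = "\n"))
  })
  names(unadjusted) <- names(factors)
  adj_txt <- c(meas, lone,
               paste0("LONE ~ ", paste(names(factors), collapse = " + ")))
  adjusted <- cfa_fit(gc, paste(adj_txt, collapse = "\n"))
  con_terms <- vapply(names(factors), function(f)
    if (f == keep_factor) f else paste0("0*", f), "")
  con_txt <- c(meas, lone, paste0("LONE ~ ", paste(con_terms, collapse = " + ")))
  constrained <- cfa_fit(gc, paste(con_txt, collapse = "\n"))
  structure(list(unadjusted = unadjusted, adjusted = adjusted,
                 constrained = constrained, keep_factor = keep_factor),
            class = "loneliness_models")
}

#' @export
print.loneliness_models <- function(x, ...) {
  get_beta <- function(fit, f) {
    r <- fit$params[fit$params$label == paste0("LONE~", f), ]
    if (nrow(r) == 0) return(c(NA, NA))
    c(r$est, r$se)
  }
  cat("Structural models for the loneliness latent factor\n")
  for (f in names(x$unadjusted)) {
    b <- get_beta(x$unadjusted[[f]], f)
    cat(sprintf("  unadjusted  LONE ~ %-6s beta = %6.3f (SE %.3f)\n",
                f, b[1], b[2]))
  }
  for (f in names(x$unadjusted)) {
    b <- get_beta(x$adjusted, f)
    if (!is.na(b[1]))
      cat(sprintf("  adjusted    LONE ~ %-6s beta = %6.3f (SE %.3f)\n",
                  f, b[1], b[2]))
  }
  b <- get_beta(x$constrained, x$keep_factor)
  cat(sprintf("  constrained LONE ~ %-6s beta = %6.3f (SE %.3f)\n",
              x$keep_factor, b[1], b[2]))
  invisible(x)
}
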