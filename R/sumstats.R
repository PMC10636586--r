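#' Read GWAS summary statistics from a delimited text file
#'
#' Maps arbitrary column names onto the internal convention
#' `SNP, CHR, BP, A1, A2, BETA, SE, P, N, INFO, FRQ`, upper-cases alleles,
#' drops rows with unparseable or invalid numerics (SE <= 0, P outside
#' (0, 1]) with a logged count, and derives the Z-score.
#'
#' @param path file path (TSV or other separator readable by
#'   [utils::read.delim()]).
#' @param column_map named character vector mapping internal names to file
#'   column names, e.g. `c(SNP = "rsid", BETA = "or", ...)`. Identity
#'   mapping by default. Use `or_to_beta = TRUE` if the effect column holds
#'   odds ratios.
#' @param or_to_beta if `TRUE`, effect sizes are log-transformed
#'   (`beta = ln(OR)`).
#' @param sep field separator.
#' @return A `sumstats` data frame with lower-case internal columns
#'   `snp, chr, bp, a1, a2, beta, se, p, n, info, frq, z`. Attributes
#'   `n_dropped` records discarded rows.
#' @export
read_sumstats <- function(path, column_map = NULL, or_to_beta = FALSE,
                          sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  std <- c(SNP = "SNP", CHR = "CHR", BP = "BP", A1 = "A1", A2 = "A2",
           BETA = "BETA", SE = "SE", P = "P", N = "N", INFO = "INFO",
           FRQ = "FRQ")
  if (!is.null(column_map)) std[names(column_map)] <- column_map
  mandatory <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "N")
  for (m in mandatory) {
    if (!(std[[m]] %in% names(raw)))
      stop("mandatory column missing from ", path, ": ", m,
           " (mapped to '", std[[m]], "')")
  }
  get <- function(m) if (std[[m]] %in% names(raw)) raw[[std[[m]]]] else NA
  tab <- data.frame(
    snp = as.character(get("SNP")),
    chr = suppressWarnings(as.integer(get("CHR"))),
    bp = suppressWarnings(as.numeric(get("BP"))),
    a1 = toupper(as.character(get("A1"))),
    a2 = toupper(as.character(get("A2"))),
    beta = suppressWarnings(as.numeric(get("BETA"))),
    se = suppressWarnings(as.numeric(get("SE"))),
    p = suppressWarnings(as.numeric(get("P"))),
    n = suppressWarnings(as.numeric(get("N"))),
    info = suppressWarnings(as.numeric(get("INFO"))),
    frq = suppressWarnings(as.numeric(get("FRQ"))),
    stringsAsFactors = FALSE
  )
  if (or_to_beta) tab$beta <- log(tab$beta)
  bad <- !is.finite(tab$beta) | !is.finite(tab$se) | tab$se <= 0 |
    !is.finite(tab$p) | tab$p <= 0 | tab$p > 1 | !is.finite(tab$n) |
    is.na(tab$snp) | tab$a1 == tab$a2
  n_dropped <- sum(bad)
  if (n_dropped > 0)
    message("read_sumstats: dropped ", n_dropped, " invalid row(s) from ",
            basename(path))
  tab <- tab[!bad, , drop = FALSE]
  if (nrow(tab) == 0) stop("no valid rows in ", path)
  if (anyDuplicated(tab$snp))
    stop("duplicate SNP ids in ", path)
  tab$z <- tab$beta / tab$se
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- n_dropped
  class(tab) <- c("sumstats", "data.frame")
  tab
}

#' Standard GWAS quality-control filter
#'
#' Retains rows with imputation INFO strictly above `info_min` and minor
#' allele frequency strictly above `maf_min`. A missing INFO or FRQ column
#' skips that filter with a warning.
#'
#' @param t a sumstats data frame.
#' @param info_min minimum imputation quality (exclusive).
#' @param maf_min minimum minor allele frequency (exclusive).
#' @return Filtered sumstats; attribute `n_removed` records the count.
#' @export
qc_filter <- function(t, info_min = 0.9, maf_min = 0.01) {
  keep <- rep(TRUE, nrow(t))
  if (all(is.na(t$info))) {
    warning("INFO column absent; skipping imputation-quality filter")
  } else {
    keep <- keep & t$info > info_min
  }
  if (all(is.na(t$frq))) {
    warning("FRQ column absent; skipping MAF filter")
  } else {
    keep <- keep & pmin(t$frq, 1 - t$frq) > maf_min
  }
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Effective sample size for a case-control GWAS
#'
#' `4 / (1/n_cases + 1/n_controls)`: the balanced-design equivalent N, the
#' scale on which binary-trait sample sizes enter every downstream
#' computation.
#'
#' @param n_cases,n_controls case and control counts (> 0).
#' @return Effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Align multiple summary-statistics tables on a common SNP set
#'
#' Restricts all tables to the SNP intersection, aligns effect alleles to
#' the first table (flipping beta and frq when a1/a2 are swapped), drops
#' strand-ambiguous palindromic SNPs (A/T, C/G) and SNPs whose allele
#' pairs cannot be reconciled, logging counts.
#'
#' @param tables list of >= 2 sumstats data frames.
#' @return Named list of aligned sumstats on identical SNPs in identical
#'   order; attribute `log` records drop counts.
#' @export
harmonize_panels <- function(tables) {
  if (length(tables) < 2) stop("need at least two tables to harmonize")
  if (is.null(names(tables)))
    names(tables) <- paste0("trait", seq_along(tables))
  common <- Reduce(intersect, lapply(tables, function(t) t$snp))
  if (length(common) == 0) stop("empty SNP intersection across tables")
  tables <- lapply(tables, function(t) {
    t <- t[match(common, t$snp), , drop = FALSE]
    rownames(t) <- NULL
    t
  })
  ref <- tables[[1]]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- ref$a2 == comp[ref$a1]
  n_mismatch <- 0L
  for (j in seq_along(tables)[-1]) {
    t <- tables[[j]]
    same <- t$a1 == ref$a1 & t$a2 == ref$a2
    swapped <- t$a1 == ref$a2 & t$a2 == ref$a1
    # allow strand-flipped annotation for non-palindromic SNPs
    flip_same <- t$a1 == comp[ref$a1] & t$a2 == comp[ref$a2] & !palindromic
    flip_swap <- t$a1 == comp[ref$a2] & t$a2 == comp[ref$a1] & !palindromic
    do_swap <- (swapped | flip_swap) & !same & !flip_same
    ok <- same | swapped | flip_same | flip_swap
    t$beta[do_swap] <- -t$beta[do_swap]
    t$z[do_swap] <- -t$z[do_swap]
    t$frq[do_swap] <- 1 - t$frq[do_swap]
    t$a1 <- ref$a1
    t$a2 <- ref$a2
    n_mismatch <- n_mismatch + sum(!ok)
    t$.ok <- ok
    tables[[j]] <- t
  }
  keep <- !palindromic
  for (j in seq_along(tables)[-1]) {
    keep <- keep & tables[[j]]$.ok
    tables[[j]]$.ok <- NULL
  }
  n_palin <- sum(palindromic)
  tables <- lapply(tables, function(t) {
    t <- t[keep, , drop = FALSE]
    rownames(t) <- NULL
    t
  })
  if (nrow(tables[[1]]) == 0) stop("no SNPs survive harmonization")
  attr(tables, "log") <- list(n_common = length(common),
                              n_palindromic_dropped = n_palin,
                              n_mismatch_dropped = n_mismatch,
                              n_final = nrow(tables[[1]]))
  tables
}

#' Advisory statistical-power gate for trait inclusion
#'
#' A GWAS is considered adequately powered for multivariate genomic
#' modelling when its SNP heritability is at least 0.05 and the
#' heritability Z-score at least 2 (both inclusive). The gate is advisory:
#' it reports failures but does not remove traits.
#'
#' @param meta data frame with columns `name`, `reported_h2`, `h2_z` (one
#'   row per trait).
#' @param h2_min,z_min inclusive thresholds.
#' @return `meta` with logical column `pass` and attribute `failures`.
#' @export
power_gate <- function(meta, h2_min = 0.05, z_min = 2) {
  stopifnot(all(c("name", "reported_h2", "h2_z") %in% names(meta)))
  meta$pass <- !is.na(meta$reported_h2) & !is.na(meta$h2_z) &
    meta$reported_h2 >= h2_min & meta$h2_z >= z_min
  fails <- meta$name[!meta$pass]
  if (length(fails))
    message("power_gate (advisory): below threshold: ",
            paste(fails, collapse = ", "))
  attr(meta, "failures") <- fails
  meta
}

#' Convert a sumstats table to standardized (per-SD) units
#'
#' Uses the identity `beta_std = z / sqrt(n)`, `se_std = 1 / sqrt(n)`,
#' which is exact for a standardized phenotype and genotype and leaves
#' Z-scores untouched.
#'
#' @param t a sumstats data frame.
#' @return The table with beta/se replaced by standardized values.
#' @export
standardize_sumstats <- function(t) {
  t$beta <- t$z / sqrt(t$n)
  t$se <- 1 / sqrt(t$n)
  t
}
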