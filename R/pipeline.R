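# Study-shaped pipeline orchestration: synthetic generation -> QC ->
# LDSC -> factor models -> latent-factor GWAS -> bidirectional MR,
# driven by one config (list or YAML file) with a single global seed
# fanned out to per-stage seeds by stable hashing of stage names.

#' Derive a per-stage seed from the global seed
#'
#' Stable string hash of the stage name combined with the global seed,
#' kept below 2^31 so it is a valid R integer seed.
#'
#' @param global_seed integer.
#' @param stage stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(global_seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1000003
  as.integer((as.numeric(global_seed) * 1009 + h) %% 2147483629 + 1)
}

#' The demo latent architecture: 11 traits, 3 correlated clusters
#'
#' Eleven traits shaped like a psychiatric-genetics panel: a loneliness
#' trait plus five neurodevelopmental/mood indicators (cluster NMD),
#' three substance-use indicators (SUT) and two psychotic-disorder
#' indicators (DPF). Heritabilities (0.042-0.412) match published GWAS of
#' such traits; the loneliness trait loads 0.66 on the NMD factor only,
#' and structural effects loneliness -> NMD = 0.5 and NMD -> loneliness =
#' 0.34 are used when instruments are planted.
#'
#' Sample sizes default to the published values. Desk-scale runs simulate
#' a ~22,000-SNP genome rather than the ~1.2 million SNPs of a real LDSC
#' analysis, so per-SNP power is higher than in the originals; keeping
#' the published N ensures every trait's heritability — including the
#' small-sample anxiety- and PTSD-like traits — is estimated safely
#' positive, which the correlation and factor stages require.
#'
#' @param n_scale optional multiplier on the published sample sizes.
#' @param overlap_frac,phenotypic_corr_overlap optional overlap structure
#'   passed to [truth_model()].
#' @return A [truth_model()].
#' @export
demo_truth <- function(n_scale = 1, overlap_frac = NULL,
                       phenotypic_corr_overlap = NULL) {
  traits <- c("lone", "mdd", "anx", "ptsd", "adhd", "asd",
              "alc", "can", "smk", "scz", "bip")
  L <- matrix(0, 11, 3, dimnames = list(traits, c("F1", "F2", "F3")))
  L[, 1] <- c(0.66, 0.80, 0.75, 0.70, 0.60, 0.50, 0, 0, 0, 0, 0)
  L[, 2] <- c(0, 0, 0, 0, 0, 0, 0.60, 0.70, 0.75, 0, 0)
  L[, 3] <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0.85, 0.80)
  Phi <- matrix(c(1, 0.45, 0.50,
                  0.45, 1, 0.35,
                  0.50, 0.35, 1), 3, 3)
  h2 <- c(0.042, 0.089, 0.079, 0.050, 0.236, 0.118,
          0.050, 0.070, 0.090, 0.412, 0.170)
  N <- round(c(445024, 807553, 15730, 9537, 55374, 46350,
               70460, 364701, 462690, 105318, 51710) * n_scale)
  truth_model(L, Phi, h2, N, overlap_frac = overlap_frac,
              phenotypic_corr_overlap = phenotypic_corr_overlap,
              causal_effect = 0.5, trait_names = traits)
}

#' Default demo pipeline configuration
#'
#' Eleven synthetic traits from [demo_truth()] at desk scale, with the
#' conventional analysis settings: INFO > 0.9, MAF > 0.01, 200 jackknife
#' blocks, PCA/EFA on odd and CFA on even chromosomes, Q_SNP exclusion at
#' p < 5e-8, clumping at 10,000 kb / r2 < 0.001, instruments at p < 5e-8
#' with a 5e-7 sensitivity threshold.
#'
#' @param seed global seed (mandatory for any run).
#' @param outdir output directory.
#' @return Config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1, outdir = tempfile("gsemr_run_")) {
  list(
    seed = seed,
    outdir = outdir,
    synthetic = list(
      n_snps_per_chr = 1000,
      block_size = 50,
      within_r2 = 0.1,
      polygenicity = 1,
      n_instruments_forward = 12,
      n_instruments_reverse = 12,
      instrument_effect_forward = 0.02,
      instrument_effect_reverse = 0.04,
      causal_forward = 0.5,
      causal_reverse = 0.34
    ),
    qc = list(info_min = 0.9, maf_min = 0.01),
    ldsc = list(n_blocks = 200),
    parity = list(efa = "odd_chr", cfa = "even_chr"),
    factors = list(
      NMD = c("mdd", "anx", "ptsd", "adhd", "asd"),
      SUT = c("alc", "can", "smk"),
      DPF = c("scz", "bip")
    ),
    loneliness_trait = "lone",
    keep_factor = "NMD",
    qsnp_threshold = 5e-8,
    mr = list(p_threshold = 5e-8, sensitivity_threshold = 5e-7,
              window_kb = 10000, r2_cap = 0.001, n_boot = 200,
              steiger = TRUE)
  )
}

#' Validate a pipeline configuration
#'
#' @param config config list, or path to a YAML file.
#' @return Character vector of violations (empty when valid); attribute
#'   `warnings` carries advisory messages.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- tryCatch(yaml::read_yaml(config), error = function(e)
      stop("cannot parse config file: ", conditionMessage(e)))
  }
  v <- character(0)
  warn <- character(0)
  if (is.null(config$seed)) v <- c(v, "seed: mandatory, missing")
  if (!is.null(config$qc)) {
    if (!is.null(config$qc$info_min) &&
        (config$qc$info_min < 0 || config$qc$info_min > 1))
      v <- c(v, "qc.info_min: must lie in [0, 1]")
    if (!is.null(config$qc$maf_min) &&
        (config$qc$maf_min <= 0 || config$qc$maf_min >= 0.5))
      v <- c(v, "qc.maf_min: must lie in (0, 0.5)")
  }
  if (!is.null(config$mr)) {
    if (!is.null(config$mr$r2_cap) &&
        (config$mr$r2_cap <= 0 || config$mr$r2_cap >= 1))
      v <- c(v, "mr.r2_cap: must lie in (0, 1)")
    for (f in c("p_threshold", "sensitivity_threshold")) {
      if (!is.null(config$mr[[f]]) &&
          (config$mr[[f]] <= 0 || config$mr[[f]] >= 1))
        v <- c(v, paste0("mr.", f, ": must lie in (0, 1)"))
    }
    if (!is.null(config$mr$window_kb) && config$mr$window_kb <= 0)
      v <- c(v, "mr.window_kb: must be positive")
  }
  if (!is.null(config$qsnp_threshold) &&
      (config$qsnp_threshold <= 0 || config$qsnp_threshold >= 1))
    v <- c(v, "qsnp_threshold: must lie in (0, 1)")
  if (!is.null(config$ldsc$n_blocks) && config$ldsc$n_blocks < 2)
    v <- c(v, "ldsc.n_blocks: must be at least 2")
  if (!is.null(config$parity)) {
    if (identical(config$parity$efa, config$parity$cfa))
      warn <- c(warn, paste0("parity: EFA and CFA assigned the same ",
                             "chromosome subset ('", config$parity$efa,
                             "'); disjoint subsets avoid overfitting"))
  }
  attr(v, "warnings") <- warn
  v
}

#' Generate the full synthetic study inputs from a config
#'
#' Builds the LD structure, draws true effects, plants bidirectional
#' instruments (loneliness trait <-> NMD-style latent factor 1), and
#' simulates per-trait summary statistics.
#'
#' @param config config list (see [demo_config()]).
#' @param truth optionally, a [truth_model()] overriding [demo_truth()].
#' @return List: `truth`, `ld`, `sumstats` (raw tables with QC columns),
#'   `registry_forward`, `registry_reverse`.
#' @export
simulate_study <- function(config, truth = demo_truth()) {
  sc <- config$synthetic
  ld <- ld_structure(n_snps_per_chr = sc$n_snps_per_chr,
                     block_size = sc$block_size,
                     within_r2 = sc$within_r2)
  eff <- simulate_true_effects(truth, ld, polygenicity = sc$polygenicity,
                               seed = derive_seed(config$seed, "effects"))
  lone <- config$loneliness_trait
  fwd <- plant_instruments(eff, truth, ld,
                           n_instruments = sc$n_instruments_forward,
                           effect_size = sc$instrument_effect_forward,
                           seed = derive_seed(config$seed, "instruments_fwd"),
                           exposure = lone, outcome = list(factor = 1),
                           causal_effect = sc$causal_forward)
  rev <- plant_instruments(fwd$effects, truth, ld,
                           n_instruments = sc$n_instruments_reverse,
                           effect_size = sc$instrument_effect_reverse,
                           seed = derive_seed(config$seed, "instruments_rev"),
                           exposure = list(factor = 1), outcome = lone,
                           causal_effect = sc$causal_reverse,
                           exclude_blocks = fwd$registry$block)
  tabs <- simulate_sumstats(rev$effects, truth, ld,
                            seed = derive_seed(config$seed, "sumstats"))
  list(truth = truth, ld = ld, sumstats = tabs,
       registry_forward = fwd$registry, registry_reverse = rev$registry)
}

# convert a raw simulated table (upper-case columns) to the internal
# sumstats representation
.as_internal <- function(tab) {
  out <- data.frame(snp = tab$SNP, chr = tab$CHR, bp = tab$BP,
                    a1 = tab$A1, a2 = tab$A2, beta = tab$BETA, se = tab$SE,
                    p = tab$P, n = tab$N, info = tab$INFO, frq = tab$FRQ,
                    stringsAsFactors = FALSE)
  out$z <- out$beta / out$se
  class(out) <- c("sumstats", "data.frame")
  out
}

.write_tsv <- function(x, path) {
  utils::write.table(format(x, digits = 10, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full study-shaped pipeline from one configuration
#'
#' Stages, in order: synthetic generation (or file loading), QC
#' filtering, harmonization, LDSC S/V assembly on all / odd / even
#' chromosomes, genetic-correlation report with FDR, PCA scree and EFA on
#' the odd-chromosome matrix, the three structural loneliness models on
#' the even-chromosome matrix, latent-factor GWAS with Q_SNP filtering,
#' and bidirectional MR at the primary and sensitivity thresholds.
#' Reruns with the same config and seed reproduce every numeric output.
#'
#' @param config config list or YAML path (see [demo_config()]); a seed
#'   is mandatory.
#' @param truth optional [truth_model()] override for the synthetic stage.
#' @return A `run_report` list with every stage's outputs and row counts;
#'   artifacts are written under `config$outdir`.
#' @export
run_pipeline <- function(config, truth = demo_truth()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  violations <- validate_config(config)
  if (is.null(config$seed)) stop("config must set a seed before any work")
  if (length(violations))
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  for (w in attr(validate_config(config), "warnings")) warning(w)
  outdir <- config$outdir %||% tempfile("gsemr_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, stages = list())
  log_stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
  }

  # -- stage 1: inputs -------------------------------------------------
  study <- simulate_study(config, truth = truth)
  tabs <- lapply(study$sumstats, .as_internal)
  log_stage("simulate", n_snps = study$ld$n_snps,
            n_traits = length(tabs))

  # -- stage 2: QC -----------------------------------------------------
  qc <- config$qc
  tabs_qc <- lapply(tabs, qc_filter, info_min = qc$info_min,
                    maf_min = qc$maf_min)
  log_stage("qc", rows_in = nrow(tabs[[1]]), rows_out = nrow(tabs_qc[[1]]),
            info_min = qc$info_min, maf_min = qc$maf_min)

  # -- stage 3: harmonize ----------------------------------------------
  tabs_h <- harmonize_panels(tabs_qc)
  tabs_h <- lapply(tabs_h, standardize_sumstats)
  log_stage("harmonize", n_snps = nrow(tabs_h[[1]]),
            log = attr(tabs_h, "log"))

  # -- stage 4: LDSC ---------------------------------------------------
  ld_scores <- data.frame(SNP = study$ld$snps$snp, L2 = study$ld$snps$l2)
  ld_ref <- ld_ref_table(study$ld)
  nb <- config$ldsc$n_blocks
  gc_all <- build_S_V(tabs_h, ld_scores, subset = "all", n_blocks = nb,
                      ld_blocks = ld_ref)
  gc_odd <- build_S_V(tabs_h, ld_scores, subset = config$parity$efa,
                      n_blocks = nb, ld_blocks = ld_ref)
  gc_even <- build_S_V(tabs_h, ld_scores, subset = config$parity$cfa,
                       n_blocks = nb, ld_blocks = ld_ref)
  corr <- correlation_report(gc_all)
  .write_tsv(as.data.frame(gc_all$S), file.path(outdir, "S_all.tsv"))
  .write_tsv(as.data.frame(corr$rg), file.path(outdir, "rg.tsv"))
  .write_tsv(as.data.frame(corr$p_fdr), file.path(outdir, "rg_p_fdr.tsv"))
  log_stage("ldsc", h2 = diag(gc_all$S), n_blocks = nb,
            subsets = c("all", config$parity$efa, config$parity$cfa))

  # -- stage 5: PCA / EFA on the odd-chromosome matrix ------------------
  scree <- pca_scree(gc_odd)
  efa <- if (scree$n_retained >= 1 && scree$n_retained < length(gc_odd$traits))
    efa_fit(gc_odd, scree$n_retained) else NULL
  .write_tsv(scree$scree, file.path(outdir, "scree.tsv"))
  log_stage("pca_efa", eigenvalues = scree$eigenvalues,
            n_retained = scree$n_retained,
            efa_total_var = if (!is.null(efa)) efa$total_var_explained)

  # -- stage 6: structural models on the even-chromosome matrix ---------
  lm3 <- loneliness_models(gc_even, config$factors, config$loneliness_trait,
                           keep_factor = config$keep_factor)
  fit_sum <- function(f) c(chi2 = f$chi2, df = f$df, srmr = f$srmr,
                           cfi = f$cfi, converged = as.numeric(f$converged))
  .write_tsv(lm3$constrained$params[, c("label", "est", "se", "z", "p")],
             file.path(outdir, "constrained_model.tsv"))
  log_stage("structural_models",
            adjusted = fit_sum(lm3$adjusted),
            constrained = fit_sum(lm3$constrained))

  # -- stage 7: latent-factor GWAS + Q_SNP ------------------------------
  keep <- config$keep_factor
  lgwas <- latent_gwas(tabs_h, gc_even, config$factors[[keep]],
                       factor_name = keep)
  lgwas_f <- qsnp_filter(lgwas, threshold = config$qsnp_threshold)
  n_sig <- sum(lgwas_f$p < config$mr$p_threshold)
  .write_tsv(utils::head(lgwas_f[order(lgwas_f$p), ], 50),
             file.path(outdir, "latent_gwas_top.tsv"))
  log_stage("latent_gwas", n_snps = nrow(lgwas),
            n_excluded_qsnp = length(attr(lgwas_f, "excluded")),
            n_significant = n_sig)

  # -- stage 8: bidirectional MR ---------------------------------------
  lone_tab <- tabs_h[[config$loneliness_trait]]
  mrc <- config$mr
  mr_primary <- bidirectional_mr(
    lone_tab, lgwas_f, ld_ref, p_threshold = mrc$p_threshold,
    window_kb = mrc$window_kb, r2_cap = mrc$r2_cap,
    steiger = isTRUE(mrc$steiger), seed = derive_seed(config$seed, "mr"),
    n_boot = mrc$n_boot, name_a = config$loneliness_trait, name_b = keep)
  mr_sens <- bidirectional_mr(
    lone_tab, lgwas_f, ld_ref, p_threshold = mrc$sensitivity_threshold,
    window_kb = mrc$window_kb, r2_cap = mrc$r2_cap,
    steiger = isTRUE(mrc$steiger), seed = derive_seed(config$seed, "mr"),
    n_boot = mrc$n_boot, name_a = config$loneliness_trait, name_b = keep)
  if (!is.null(mr_primary$table))
    .write_tsv(mr_primary$table, file.path(outdir, "mr_primary.tsv"))
  if (!is.null(mr_sens$table))
    .write_tsv(mr_sens$table, file.path(outdir, "mr_sensitivity.tsv"))
  if (!is.null(mr_primary$forest))
    .write_tsv(mr_primary$forest, file.path(outdir, "mr_forest.tsv"))
  log_stage("mr", primary = mr_primary$table, sensitivity = mr_sens$table)

  report$stages <- report$stages
  report$correlations <- corr
  report$scree <- scree
  report$efa <- efa
  report$models <- lm3
  report$latent_gwas <- lgwas_f
  report$mr_primary <- mr_primary
  report$mr_sensitivity <- mr_sens
  report$registry_forward <- study$registry_forward
  report$registry_reverse <- study$registry_reverse
  report$outdir <- outdir
  class(report) <- "run_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ") -> ", x$outdir, "\n", sep = "")
  for (nm in names(x$stages)) cat("  stage:", nm, "\n")
  if (!is.null(x$mr_primary$table)) {
    cat("Primary MR results:\n")
    print(x$mr_primary$table, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
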