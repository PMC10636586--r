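---
title: "Genomic SEM and Mendelian randomization on summary statistics: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic SEM and Mendelian randomization on summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gsemr)
```

This vignette is the package's account of its own methods: the models
it fits, the assumptions they lean on, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
the numerical choices inside the estimators, and the limitations a user
should keep in mind. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis chain

The package implements one coherent chain, each stage consuming the
previous stage's output:

1. **Summary statistics in, QC, harmonization** (`read_sumstats`,
   `qc_filter`, `harmonize_panels`). All downstream work uses
   standardized (per-SD) units, in which the standard error of a
   per-SNP effect is 1/√N; per-allele effects are converted via
   `beta_std = z/√N`, which leaves Z-scores untouched.
2. **LD score regression** (`univariate_ldsc`, `bivariate_ldsc`,
   `build_S_V`, `correlation_report`): the genetic covariance matrix
   **S** and its sampling covariance **V**.
3. **Genomic factor analysis** (`pca_scree`, `efa_fit`, `cfa_fit`,
   `loneliness_models`): measurement and structural models fit to
   **S** weighted by **V**.
4. **Latent-factor GWAS** (`latent_gwas`, `qsnp_filter`): per-SNP
   effects on a latent factor with the Q_SNP heterogeneity filter.
5. **Bidirectional MR** (`select_instruments`, `harmonize_io`,
   `steiger_filter`, the five `mr_*` estimators, `bidirectional_mr`).

`run_pipeline()` executes the chain from a single config with one
global seed, fanned out to per-stage seeds by a stable string hash of
the stage name (`derive_seed`), so any stage can be reproduced in
isolation without seed bookkeeping.

## 2. LD score regression

The estimator regresses per-SNP χ² (or the cross-trait product
z₁z₂) on the LD score. Assumptions inherited from the method: an
additive polygenic architecture in which per-SNP expected association
strength is linear in the LD score, and estimation noise that is
homogeneous enough for the two-step weights to be sensible.

Choices and parameters:

- **Weights.** Step one is an unweighted fit; step two uses
  `w_j = 1/(l_j · fitted_j²)` (univariate) or
  `w_j = 1/(l_j · (f1_j·f2_j + f12_j²))` (bivariate), the standard
  heteroskedasticity-plus-oversampling form. Fitted values are floored
  at 0.5 so early-iteration negatives cannot flip weights.
- **Jackknife.** 200 contiguous genome-ordered blocks by default.
  When an LD reference is available (`ld_blocks`), block boundaries
  snap to LD-block boundaries: an LD block straddling a boundary
  correlates adjacent delete-one blocks and biases the variance down.
  On simulated data with 22,000 SNPs this alignment moved the ratio of
  empirical to jackknife SE from about 1.2 to about 1.08 (the residual
  gap is finite-block noise); the pipeline therefore always passes its
  LD reference. The sampling covariance **V** of vech(**S**) uses the
  same blocks for every trait pair, so covariances between elements of
  **S** are estimated coherently.
- **M, the SNP count.** Standalone estimators use the number of
  regression SNPs, keeping the synthetic setting self-contained. When
  `build_S_V` is restricted to odd or even chromosomes it converts
  slopes with the *genome-wide* SNP count instead: under a uniform
  per-SNP architecture the subset regression estimates the genome-wide
  quantity, which keeps the odd- and even-chromosome **S** matrices on
  the same scale as the all-chromosome one (and mutually comparable —
  their element-wise average reproduces the all-chromosome estimate
  within sampling error, which the test suite checks).
- **Binary traits** enter via effective sample size
  `4/(1/cases + 1/controls)` on the observed scale; no liability-scale
  conversion is applied.
- **FDR.** The correlation report adjusts the k(k−1)/2 two-sided
  p-values with Benjamini–Hochberg.

## 3. The DWLS factor-model engine

Models are declared in a small text syntax (`=~` loadings, `~`
regressions among latents, `~~` (co)variances, `value*name` fixes a
parameter) and compiled to LISREL-style matrices. Identification
defaults: exogenous factors get unit variance (so structural paths are
partial genetic correlations); a factor with a fixed nonzero "marker"
loading gets a free variance; endogenous factors get a free disturbance
variance; exogenous factor covariances are free; indicator residuals
are free. A single-indicator latent is specified as
`LONE =~ 1*lone` with `lone ~~ 0*lone`.

Estimation minimizes the diagonally weighted least-squares discrepancy
with weights `1/diag(V)`. Numerical choices:

- **Optimization.** BFGS from a scale-aware start plus two jittered
  starts under fixed internal seeds; near-ties between starts (flat
  ridges of equally fitting solutions, e.g. a one-factor model on an
  identity matrix) are broken toward the smallest structural-parameter
  norm — among equally supported solutions the engine prefers the one
  claiming the least signal. A Gauss–Newton polish then drives the
  gradient to machine precision under a strict-improvement rule, so
  just-identified models reproduce **S** exactly.
- **Sign convention.** Each factor's sign is canonicalized so its
  largest-magnitude loading is positive (fixed marker loadings pin the
  sign instead).
- **Standard errors** are sandwich estimates `A⁻¹ Δᵀ W V W Δ A⁻¹`
  with Δ the numerical Jacobian of σ(θ); they acknowledge that the
  DWLS weight matrix is not the full inverse of **V**.
- **Model χ².** The residual-based statistic `eᵀ U⁺ e` with
  `U = (I−P) V (I−P)ᵀ` and the pseudo-inverse truncated at the model's
  degrees of freedom. It is exactly zero for saturated models and
  asymptotically χ²(df) otherwise. SRMR averages squared
  correlation-scale residuals over all unique elements including the
  diagonal; CFI compares against the no-covariance baseline, whose χ²
  has closed form because the baseline reproduces the diagonal exactly
  (if the baseline χ² falls below its df, CFI is reported as 1 with a
  flag).
- **PD smoothing.** LDSC **S** matrices can be indefinite;
  `smooth_to_pd` clips eigenvalues at 10⁻⁶ and rescales to preserve
  the diagonal, iterating the pair to a fixpoint because each step
  slightly undoes the other.
- **EFA** uses maximum-likelihood extraction (`factanal`) with promax
  rotation; factor correlations derive from the rotation matrix and
  the default salience threshold for proposing a confirmatory pattern
  is |λ| ≥ 0.25. The rotation is oblique by design — the retained
  factors are expected to be genetically intercorrelated. A saturated
  EFA (as many factors as traits) is not identified under ML factor
  analysis and is rejected; the saturated limit is exercised through
  the DWLS engine instead, where a just-identified model reproduces
  **S** exactly.

The three structural models around the loneliness latent mirror a
standard robustness progression: separate bivariate regressions
(marginal associations), a joint regression with free factor
intercorrelations (partial associations), and the joint regression
with all but one path constrained to zero. The constrained model
guards against the reversal paradox — sign flips on nuisance paths
under multicollinearity — which the test suite reproduces by
generating factors with intercorrelations near 0.9.

## 4. Latent-factor GWAS and Q_SNP

Per-SNP fits hold the measurement model fixed at its no-SNP estimates
(two-stage). This is orders of magnitude faster than a joint per-SNP
refit and asymptotically equivalent when the SNP's contribution to the
factor variance is negligible, as it is for any single common variant.
Consequences worth knowing:

- The factor-level effect is a weighted combination
  `b̂ = (λᵀD⁻¹λ)⁻¹ λᵀD⁻¹ β`; error in the estimated loadings
  propagates *multiplicatively* into all SNP effects, so a replicate's
  instrument effects share a common scale wobble of a few percent.
- The per-SNP sampling covariance uses `se_i se_j` scaled by the
  cross-trait LDSC intercepts (the sample-overlap term). Intercept
  estimates are noisy at reduced SNP counts, so the implied
  error-correlation matrix is clamped (diagonal to [0.9, 1.1],
  off-diagonal correlations to ±0.9) and PD-smoothed before use. Exact
  nominal calibration of the latent association test is a property of
  the estimator given the true error covariance (verified as such in
  the tests); through estimated intercepts it is approximate, and this
  is the dominant miscalibration source at desk scale.
- Q_SNP is the residual quadratic form against the common-pathway
  prediction, with df = indicators − 1. Its χ² calibration holds under
  a *common-pathway truth* (all genetic signal through the factor);
  trait-specific genetic variance is genuine factor heterogeneity and
  inflates Q_SNP by design — that is the statistic doing its job.
- The filter default applies to the latent factor wherever it is used
  (the factor's own GWAS is filtered before either MR direction), and
  exclusion is one-sided: retained iff Q_SNP p ≥ 5×10⁻⁸.

## 5. Mendelian randomization

Instrument selection is greedy clumping: sort by p, accept the best,
discard candidates within 10,000 kb *and* reference r² > 0.001 of an
accepted SNP (ties on p broken by position then id; SNPs missing from
the LD reference are treated as independent and logged). Harmonization
sign-aligns outcome alleles, drops palindromic (A/T, C/G) SNPs, and
orients exposure betas positive — the convention Egger and the mode
estimator require. Steiger filtering keeps instruments with
`z²/(z²+N)` larger in the exposure (strict inequality).

Estimators, with their conventions:

- **IVW**: weights 1/se²_out, regression through the origin;
  multiplicative random-effects SE (`max(1, √(Q/df))` scale) as the
  primary convention, fixed effects available.
- **Egger**: free intercept (average directional pleiotropy);
  I²_GX reported as an instrument-strength (NOME) gauge; same
  multiplicative scaling. Confidence intervals are normal-theory by
  default.
- **Weighted median / mode**: inverse-variance weights on delta-method
  ratio variances; the mode uses a Gaussian kernel with
  modified-Silverman bandwidth, a 512-point grid restricted to the
  data range (the maximum of a Gaussian mixture lies in the convex
  hull of its centres), and both use parametric-bootstrap SEs with
  1,000 replicates under a caller-supplied seed.
- **RAPS**: profiling the unknown true exposure effects out of the
  Gaussian pair likelihood leaves exactly the standardized residuals
  `t_j = (bY_j − b·bX_j)/√(seY² + b² seX² + τ²)`; the estimate
  minimizes Σρ(t) (squared-error or Huber loss). The derivation
  matters: the profiled likelihood carries no `log v` volume term, and
  adding one re-introduces precisely the weak-instrument attenuation
  the method exists to remove. Overdispersion τ² (balanced pleiotropy)
  is profiled by method of moments (`mean(t²) = 1` with an n−1
  adjustment), alternating with the slope; the SE is a sandwich from
  the profile score.
- **Cochran's Q** with df = n−1 (IVW) or n−2 (Egger); fewer than the
  required instruments yields a flagged, undefined result rather than
  a number.

A warning is raised when fewer than 10 instruments survive, reflecting
the small-instrument bias caution standard in this literature. The
sensitivity threshold 5×10⁻⁷ can only add instruments, never remove
them, and the tests assert this monotonicity.

## 6. What the generator emulates — and what it does not

`truth_model` + `ld_structure` + `simulate_true_effects` +
`simulate_sumstats` produce multi-trait summary statistics from a known
latent architecture:

- **Emulated:** standardized per-SD effects with SE = 1/√N; a
  block-diagonal LD structure (exchangeable within-block r², zero
  between blocks, blocks never spanning chromosome boundaries, block
  sizes cycling over a deterministic profile so LD scores vary — a
  regression on a constant LD score is unidentified); 22 autosomes so
  chromosome-parity splits are exercisable; cross-trait estimation
  error correlated as `overlap_frac × phenotypic_corr_overlap`, which
  reproduces the theoretical cross-trait intercept ρ·N_s/√(N₁N₂);
  deliberate sub-threshold INFO and MAF rows for QC testing; binary
  traits via effective N only.
- **Instrument planting** overwrites one SNP per chosen LD block and
  clears the block's polygenic background, so a planted instrument's
  LD-smoothed effect is exactly proportional across traits — the
  valid-instrument contract. Varying per-instrument effect sizes keep
  the Egger regression identified (constant exposure effects make
  slope and intercept collinear). Exposures and outcomes may be traits
  or latent factors; factor-level effects propagate through
  covariance-scale loadings.
- **Not emulated:** realistic MAF spectra and LD decay (allele
  frequencies only scale the written per-allele effects; Z-scores are
  frequency-free), liability-threshold binary phenotypes, the X
  chromosome, population stratification, and real LD panel structure.
  Passing tests therefore demonstrate estimator correctness under the
  stated generative model, not robustness to real-data pathologies
  such as stratification or mismatched LD references.

**Desk scale has consequences.** The validation experiments use
genomes of roughly 22,000–50,000 SNPs instead of the ~1.2 million of a
real LDSC analysis. With published sample sizes on a compressed
genome, per-SNP power is far higher than in reality: LDSC intercepts
are noisy (hence the clamping above), and many polygenic background
SNPs reach genome-wide significance, entering MR as
correlated-pleiotropy instruments. The demo pipeline keeps the
published sample sizes anyway, because the alternative — scaling N
down — drives the weakest traits' heritability estimates negative and
the correlation stage (correctly) refuses a non-positive diagonal.
The demo's MR table is therefore read as a robustness exercise: median
and mode estimators sit near the planted effects while IVW is diluted.
The recovery experiments that make quantitative claims (in
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`) use
moderate sample sizes — 20,000–100,000 at ~50,000 SNPs — chosen once
so that per-SNP power, intercept stability and instrument counts are
in realistic ranges: two-trait LDSC recovery at N = 20,000 with
h² = {0.3, 0.1} and r_g = 0.6 over 20 replicates; ten-trait factor
recovery at N = 50,000; Q_SNP calibration on a common-pathway truth
with h² = 0.05 at N = 100,000; bidirectional recovery of planted
0.5/0.34 effects with 12 instruments per direction at N = 50,000; and
400 small null datasets for the IVW type-I error.

## 7. Known limitations

- Jackknife SEs remain mildly anti-conservative (~8%) even with
  aligned blocks at desk-scale SNP counts; 3-SE recovery bands in the
  tests absorb this honestly rather than hiding it.
- The standardized solution's SEs are first-order rescalings of the
  unstandardized sandwich SEs, not full delta-method propagations
  through the standardization.
- The V matrix entering structural fits is standardized only through
  the fit's covariance scale; fits are run on the covariance-scale
  **S**, and standardized coefficients are derived afterwards.
- Q_SNP filtering with trait-specific genetic variance excludes a
  nontrivial share of genuinely polygenic SNPs at desk scale (for the
  demo: a few hundred of ~21,000); at realistic SNP counts per-SNP
  signal is far weaker and exclusion rates correspondingly lower.
- `efa_fit` rejects a saturated factor count (unidentified under ML
  factor analysis); use the DWLS engine for saturated checks.
- The pipeline's MR stage inherits whatever instruments pass the
  significance threshold; it does not attempt outlier removal beyond
  Steiger and Q_SNP filtering.
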