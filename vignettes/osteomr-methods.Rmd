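---
title: "Methods: staged GWAS meta-analysis, LD score regression and two-sample Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged GWAS meta-analysis, LD score regression and two-sample Mendelian randomisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomr)
```

osteomr implements the statistical chain behind a staged case-control GWAS
of osteoporotic fracture and the causal assessment of its clinical risk
factors: per-study genomic control and fixed-effects meta-analysis,
instrument selection with LD clumping, a two-sample Mendelian
randomisation (MR) estimator suite, and LD score regression (LDSC) for
heritability and genetic correlation. This vignette records the models,
the conventions and tunable parameters, what the synthetic-data generators
do and do not emulate, and the design choices made where more than one
defensible option existed.

## Data model and harmonisation

The unit of exchange is a per-SNP summary-statistics table
(`sumstats()`): rsID, position, effect and other allele, effect-allele
frequency (EAF), per-allele effect (log odds ratio for binary traits), its
standard error, p-value and sample size. Validation drops — never repairs —
rows with non-ACGT or identical alleles (which excludes indels and
multi-allelic records), non-positive standard errors, frequencies outside
[0, 1], p-values outside (0, 1], or duplicated rsIDs; counts are kept by
reason. Matching between tables is by rsID, not position, because
instrument lists in the field are rsID-keyed; coordinates are carried but
never lifted over.

`harmonize()` expresses the outcome effect for the exposure's effect
allele. Exact allele matches pass through; swapped alleles flip the sign
of the outcome beta and complement its EAF; pairs that match only after
strand complementing are treated the same way. For palindromic (A/T, C/G)
SNPs both readings are consistent with either strand, so the exact-match
reading takes priority and SNPs whose EAF lies within a window of 0.5
(default `palindrome_eaf_window = 0.08`) in either study are excluded
outright — at such frequencies the allele frequency cannot resolve the
strand, and a silent strand error would flip the sign of an instrument.
The window is a conservative default; published analyses vary between
about 0.05 and 0.10. How the original multi-cohort studies reconciled
effect alleles beyond these flip rules is not documented anywhere we can
see, so no further convention is invented.

## Genomic control and fixed-effects pooling

Genomic control estimates the inflation factor as the median association
chi-square divided by the chi-square(1) median. The denominator is the
full-precision constant `qchisq(0.5, 1)` = 0.4549364 (the conventional
"0.455"). When lambda exceeds 1, standard errors are multiplied by
`sqrt(lambda)` and p-values recomputed; deflation below 1 is never
applied. Correction happens per input study *before* pooling, never to the
pooled result — a second, post-meta-analysis round is deliberately not
applied, since the staged design's replication already guards the
discovery signal and the original analysis does not describe one.

Fixed-effects inverse-variance pooling, Cochran's Q and I² are as in any
meta-analysis package; the implementation is exact precision-weighted
arithmetic, associative to 1e-12 under regrouping. The 95% normal
quantile is used at full double precision (1.959964...), not 1.96, so
that interval arithmetic reproduces printed values to their last digit.
Published tables print odds ratios with confidence intervals rather than
standard errors; `se_from_ci()` inverts the interval under log-normality.
A handful of printed cells in transcribed tables are internally
inconsistent (degenerate intervals, or intervals excluding their point
estimate — typesetting artefacts); for those, `pool_printed_stages()`
falls back to recovering the standard error from the printed p-value via
the Wald relation `se = |ln OR| / z(p)`. Acceptance-style comparisons
round half away from zero to the printed precision (`round_half_away()`),
matching how such tables are typeset.

The genome-wide filter keeps SNPs with `P < 5×10⁻⁸`, presence in strictly
more than two studies, and MAF ≥ 1% — the strictness of the study-count
gate and the inclusive MAF bound follow the reporting rules of the staged
design.

## Instrument selection and clumping

Instruments must be common (MAF strictly above 5%) and strongly associated
(`P < 5×10⁻⁸`). Clumping is greedy on ascending p-value: a SNP is kept if
its r² with every previously kept SNP is at most the threshold (default
0.05). Because the grouping criterion is `r² > 0.05`, the boundary value
itself counts as independent. P-value ties are broken lexicographically by
rsID so the output is identical across platforms. The greedy trace equals
the brute-force "lowest P per LD group" rule — the test suite verifies
this against full subset enumeration on random 12-SNP instances. The LD
matrix is always an explicit input (file or simulated); no reference panel
is consulted.

## The MR estimator suite

With harmonised effects `(bx, by)` the Wald ratio is `by/bx` with
first-order delta-method standard error `se_by/|bx|`. Ignoring the
exposure-side uncertainty is deliberate: it matches the inverse-variance
weighting that makes IVW "formally an inverse-variance weighted
meta-analysis" of ratios, and for the strong instruments the selection
gates enforce, the second-order term (available via `second_order = TRUE`)
is negligible. IVW is fixed-effects with no residual overdispersion
scaling. MR-Egger is weighted least squares with a free intercept; all
instruments are first oriented so `bx ≥ 0` by joint sign flips — without a
fixed orientation the intercept, which estimates average directional
pleiotropy, would be meaningless. Egger standard errors come from the
weighted-information matrix without residual scaling, keeping the
fixed-effects convention consistent across estimators; it requires more
than two variants, below which the fit is saturated.

The weighted median sorts per-SNP ratios, takes normalised weights
`bx²/se_by²`, and interpolates linearly between the ratios whose
cumulative-weight midpoints (`s'_j = s_j − w_j/2`) bracket 0.5. Its
standard error is the standard deviation of parametric bootstrap
replicates (default `n_boot = 1000`, seed mandatory) in which `bx` and
`by` are redrawn from normal distributions centred on their estimates;
`n_boot = 0` skips the bootstrap for simulation loops that need only
point estimates. The penalised variant multiplies each weight by
`min(1, 20 · q_j)` where `q_j` is the chi-square(1) upper-tail probability
of the SNP's contribution `Q_j = w_j (r_j − beta_IVW)²` to Cochran's Q;
`penalty_scale = 20` means penalties engage below `q_j = 0.05`. The
reference point is the IVW estimate, so a *gross* outlier that drags IVW
far from the consensus can corrupt the reference and penalise valid
instruments — the penalisation is designed for, and tested in, the
moderate-outlier regime (a few sigma). This is a known limitation of
single-step penalisation.

Binary exposures are re-expressed per doubling of the odds of exposure by
multiplying the causal log-odds, its standard error and interval bounds by
0.693 — the conventional printed constant, applied exactly as printed
rather than as ln 2 = 0.6931...; the difference is far below reporting
precision, and z-statistics (hence p-values) are unchanged. Power for a
binary outcome uses the closed-form normal approximation with
non-centrality `ln(OR)·√(N·R²·K(1−K))`. Bonferroni flags use strict
inequality at `0.05/n_tests`; with 15 exposures the threshold is 3.3×10⁻³
(12 tests, 4.2×10⁻³, for genetic correlations).

## LD score regression

LD scores are row sums of the squared-correlation matrix including the
diagonal. The single-trait regression fits `χ²_j` on `ℓ_j`, the
cross-trait regression fits `z1_j·z2_j` on `ℓ_j`; slopes convert to `h²`
and genetic covariance via `M/N` and `M/√(N₁N₂)`. The genetic correlation
divides the covariance by `√(h₁²h₂²)`; non-positive heritability leaves it
undefined (flagged with a reason), and estimates outside [−1, 1] — which
happen in noisy fits — are clamped with the raw value preserved.
Regression weights are the single-step heteroskedasticity proxy `1/ℓ_j`;
the original method's iterative variance-based weighting is a deliberate
simplification left out of scope, which costs some efficiency but no
consistency. Standard errors come from a delete-one-block jackknife over
contiguous SNP blocks (default 20), jackknifing the *entire* three-
regression pipeline jointly for the correlation. Sample overlap is
absorbed by the intercept, never subtracted. One consequence of the
model's own algebra worth recording: at fixed N and total h², the
jackknife error of ĥ² does **not** shrink as more SNPs are simulated
(var ∝ M·σ²/N²); the 1/√M shrinkage applies to the regression
coefficients at fixed per-SNP noise, and that is what the test suite
checks (on null-trait intercepts).

## What the generators emulate — and what they do not

All generators are pure functions of (parameters, master seed); named
sub-streams (frequencies, genotypes, phenotypes, noise) keep the modules
independently reproducible.

`simulate_cohort_gwas()` draws genotypes from block-diagonal AR(1) LD
(two latent-Gaussian haplotypes thresholded at the allele frequency),
assigns case status from a logistic model with sex, age (linear and
quadratic), height and weight covariates plus the specified per-allele
effects, and fits per-SNP covariate-adjusted logistic regressions (IRLS
capped at 25 iterations, tolerance 1e-8; non-converged SNPs dropped). The
intercept is tuned so the expected case count matches the request;
realised counts vary binomially. The AR(1) block structure is chosen
because it yields non-trivial clumping and LD scores from a single
parameter; it does not reproduce real LD decay, imputation uncertainty,
family structure, or genome-wide scale (the null-calibration tests use
hundreds of SNPs and cohorts of ~1 000, not millions and hundreds of
thousands).

`simulate_two_sample()` draws true instrument effects uniformly from
`bx_range` (default 0.03–0.15 in exposure-SD units, trait-increasing
orientation so no sign flips are needed), sets
`by = causal·bx + α` with `α = 0` for valid instruments and
`α ~ N(pleiotropy_mean, pleiotropy_sd²)` for the invalid fraction, and
adds sampling noise with `se_bx = 1/√N_exposure` (standardised exposure)
and `se_by = 1/√(N_outcome·K(1−K))` (binary-outcome log-odds scale,
default case fraction 0.329, a fracture-scale case-control mix). InSIDE
holds unless `inside_cor` couples α with instrument strength. The
headline-recovery simulations use the study-scale sizes (43 instruments,
N_exposure ≈ 33 000, N_outcome ≈ 562 000); the 500-replicate calibration
suite instead uses N_exposure = 100 000 and N_outcome = 50 000 so that
first-order weak-instrument attenuation (of order `se_bx²/E[bx²]`) is far
below the Monte-Carlo resolution of a 500-replicate mean — at the smaller
exposure-study size that attenuation, though practically negligible
(<0.5%), would be resolvable and the "unbiasedness" being tested would be
a property of the regime, not the estimator. One boundary worth noting:
with exactly 50% invalid weight the weighted median sits at the edge of
its consistency condition, so the robustness scenario asserts only that
its bias is smaller than IVW's, not that it vanishes.

`simulate_ldsc_pair()` draws per-SNP true effect pairs from a bivariate
normal with variances `h²/M` and correlation `rg`, propagates them through
per-block signed AR(1) correlation, and adds unit noise; overlap induces
cross-trait noise correlation `n_shared·ρ_pheno/√(N₁N₂)` with
`ρ_pheno = rg·√(h₁²h₂²) + env_cor·√((1−h₁²)(1−h₂²))`. Block correlations
are drawn per block from a range (default 0.1–0.95) rather than fixed:
with a single high correlation every LD score is large and the regression
intercept becomes an extrapolation far outside the observed range; a
spread of block strengths gives near-independent SNPs that anchor it, as
real genomes do. LDSC recovery tests use 5 000 SNPs and N = 20 000.

## Numerical conventions

* 95% normal quantile at full precision (1.959964...), chi-square(1)
  median at full precision (0.4549364).
* Odds-ratio comparisons against printed tables round half away from zero
  to the printed number of decimals.
* Greedy clumping breaks p-value ties by rsID; all generators flow from
  one master seed through named sub-streams.
* Degenerate inputs fail loudly: empty meta-analysis input, `bx = 0` Wald
  ratios, Egger with ≤ 2 variants, medians with < 3 instruments, SNPs
  missing from the LD matrix (named in the error), fewer SNPs than
  jackknife blocks.
* `rg` outside [−1, 1] is clamped with the raw value kept; non-positive
  ĥ² flags the correlation as undefined rather than producing a complex
  number.

## Known limitations

The LDSC weighting is single-step; constrained-intercept and partitioned
analyses are out of scope, and real-data genetic correlations require the
full external summary statistics, which are not packaged. The penalised
median's IVW reference point can be corrupted by extreme outliers (above).
The per-doubling rescaling applies the printed 0.693 uniformly. The
harmonisation cannot rescue palindromic SNPs near 50% frequency — they are
discarded by design. Passing calibration on these generators shows the
estimators implement their definitions and recover known truths under the
stated generative models; it does not certify behaviour under real LD,
selection effects, or assortative mating, none of which are simulated.
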