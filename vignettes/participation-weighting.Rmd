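---
title: "Correcting participation bias in biobank genetic studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting participation bias in biobank genetic studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Volunteer biobanks are not random draws from their target populations.
Participants tend to be healthier, better educated and older than the people
who were invited but did not join, and when study participation depends on
variables that also appear in an analysis — directly or through shared causes
— conditioning on being sampled opens collider paths and distorts estimated
associations. Genome-wide association (GWA) statistics, heritability and
genetic-correlation estimates, and Mendelian-randomization (MR) effects
inherit those distortions.

`ipwgwas` implements a correction workflow built on inverse-probability
participation weights:

1. model the probability `P_i` that an individual participates in the
   selected cohort rather than belonging to a representative reference
   sample, using auxiliary variables harmonized between the two;
2. weight each selected individual by `w_i = (1 - P_i) / P_i`, creating a
   pseudo-sample that matches the target population;
3. rerun every downstream analysis — per-SNP scans, LD-score regression,
   MR — in weighted form, and test whether weighting changed the answer.

Because the individual-level biobank and survey data that motivate this
workflow are access-restricted, the package ships a first-class synthetic
cohort generator with known ground truth; every claim the package makes
about its estimators is tested against that generator.

## The participation-probability model

The weight model is a logistic LASSO (via `glmnet`, with the penalty chosen
by five-fold cross-validation minimizing cross-validated deviance) of the
participation label (selected = 1, reference = 0) on fourteen auxiliary
variables: five continuous (age, BMI, weight, height, age completing
full-time education) and nine categorical with fixed level counts
(7, 2, 6, 3, 4, 5, 4, 3, 3). Every level of every categorical becomes its
own indicator — no reference level is dropped — and all pairwise products of
the 42 main-effect columns are added, including the identically-zero
products of two levels of the same variable, which the LASSO is left to
discard. This convention gives `42 + choose(42, 2) = 903` predictors.
Survey design weights of the reference sample enter the LASSO deviance as
observation weights, the standard survey-adjusted likelihood; selected rows
carry weight 1. Continuous predictors are standardized internally for the
penalty (`glmnet`'s default) so shrinkage is scale-equivariant across the
mixed-type columns, and coefficients are reported on the original scale.
Ties in the cross-validated deviance resolve to the larger, sparser penalty.

Weights are *not* trimmed by default; `compute_weights()` exposes an
optional percentile cap (`cap_quantile`) that is off unless requested,
because trimming trades bias for variance in a way the analyst should opt
into explicitly.

Weight quality is evaluated three ways, mirroring how a weighting exercise
should be audited:

- **moment recovery**: weighted means/proportions of the auxiliaries against
  their population (reference) values;
- **bias reduction**: for each auxiliary pair, how much of the gap between
  the reference correlation and the selected-sample correlation the
  weighting closes: `(|r_ref − r_sel| − |r_ref − r_sel,w|) / |r_ref − r_sel|`.
  The fraction is undefined when `r_ref = r_sel`; such pairs are flagged and
  excluded from summaries, which by default consider pairs with
  `r_diff > 0.05`;
- **balance regressions**: univariate weighted logistic regressions of the
  label on each auxiliary, with HC0 sandwich standard errors; good weights
  drive these coefficients to zero.

`crossvalidate_weights()` guards against overfitting by refitting the model
in 80:20 train-test splits so every selected individual receives one
out-of-sample probability, then comparing the out-of-sample bias-reduction
summary to the full-sample one.

## Weighted association scans

Per SNP, `run_scan()` fits `Y ~ genotype + covariates + 1` by (weighted)
least squares. With weights `W` the estimator is
`beta_w = (X'WX)^{-1} X'WY`, and because sampling weights violate
homoskedasticity its variance uses the Huber–White sandwich
`(X'WX)^{-1} (X'WDWX) (X'WX)^{-1}`, `D = diag[(Y − X beta_w)^2]`. The
unweighted arm reports classical ordinary-least-squares standard errors, as
a standard GWA does; a `robust_unweighted` flag switches it to the same
sandwich, which is also the configuration in which constant weights make
the two arms exactly identical. Binary phenotypes are analysed with the
same linear model on a 0/1 coding. P-values use the normal approximation —
at scan sample sizes the distinction from the t reference is negligible and
it matches summary-statistics conventions downstream.

Standardized effects `beta_std = Z / sqrt(2p(1−p)(n + Z^2))` (with standard
error `1/sqrt(2p(1−p)(n + Z^2))`) are appended to every scan; the weighted
arm substitutes the effective sample size
`n_eff = (sum w_in)^2 / sum(w_in^2)` — algebraically `n / (Var(w_in) + 1)`
for normalized weights — and the weighted allele frequency, so the
standardization target population is consistent with the estimator.

Quality control retains SNPs with minor-allele frequency > 1%, call rate
> 90% and Hardy–Weinberg chi-square P > 1e-6. Clumping is greedy: the
smallest-P SNP below threshold leads, and SNPs within a symmetric physical
window whose r² with the lead exceeds the cutoff are pruned (defaults
250 kb / 0.1 for scan reporting, 10,000 kb / 0.001 for MR instruments).
Genotype positions are 1-based base pairs and must be strictly increasing
within a chromosome; clumping refuses unsorted panels. Principal components
for covariate adjustment come from an eigen-decomposition of the
standardized dosage matrix on its smaller dimension.

Two participation-specific analyses complete the module: a scan of
biological sex (autosomal SNP effects on sex should be null in a
representative sample, so nonzero unweighted effects that shrink under
weighting indicate sex-differential participation), and a weighted scan of
the participation probability itself as a continuous outcome (an unweighted
version would be meaningless — the analysis sample is already conditioned
on participating).

## LD-score regression and paired difference tests

`estimate_h2()` regresses per-SNP chi-square on `n * l_j / M` with a free
intercept; the slope estimates observed-scale SNP heritability and the
intercept captures confounding-style uniform inflation. Regression weights
are the single-step heteroskedasticity weights `1 / max(l_j, 1)`; iterative
reweighting, as reference implementations default to, changes desk-scale
estimates negligibly and is deliberately not performed. LD scores sum
bias-adjusted squared correlations `r^2 − (1 − r^2)/(n − 2)` over a
physical window, self included. Genetic correlations come from the
cross-trait regression of `Z1*Z2` on `sqrt(n1*n2) l_j / M`, normalized by
the two heritabilities; the estimate is flagged when either heritability is
non-positive.

Standard errors use a delete-one-block jackknife over 200 contiguous SNP
blocks whose sizes differ by at most one (the genome-block logic without
genetic maps). The jackknife is computed from per-block sufficient
statistics, so the delete-one estimates are exact refits. For a binary
trait, observed-scale heritability converts to the liability scale by
`K^2 (1−K)^2 / (P(1−P) z^2)`; the weighted arm takes the population
prevalence K to be the *weighted* sample prevalence, the unweighted arm the
raw sample prevalence.

Weighted and unweighted estimates share the data, so their difference test
must account for the dependence:
`se_diff = sqrt(se_a^2 + se_b^2 − 2 r se_a se_b)` with `r` the correlation
of the paired delete-one-block series (raw estimates, not pseudovalues —
with near-equal blocks the correlation is invariant to the affine
pseudovalue transform). `Z = diff / se_diff` is referred to the normal
distribution, and Benjamini–Hochberg FDR at 5% is applied across each batch
of comparisons.

## Mendelian randomization

Instruments are SNPs genome-wide significant in *either* arm, pooled and
clumped by the smaller P across arms; exposures with fewer than 10
instruments are excluded. The estimator is fixed-effect IVW on the
standardized effects: `alpha_IVW = sum(u_j alpha_j) / sum(u_j)` with ratio
estimates `alpha_j = beta_out_j / beta_exp_j` and weights
`u_j = (beta_exp_j / se_out_j)^2`, identical to a weighted through-origin
regression.

Because IVW takes exposure effects as known, instruments that are
significant in only one arm carry estimation noise that attenuates the
estimate. The selection correction rescales by the ratio of the observed
exposure-effect variance `S^2` to its noise-free part
`sigma^2 = S^2 − mean(Var(beta_exp_j))`. The printed form of the corrected
*estimate* divides by `sigma` while the corrected *variance* divides by
`sigma^2`; an attenuation factor must be dimensionless, so both implement
`S^2 / sigma^2`, and a strict `as_printed` mode retains the literal
exponent for audit. When `sigma^2 <= 0` the correction is undefined and the
uncorrected fit is returned, flagged. The correction's derivation treats
the exposure effects as a mean-zero spread (instruments are signed); its
simulation study in this package draws them accordingly.

The weighted-vs-standard comparison `alpha_DIFF` uses a leave-one-SNP-out
jackknife in both arms to estimate the correlation between the paired
estimates, then the same difference test and FDR machinery as the LD-score
module.

## The synthetic cohort generator

The generator is the package's ground truth and defines its study
conditions.

- **Genotypes** are sums of two independent haplotypes; within an LD block
  the haplotype indicators share a block-equicorrelated Gaussian latent
  thresholded at the allele-frequency quantile. Per-SNP genotypes are
  exactly Hardy–Weinberg; within-block LD is tunable and cross-block LD is
  zero. Drawing the block correlation from a range (default 0.1–0.7) gives
  the LD-score variation that LD-score regression needs for identification.
- **Traits** are additive-polygenic with noise scaled to a target
  heritability; binary traits threshold the liability at the sample
  quantile of the target prevalence. The default scenario has an exposure
  trait with a causal effect (`alpha = 0.3` per standard deviation) on an
  outcome trait, the MR estimand.
- **Auxiliaries**: continuous ones are linear-plus-noise in standardized
  traits, reported in natural units; categorical ones discretize a latent
  Gaussian at the quantiles of fixed marginal level probabilities, so the
  declared level structure always holds. Thresholded latents reproduce the
  ordered level structure without claiming to match any real joint
  distribution.
- **Participation** is logistic in the standardized numeric codings of the
  auxiliaries, with the intercept solved numerically (root finding) to hit
  a target participation rate — the observable quantity a study reports.
  Coefficient names of the form `"a:b"` add interaction terms.

One scenario-design finding is worth stating because it shapes the default:
with rare participation, a mechanism that is *linear* in jointly
Gaussian-like auxiliaries acts as an approximate exponential tilt — it
shifts means but leaves correlations nearly intact, so correlation-scale
collider bias is second order. Visible distortion of pairwise associations
requires either saturating selection or non-additive mechanisms. The
default healthy-volunteer scenario therefore puts small positive weights on
education, health and age main effects (and negative on smoking and BMI),
and its strongest terms on pairwise interactions such as education×health —
educated *and* healthy people volunteering disproportionately — which is
also precisely why the weight model carries interaction predictors.

Desk-scale default sizes: population 50,000; participation rate 10%
(about 5,000 volunteers); reference sample 8,000; 5,000 SNPs in blocks of
5. The reference is deliberately large relative to the selected sample:
the bias-reduction measure uses the reference correlation as its target,
and a small reference would both false-flag null pairs past the
`r_diff > 0.05` threshold and cap the attainable reduction; real reference
surveys have proportionally tiny correlation noise, and that is the
property being emulated. The shipped fixture configuration
(`inst/extdata/healthy_volunteer.yaml`) scales further down (population
20,000, 1,200 SNPs) for a minutes-scale end-to-end run, and relaxes the
discovery threshold to 1e-5 — genome-wide 5e-8 is calibrated to sample
sizes two orders of magnitude beyond these cohorts.

What the generator does *not* emulate: the joint distributions of any real
biobank or reference survey, geography, recruitment logistics, genotyping
error, imputation,
relatedness, or population structure beyond what the PC covariates absorb.
Tests passing on this generator show the estimators are correct and the
corrections behave as designed under a known mechanism; they do not certify
performance on any particular real cohort.

## Numerical and design choices

- `(1 − P)/P` weights make the weighted selected sample reproduce the
  *non-participant* population exactly; with rare participation that
  coincides with the target population, which is the regime the method is
  meant for. Evaluation scenarios keep participation at 3–10% where this
  distinction is negligible, except for stress scenarios that deliberately
  exceed it.
- Probabilities outside (0, 1) raise errors; there is no silent clipping.
- The sandwich-variance scan is exact linear algebra per SNP (block
  decomposition of `X'WX` with precomputed covariate blocks); SNPs with
  rank-deficient designs are skipped with a log entry rather than failing
  the scan.
- Degenerate difference tests (`r = 1` with equal SEs and a zero
  difference, as when comparing an arm to itself) return `Z = 0`; a zero
  variance with a nonzero difference is an error.
- Jackknife correlation of a constant series is undefined and returned as 0
  with a warning.
- All randomness is seeded through function arguments; identical seeds give
  byte-identical outputs, including across the full pipeline, whose stages
  derive their seeds from the master seed.

## Evaluation studies

The `*_study()` functions are the package's replicate experiments; the test
suite and the acceptance script run them at these problem sizes (chosen to
resolve the effects under study at desk scale):

- `scan_bias_study()`: 200 replicates of a population of 40,000 with 40
  causal SNPs (`beta = 0.15`, h² = 0.4), participation rate 1.5% driven by
  the trait (logit coefficient 1.2) — rare participation is the regime the
  `(1 − P)/P` weights target. Reports the mean deviation of unweighted and
  oracle-weighted SNP effects from the generating value.
- `null_calibration_study()`: 10,000 null SNPs, population 30,000,
  participation 10% on an independent trait (coefficient 0.7); empirical
  type-I error of the weighted sandwich test at 5%.
- `weight_recovery_study()`: the default scenario; oracle-weight moment
  recovery in Monte-Carlo SE units plus LASSO bias-reduction summaries.
- `ldsc_recovery_study()`: Z-scores drawn from the polygenic model at
  h² = 0.2, n = 20,000, M = 5,000.
- `mr_correction_study()`: 500 instrument panels (m = 30) with
  exposure-noise variance 25% of the effect spread, true effect 0.3.
- `difference_calibration_study()`: 500 null replicates per statistic
  (M = 2,000 SNPs, 200 blocks; m = 50 instruments); type-I error of the
  three paired difference tests.
- `sex_participation_study()`: sex-differential volunteering (trait effect
  on participation with opposite sign by sex, rate 25%, coefficient 1.5) in
  populations of 25,000 with 800 SNPs; apparent autosomal heritability of
  sex, unweighted versus weighted. This is a deliberately strong stress
  scenario: the effect is quadratically small in the induced trait–sex
  correlation, and a mechanism mild enough to look like a real cohort would
  need far larger samples to resolve.

## Known limitations

- Weighting corrects only bias that operates through the modeled
  auxiliaries; selection on unmeasured variables leaves residual bias.
- The LD-score implementation is univariate/bivariate only — no partitioned
  heritability, no SEM extensions, no external reference panels.
- No mixed-model or relatedness correction in the scans, no X-chromosome
  model, no logistic arm for binary traits (linear coding throughout).
- Fixed-effect IVW only (a random-effects SE is a flag away); no MR-Egger,
  weighted-median or other pleiotropy-robust estimators.
- Missing auxiliary data are dropped, not imputed.
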