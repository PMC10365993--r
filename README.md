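# ipwgwas

Participation-bias correction for biobank genetic studies via
inverse-probability weighting.

## The problem

Volunteer biobanks over-represent healthy, educated, older people. When
study participation depends on variables that also enter an analysis,
conditioning on being sampled opens collider paths: SNP effects,
heritability (h²), genetic correlations (r_g) and Mendelian-randomization
(MR) estimates all shift, most visibly for socio-behavioural traits. This
package is for statistical geneticists and epidemiologists who want to
quantify and correct that distortion when a representative reference
sample sharing harmonized "auxiliary" variables with the biobank is
available — and for methodologists who want a fully synthetic, ground-truth
testbed for selection-bias machinery.

## The method

1. **Participation weights.** Stack the selected cohort (label 1) on the
   reference sample (label 0) and fit a logistic LASSO of the label on 14
   auxiliary variables expanded into all level indicators plus all pairwise
   interactions (903 predictors), with reference survey weights as
   observation weights and the penalty chosen by 5-fold cross-validation.
   Each selected individual gets the weight

   `w_i = (1 − P_i) / P_i`,

   normalized to `w_in = w_i / mean(w_i)`. The effective sample size is
   `n_eff = (Σ w_in)² / Σ w_in² = n / (Var(w_in) + 1)`.

2. **Weighted GWA scans.** Per SNP, `β̂_w = (X'WX)⁻¹X'WY` with the
   Huber–White variance `(X'WX)⁻¹(X'WDWX)(X'WX)⁻¹`,
   `D = diag[(Y − Xβ̂_w)²]`; standardized effects
   `β_STD = Z/√(2p(1−p)(n + Z²))` use `n_eff` and the weighted allele
   frequency in the weighted arm.

3. **LD-score regression.** χ² regressed on `n·ℓ_j/M` gives h² (slope) and
   confounding (intercept); cross-trait products give r_g. Standard errors
   and the correlation between paired weighted/unweighted estimates come
   from a 200-block jackknife, feeding the difference test
   `Z = (est − est_w) / √(se² + se_w² − 2·r·se·se_w)` with
   Benjamini–Hochberg FDR across each batch.

4. **MR.** Instruments significant in either arm (clumped at
   10,000 kb / r² 0.001, minimum 10), fixed-effect IVW on standardized
   effects, and a selection correction `α̂·S²/σ̂²` with
   `σ̂² = S² − mean(Var(β̂_EXP))` for the noise in exposure effects of
   instruments discovered in only one arm.

A synthetic-cohort module (genotypes in exact Hardy–Weinberg proportions
with block LD, polygenic traits, the 14-variable auxiliary structure, a
logistic participation mechanism with interaction terms, reference samples
with survey design weights) provides known ground truth for every stage.

## Worked example

Run the shipped healthy-volunteer scenario end to end (population 30,000,
participation rate 10%, reference sample 4,000, 1,500 SNPs; about a minute
on a laptop):

```r
library(ipwgwas)
cfg <- read_config(system.file("extdata", "healthy_volunteer.yaml",
                               package = "ipwgwas"))
report <- run_pipeline(cfg)   # add output_dir = "run1" to persist artifacts
print(report)
```

```
Participation-bias correction pipeline report
  config 4a075dab | seed 1
  population 30000, selected 2936 (9.8%), reference 4000
  weights: n_effective 1031.6 (0.35 of n), lambda 0.001348, 300 predictors
  bias reduction (pairs with r_diff > 0.05): median 0.80 over 21 pairs
  exposure scan: 36 significant (GWA-only 32, wGWA-only 1, both 3)
  outcome scan: 27 significant (GWA-only 27, wGWA-only 0, both 0)
  h2 exposure: 1.286 (se 0.346) vs weighted 0.926 (se 0.453), diff Z 0.92
  h2 outcome: 0.401 (se 0.262) vs weighted 0.421 (se 0.327), diff Z -0.08
  MR: alpha 0.571 (corrected 0.594) vs weighted 0.434 (corrected 0.492), diff Z 2.02
```

Reading the report: the LASSO retained 300 of 903 predictors and the weight
variability cut the effective sample size to 35% of the 2,936 volunteers —
information is the price of representativeness. Weighting closed a median
80% of the participation-induced gaps in pairwise auxiliary associations
(21 pairs had visible bias, `r_diff > 0.05`). In the scans, weighting's
larger standard errors cost discoveries (32 exposure loci significant only
in the standard arm), while one locus surfaced only after weighting. The
generating causal effect of the exposure on the outcome is 0.287 on the
standardized scale; the collider-distorted standard MR arm estimates 0.57,
the weighted arm moves to 0.43 (0.49 corrected) — toward the truth, with
the residual gap reflecting the deliberately strong selection and the
overlapping causal architectures of the two traits. Desk-scale LD-score
heritabilities carry large jackknife errors; their difference tests are
correspondingly conservative here.

The same stages are scriptable from a shell via
`inst/cli/ipwgwas.R` (`simulate`, `fit-weights`, `gwas`, `compare-gwas`,
`ldsc`, `mr`, `run-all`), reading and writing PLINK1 bed/bim/fam and
header-validated TSV throughout.

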