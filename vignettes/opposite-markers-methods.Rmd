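---
title: "Methods: opposite-direction methylation markers and ICA fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: opposite-direction methylation markers and ICA fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Alcohol use leaves detectable marks on the saliva methylome; exercise
also modifies methylation. `oppomark` implements a comparative design
that asks, probe by probe, whether an exercise intervention shifts
methylation in the direction *opposite* to the shift associated with
hazardous drinking. Three cohorts enter the analysis: a paired
longitudinal exercise cohort (53 participants measured at baseline and
after a year-long intervention), an age/sex-matched case-control
drinking cohort (81 + 81), and a single-group binge-drinking cohort
(281 participants with a complete 13-measure behavioral battery: five
Alcohol Dependence Scale scores, four AUDIT items, four Impaired
Control Scale scores).

# Models and procedures

## Quality control

The chain runs in a fixed, logged order per cohort: detection-p mask
(strict `p > 0.05` set missing), sample missing-rate filter (> 5%
dropped), probe missing-rate filter (> 5%), removal of externally
listed probes (cross-hybridizing probes; for the exercise cohort also a
published age-predictor CpG list consumed as an input file), per-probe
batch regression, and an inter-subject SD filter. Batch adjustment
precedes the SD filter deliberately: retention should be judged on
analysis-ready values, not on variance inflated by batch structure.
The SD threshold (default 0.06 beta) is the replicate-derived
measurement error of the noisier cohort, applied globally so both
analyses face the same filter; the per-cohort error SDs themselves are
estimated from technical replicate pairs as
`sd(paired difference) / sqrt(2)` — the standard estimator when each of
the two measurements carries independent error. The exercise cohort
additionally drops probes whose methylation associates with age
(`DNAm ~ age + sex + race`, `p < 0.01` uncorrected, on baseline
samples): in a year-long longitudinal design, ageing and intervention
are confounded by construction, so age-sensitive probes are
uninterpretable and are excluded rather than modeled.

## Cell-type deconvolution

Saliva is a mixture of buccal-epithelial and leukocyte fractions.
Given a reference panel of per-type mean beta profiles, each sample's
proportions solve a least-squares problem constrained to the
probability simplex. The solver is projected gradient descent with
fixed step `1/L` (`L` the largest eigenvalue of the Gram matrix), which
guarantees a monotonically decreasing residual; the simplex projection
is the standard sorted-threshold algorithm. Estimated proportions are
used only as post-hoc covariates, mirroring the design: the primary
discovery is run unadjusted, then the markers are re-tested with
proportion covariates (dropping one cell type to avoid the sum-to-one
collinearity) to check that calls are not mixture artifacts.

## Association engines

*Exercise*: per probe, a paired t-test on follow-up minus baseline
differences over complete pairs, two-sided, Bonferroni-controlled over
the probes actually tested — the denominator is always the data-driven
count, never a constant. Zero-variance difference vectors are
degenerate for the t statistic; they are logged and assigned `p = 0`
when the mean difference is non-zero (a perfectly reproducible shift)
and `p = 1` otherwise.

*Drinking*: a two-step procedure. Step 1 regresses each probe on the
drinker/control indicator with five race dummies (the groups are
matched in age and sex but not race; dummy coding uses the most
frequent race level as reference — the variance-maximizing conventional
choice, configurable). Step 2 verifies each Bonferroni-significant
probe against the behavioral principal components in the all-drinker
cohort. The 13 measures are standardized before PCA because their
ranges are heterogeneous; the number of components is the smallest k
whose cumulative variance reaches 90%. Each probe is modeled per PC
(adjusted for age, sex, race) and passes when its minimum PC p-value is
below 0.05, uncorrected — the most inclusive reading of a verification
step that deliberately trades false negatives for sensitivity, since
its inputs already passed family-wise control. An `any`/`all`/single-PC
switch is exposed.

## Marker intersection and direction

The overlap of the two hit sets is classified by the sign of the mean
difference (drinker minus control; follow-up minus baseline). Exact
ties classify as `none` and can never be opposite — the conservative
choice. The regression-coefficient sign is cross-checked against the
mean-difference sign; a disagreement (possible under covariate
adjustment) flags the probe and defers to the coefficient. Subgroup
confirmations re-run the primary test on participants with objectively
increased VO2 max, and on a drinker/control subset greedily matched
exactly on race and then by nearest age within race.

## ICA fusion

On the opposite markers, methylation is residualized on age, sex and
race (so no component can be demographic structure), behavior is
standardized, and each modality is decomposed as `X = A S` by Infomax
ICA: PCA whitening to exactly k dimensions, then natural-gradient
updates `W <- W + lr (I + (1 - 2 g(U)) U'/p) W` with the logistic
nonlinearity, fixed learning rate halved on divergence, tolerance
`1e-7`, at most 10,000 iterations. Component signs are fixed so each
component's largest-magnitude source score is positive, making fits
reproducible and the loading-correlation magnitudes sign-invariant.
Loading columns are correlated across modalities with the exact t
transform (a permutation option exists for small n), Bonferroni
threshold `0.05 / (k1 k2)`. Contributors of a significant pair are the
features with `|z| > 1.5` on the component's standardized source
scores; standardization uses the population SD (root mean squared
deviation), under which the canonical five-score example
`(3, 0, 0, 0, -3)` yields `|z| = 1.58` for both extremes.

*Model order.* A stability index repeats the decomposition across
bootstrap resamples of the samples, clusters the pooled components by
absolute source-score correlation, and scores mean within-cluster |r|
minus mean between-cluster |r| (an ICASSO-style index; the original
criterion is defined only by citation, so this stand-in is documented
as such). Two design points deserve emphasis. First, restart-only
repeats on fixed data are useless here: a deterministic algorithm
reproduces every order almost perfectly, so resampling is what exposes
spurious components. Second, the chosen k is the *largest* candidate
whose mean index exceeds 0.8, not the argmax: underestimated orders are
trivially stable (k = 1 scores 1.0 by construction on almost any data),
so the largest stable order is the informative one. On weak-signal
matrices the index is mediocre at every order — the known regime where
stability selection is uninformative — and for study-sized worked
analyses the package follows the published configuration of fixed
k = 2 (methylation) and k = 7 (behavior) via the `k_meth`/`k_behav`
arguments.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `detect_p_max` | 0.05 | probability | strict inequality; boundary measurements retained |
| `max_missing_rate` | 0.05 | fraction | applied to samples, then probes |
| `sd_threshold` | 0.06 | beta | larger of the two cohort replicate-error SDs |
| `age_screen_p` | 0.01 | probability | uncorrected, conservative exclusion screen |
| `family_alpha` | 0.05 | probability | Bonferroni family-wise level, denominator data-driven |
| `step2_alpha` | 0.05 | probability | uncorrected verification step |
| `pca_variance_target` | 0.90 | fraction | minimal k reaching the target |
| `z_contrib_threshold` | 1.5 | SD | contributor cutoff on standardized source scores |

# The synthetic cohorts

The generator emulates the statistical structure the analysis assumes,
with a ground-truth manifest for scoring recovery. Probe classes:
`null`, `exercise_only`, `drinking_only`, `overlap_concordant`,
`overlap_opposite` (signed so 9 of 15 are hypomethylated in drinkers,
matching the observed split), plus nuisance classes `age_driven`,
`batch_driven` and `race_driven` (the last added so the
confounder-adjustment behaviour of the race-imbalanced case-control
design is testable). Baseline profiles are convex combinations of a
two-type reference panel with Dirichlet(5, 2) proportions
(buccal-dominant saliva); subject-level deviations persist across
timepoints so paired differences cancel them; technical noise is
additive Gaussian on the beta scale (SD 0.02) with clipping to [0, 1]
applied only after noise addition and the clipping rate logged
(logit-normal generation is available but not the default, since the
replicate-error framing is on the beta scale).

Calibration of the planted effects follows the published marker table:
`|Δβ| = 0.08` with an inter-subject SD of 0.07 at effect probes puts
the planted case-control t statistics mid-range of the published ones
(whose p-values imply t ≈ 4.6–8.5 at n = 162) while comfortably
exceeding the 0.06 SD retention threshold. Behavioral scores arise from
two latent severity factors — a shared factor loading all 13 measures
(the source of their strong mutual correlation) and an impaired-control
factor loading the ICS measures, with ICS-total strongest. The latent
factors are unit-variance Laplace, not Gaussian: heavy-tailed severity
is the realistic choice and, more importantly, Gaussian sources are
unidentifiable for ICA (rotation indeterminacy), so a Gaussian planted
scenario could not validate a source-separation method.
Drinking-affected probes covary with the shared factor at r = 0.3; the
two designated fusion probes covary with the impaired-control factor at
r = 0.75, chosen so that the factor is the dominant variance source of
those probes (r² = 0.56) and the two-probe component's leading
eigenvalue `σ² + 2c²` sits well above the sample-covariance noise-bulk
edge `σ²(1 + √(p/n))²` at n = 281, p = 15 — a planted component that is
recoverable by construction rather than sitting at the detection
boundary.

What the generator does *not* emulate: genomic probe annotation and
spatial correlation along the genome, probe-type chemistry differences,
beta-value heteroscedasticity near the boundaries, non-linear age
trajectories, and cellular heterogeneity beyond a two-type mixture.
Passing recovery tests therefore demonstrate that the pipeline's
inference machinery is correct and calibrated under its own
assumptions, not that real cohorts of this size would yield the same
power.

# Numerical choices and degenerate inputs

Complete-case analysis inside every per-probe model (the design is
silent on imputation; missingness is sparse after filtering). The
missing-rate and SD filters use strict inequalities at their
boundaries. Rank-deficient designs raise errors naming the aliased
columns. The deconvolution solver stops when the objective decrease
falls below `1e-13` or after 2000 iterations. Identical marker values
across all samples (zero variance) raise in the ICA path rather than
propagating NaNs. The few detection-masked entries remaining in the
marker matrix at fusion time are mean-imputed per probe so the
decomposition sees a complete matrix. All randomness fans out from one
root seed through a documented per-stage derivation, so any stage can
be reproduced in isolation.

# Problem sizes in the shipped tests

The test-suite simulations use the study's cohort sizes (53 pairs,
81 + 81, 281) with 1,500 probes for end-to-end recovery and calibration
batches (20 replicates) and 500 probes for the shared unit-test study;
blind-source-separation checks use two Laplace sources of length 500.
These sizes keep the full suite within a few minutes on a single CPU
while leaving every per-probe family large enough for Bonferroni
accounting to be meaningful.

# Known limitations

Bonferroni is the only multiplicity control offered (by design; FDR
variants are out of scope). The two-step drinking procedure inherits
the case-control cohort's probe set; probes filtered there are
invisible to verification. The stability index is a practical stand-in,
not the cited criterion. Post-hoc cell-proportion models drop the last
panel type; with more than two types the choice of dropped column is
logged but arbitrary. The pipeline models beta values directly
(the published tables are on the beta scale); M-value variants are not
implemented.
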