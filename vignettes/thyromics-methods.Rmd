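---
title: "Methods: robust FT4-association screening and biomarker panel selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: robust FT4-association screening and biomarker panel selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thyromics)
```

## The problem

Experimental thyrotoxicosis — healthy volunteers taking a fixed daily dose of
levothyroxine for eight weeks — provides a rare, strictly controlled setting
in which to ask which plasma metabolites and proteins track thyroid-hormone
action. The design `thyromics` analyses is a 16-subject panel sampled at five
time points (baseline `bas`, treatment weeks `w4` and `w8`, post-treatment
weeks `w12` and `w16`), with serum free thyroxine (FT4) roughly doubling
under treatment while thyrotropin (TSH) is suppressed to near zero, and both
normalising after cessation. The package implements the full downstream
analysis of such a study — association screening, robustness subsampling,
fold-change summaries and biomarker panel selection — together with a
synthetic-data generator that reproduces its statistical structure, so every
stage is testable without access to any deposited data.

## The association model

For each feature $j$, the log10 intensity of sample $(i,t)$ (subject $i$,
time point $t$) is modelled as

$$
y_{itj} = \mu_j + \beta_j \,\mathrm{FT4}_{it} + \gamma_a\,\mathrm{age}_i +
\gamma_b\,\mathrm{BMI}_i \,(+\,\mathrm{batch}_i) + b_{ij} + \varepsilon_{itj},
\qquad b_{ij} \sim N(0, \sigma_b^2),\ \varepsilon \sim N(0, \sigma_e^2).
$$

FT4 is the continuous exposure (treating exposure continuously absorbs
differences in compliance and intestinal resorption), the subject is a random
intercept absorbing the repeated-measures correlation, and baseline age and
BMI are fixed covariates; proteome fits additionally adjust for the
experimental batch. The Wald p-values of $\hat\beta_j$ are adjusted by
Benjamini–Hochberg within each omics layer — the metabolome and proteome
panels are screened and corrected separately.

Because the robustness stage refits every feature across 101 participant
subsets, the model is fitted by a dedicated profiled-REML solver
(RcppArmadillo): with a single grouping factor, $V = I + \lambda ZZ^\top$ is
block diagonal and inverts in closed form, so the restricted likelihood
profiles down to a one-dimensional search over the variance ratio
$\lambda = \sigma_b^2/\sigma_e^2 \geq 0$, optimised by golden section on
$\log\lambda$ and compared against the $\lambda = 0$ boundary. A boundary
optimum is accepted and reduces to ordinary least squares — singular fits are
common and benign at these sizes. The test suite cross-checks coefficients
and standard errors against `lme4::lmer` and against a dense closed-form GLS
oracle. p-values use a normal reference without a degrees-of-freedom
correction; at 80 observations and 4–5 fixed effects the difference to a
Satterthwaite correction is small, and the leave-three-out averaging below,
not any single p-value, drives the final significance calls. REML is the
default with ML available (`reml = FALSE`).

## Robustness by leave-three-out subsampling

`make_subsets()` draws 100 distinct exclusion triples of participants
uniformly at random and appends the fixed triple of flagged "outlier"
subjects (participants whose transaminase response differed strikingly),
giving 101 pairwise distinct subsets of a 16-subject panel (560 triples
exist). `robust_associate()` reruns the full screen on every subset —
excluding a participant removes all five of their samples, and the BH
adjustment is recomputed *within* each subset — then averages estimates and
FDR values across subsets. A feature is significant when its **average FDR**
is below 0.05. Averaging q-values rather than p-values is a deliberate,
literal implementation of the procedure's description; it is conservative
(the null-calibration test below measures a family-wise rate well under the
nominal 5%). A feature must converge in at least 80% of subsets to receive a
significance call, preventing averages over a handful of subsets; this
gate is a package choice where the procedure is silent.

## Fold changes

`mean_log2fc()` computes, per feature and time point, each participant's
ratio to their own baseline value and reports the mean of the log2 ratios
(mean of logs, not log of the mean) with the count of contributing
participants; pairs are used only when both values are present. The quantity
is scale-invariant per feature and antisymmetric under ratio inversion, which
the property tests assert.

## Classification and panel selection

Samples at `bas` and `w16` are labelled euthyroid, `w4` and `w8`
hyperthyroid; `w12` is dropped as an intermediate state, leaving 64 of 80
samples. Only features without any missing value among labelled samples
enter. `nested_cv()` then runs the two-stage procedure: 30 outer splits into
training/validation; within each outer training set, 50 inner splits into
train/test, a random forest (500 trees, $\lfloor\sqrt p\rfloor$ candidate
variables per split, via the `randomForest` package) trained per inner split,
its test-set ROC AUC and Gini importances recorded; importances aggregated
across inner loops weighted by AUC, $I_j = \sum_l \mathrm{AUC}_l
g_{lj}/\sum_l \mathrm{AUC}_l$; the top 15 features by $I$ taken forward to a
new forest on the outer training set, scored on the untouched validation
samples. ROC scores are the fraction of trees voting hyperthyroid; AUC uses
the rank/midpoint tie convention (pairwise concordance with ties counted
half), verified against brute-force pair counting.

Open choices resolved here: split fractions are 2/3 training / 1/3
validation at both stages, stratified by class (not stated in the source
procedure; 2/3 is the conventional default). Splits are at the sample level
by default, so a subject's samples can land on both sides; a
`subject_aware = TRUE` mode keeps whole subjects together and is recommended
for honest generalization — both modes are tested. Since "the 15 most
important variables" is ambiguous between one global panel and per-outer-loop
panels, both are emitted: per-loop panels drive the per-loop validation AUC,
and the single reported panel aggregates importances over all inner loops of
all outer loops. Importance ties are broken by feature id for
reproducibility.

## The synthetic-data generator

`simulate_features()` generates intensities from exactly the model the
screen fits, plus the technical structure the preprocessing removes:

* hormone trajectories: independent truncated-at-zero normals per
  subject/time point with the study's printed means/SDs (FT4 13.2, 28.6,
  25.9, 11.5, 12.8 pmol/L; SDs 1.4, 6.5, 5.7, 1.5, 1.5); no within-subject
  autocorrelation is imposed, as none is reported;
* a configurable fraction of features with nonzero $\beta_j$ — defaults 19%
  for metabolites (45:20 positive:negative) and 14% for proteins (47:16) —
  with magnitudes log-uniform on [0.005, 0.04] log10 units per pmol/L, a
  range that spans barely-detectable to strong effects over the ~17 pmol/L
  FT4 excursion;
* subject random intercepts (SD 0.20), residual noise (SD 0.15), age/BMI
  slopes (0.002, 0.004), two proteome batches assigned by subject (shift SD
  0.10), and lognormal run-day scale factors (log10 SD 0.25) over 8
  acquisition days assigned by sample order;
* feature-concentrated missingness: half the features are affected, each
  with its own rate drawn up to 0.5, completely at random or left-censored
  (LC-MS missingness is intensity-dependent; both modes must pass the
  filter). Cell-wise uniform missingness was rejected because it leaves
  essentially no fully observed feature across 64 samples, contradicting the
  sizeable complete-feature panels real studies retain;
* the three flagged outlier subjects receive idiosyncratic shifts on a
  random 5% of features.

Values are then multiplied by the run-day factor and exponentiated to the
raw scale, and the catalog keeps `true_beta` as planted ground truth. What
the generator does **not** emulate: correlated feature blocks (pathway
structure), heavy-tailed or non-Gaussian residuals, intensity-dependent
variance, and drift within a run day. Passing tests therefore demonstrate
that the pipeline's procedures are correct and calibrated under the model
they assume, not that the model captures every property of real plasma
omics data.

## Preprocessing choices

Run-day normalization divides by the per-day, per-feature median of
non-missing values (standard midpoint convention); it is idempotent and
undoes the generator's scale factors exactly. It is applied to the
metabolome only by default — the platform description states it for
metabolites — with a flag to extend it to the proteome. The missingness
filter is strict (`< 40%`), matching the stated rule at its boundary: a
feature missing in 32 of 80 samples is dropped, in 31 kept. Zeros cannot be
log-transformed and are treated as missing rather than imputed; no
imputation or variance-stabilising alternative is offered.

## Numerical and testing choices

All randomness flows from one integer seed through named per-stage
substreams, so every object is bit-reproducible. Problem sizes used by the
automated checks, chosen to exercise study-scale structure while keeping a
full run in minutes on one CPU: null calibration uses 200 replicate datasets
of 100 features with a reduced 20-subset plan (19 random + the fixed
triple); parameter recovery uses 200 single-feature replicates at low noise
(subject SD 0.1, residual SD 0.05), where the Wald interval's coverage must
fall in [90%, 98%]; panel mechanics run the full 30x50 nested CV on 100
features with 200 trees; generator calibration simulates 10,000 subjects.
The acceptance script (`scripts/acceptance.R`) recomputes the null
family-wise rate and the simulated FT4 peak from scratch at those sizes.

## Limitations

The headline real-data results of the motivating setting (65/349 associated
metabolites, 63/437 proteins, mean panel AUC 0.86) depend on unreleased
measured data and are out of reach by construction; this package reproduces
the *procedures* and validates them on synthetic ground truth. Sample-level
CV splits leak within-subject correlation across the split and flatter the
AUC; the `subject_aware` mode exists precisely because of that, and analyses
of real longitudinal data should prefer it. The mean-FDR rule inherits the
conservatism measured in the calibration test; it trades power for
stability, which is its purpose.
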