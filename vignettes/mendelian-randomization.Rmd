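---
title: "Mendelian randomization of homocysteine and blood pressure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of homocysteine and blood pressure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcymr)
```

## The scientific question

Circulating homocysteine is observationally associated with blood pressure,
but homocysteine also tracks socioeconomic position, diet, smoking and
kidney function, so the observational slope may be confounding rather than
causation. Mendelian randomization (MR) sidesteps this by using genetic
variants as instrumental variables: because alleles are assigned at
conception, a variant that raises homocysteine — such as the T allele of
*MTHFR* C677T (rs1801133), which impairs methylenetetrahydrofolate
reductase activity — is essentially randomized with respect to lifestyle
confounders. If homocysteine causes higher blood pressure, carriers of
homocysteine-raising alleles should show proportionally higher pressure.

This package implements both standard MR designs for this question:

* **One-sample MR** on individual-level data: genotype dosage, homocysteine
  and blood pressure measured on the same people (a young-adult birth
  cohort, analysed at n = 3701 complete cases).
* **Two-sample MR** on GWAS summary statistics: per-allele SNP effects on
  standardized log homocysteine from one consortium (18 genome-wide
  significant SNPs) combined with per-allele effects on systolic/diastolic
  blood pressure (SBP/DBP) from a blood-pressure consortium.

Because neither the individual-level cohort nor the consortium panels are
publicly deposited, the package ships seeded generators that emulate both
data sources with the statistical structure the estimators assume, so that
every stage is testable by parameter recovery.

## Estimators

### Exposure scale

Homocysteine is right-skewed, so the analysis scale is natural-log
concentration standardized to SD units (`standardize_log_exposure`). The
sample SD (n − 1 denominator) is used — a deliberate choice, since either
convention is defensible and they differ negligibly at n ≈ 3700. Grouped
(e.g. sex-specific) standardization is available, matching the convention
of the homocysteine GWAS; overall standardization is the default.

### One-sample arm

Writing $y$ for blood pressure (mm Hg), $z$ for standardized log
homocysteine and $g \in \{0,1,2\}$ for T-allele dosage:

* `ols_fit` — the observational estimate: OLS of $y$ on $z$ with optional
  covariates, classical SEs, t-based 95% CIs.
* `tsls_fit` — two-stage least squares. Stage one regresses $z$ on $g$
  (plus covariates); stage two regresses $y$ on the fitted values. The
  coefficient SE uses the IV variance formula with residuals
  $y - X\hat\beta$ computed from the *original* exposure, not the
  stage-two plug-in residuals — the plug-in residuals understate the error
  variance. With a single instrument and no covariates the estimate equals
  the Wald ratio $\mathrm{cov}(g,y)/\mathrm{cov}(g,z)$ exactly, which the
  tests assert to 1e-10 against a brute-force moment oracle. First-stage
  diagnostics report the instrument's partial F and partial $R^2$; partial
  F < 10 logs a weak-instrument warning (the emulated study sits at
  F ≈ 208, far from that regime).
* `dwh_test` — the Durbin–Wu–Hausman endogeneity test in control-function
  form: add the first-stage residual to the outcome OLS and test its
  coefficient against zero (squared t with (1, n − p) df). This is
  asymptotically equivalent to the classical contrast form
  $(\Delta\beta)^2/\Delta\mathrm{Var}$ but numerically stable when the
  variance difference is near zero.
* `covariate_balance` — the instrument-validity check: genotype class as a
  3-level multinomial outcome of each covariate, likelihood-ratio p-value,
  optionally with ancestry scores in both models. The multinomial
  likelihood is maximized by `nnet::multinom`.

Sex-stratified estimates are produced by subsetting, not interaction
terms. Missing data are handled by complete-case analysis only. CIs use the
t distribution with residual df (at n ≈ 3700 this differs from the normal
multiplier only in the third decimal).

### Two-sample arm

With harmonized per-allele effects $X_k$ (SD log-exposure) and $Y_k$
(mm Hg), $Y_k$ having SE $\sigma_{y,k}$:

* `harmonize` — re-orients every record to the exposure-increasing allele:
  records with $X_k < 0$ have alleles swapped and both betas negated.
  Records with $X_k = 0$ are excluded (orientation undefined). Palindromic
  (A/T, G/C) records are flagged but retained — no exclusion rule is
  imposed, and strand inference from allele frequency is out of scope.
* `ivw_single` — the Wald ratio $Y/X$ with first-order SE $\sigma_y/|X|$.
  The exposure-side SE is ignored by construction (the strong-instrument
  first-order approximation); a delta-method SE including it is available
  behind `delta_se = TRUE` and is always at least as large.
* `ivw_multi` — the fixed-effects inverse-variance-weighted estimator
  $$\hat\beta_{IVW} = \frac{\sum_k X_k Y_k \sigma_{y,k}^{-2}}
  {\sum_k X_k^2 \sigma_{y,k}^{-2}}, \qquad
  \mathrm{SE} = \Big(\sum_k X_k^2 \sigma_{y,k}^{-2}\Big)^{-1/2},$$
  algebraically identical to a fixed-effects meta-analysis of the per-SNP
  Wald ratios and to weighted regression of $Y$ on $X$ through the origin.
  The tests assert the meta-analysis identity to 1e-10.
* `fixed_effects_meta` — inverse-variance pooling with Cochran's Q and
  $I^2 = \max(0, (Q - df)/Q) \times 100$, floored at zero.
* `egger_regression` — MR-Egger: weighted least squares of $Y_k$ on $X_k$
  *with* an intercept, weights $\sigma_{y,k}^{-2}$. Under the InSIDE
  assumption (instrument strength independent of direct effects) the slope
  is a consistent causal estimate even under directional pleiotropy, and
  the intercept estimates the average direct effect per allele. 95% CIs
  come from a 10,000-iteration percentile bootstrap; because the intercept
  is only meaningful when all effects refer to exposure-increasing
  alleles, the function refuses un-harmonized panels.

IVW and Wald-ratio CIs use the 1.96 normal multiplier (large-sample summary
statistics); Egger analytic CIs use the t distribution on k − 2 df. All
p-values are two-sided and no multiple-testing correction is applied (none
belongs to this analysis plan).

### Bootstrap scheme

The published description of Egger bootstrapping says only "10,000
iterations, percentile method", which leaves the resampling unit open. The
default here is nonparametric resampling of the k SNP records with
replacement; a parametric alternative (redraw $Y_k \sim N(\hat Y_k,
\sigma_{y,k})$ at fixed $X$) is available via `scheme = "parametric"`.
Neither is asserted to be "the" published variant; with k = 18 the two give
similar but not identical intervals, and both are surfaced in the result
object together with the analytic t intervals. Resamples in which all
$X_k$ coincide (slope unidentified) are discarded and redrawn. A note on
Monte-Carlo error: a percentile endpoint estimated from $B = 10^4$
resamples has standard error ≈ 0.027 × SE of the coefficient, so
seed-to-seed endpoint differences of a few percent of the SE are expected
and not a defect.

## The synthetic-data generators

### Cohort generator (`simulate_cohort`)

The generative model is, per individual:

$$g \sim \mathrm{Binomial}(2, q_s), \quad C \sim N(0,1), \quad
\log x = \mu + b_g g + b_{cx} C + \varepsilon_x,$$
$$y = \alpha + \beta \, z(\log x) + b_{cy} C + \delta g +
\mathrm{offset}_s + \varepsilon_y,$$

where $s$ indexes ancestry strata, $z(\cdot)$ standardizes using the
model's *theoretical* log-exposure moments (so the causal effect $\beta$ is
expressed exactly in mm Hg per SD), $\delta$ is horizontal pleiotropy
(default 0), and both SBP and DBP are generated with the same structure and
independent noise (DBP residual SD is scaled to 0.75 of SBP's, matching the
narrower DBP spread).

Default calibration emulates the target study's published margins:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 3701 | complete-case sample size |
| `allele_freq` | 0.31 | T-allele frequency from the genotype distribution 47.9/43.0/9.1%: (0.430 + 2×0.091)/2 |
| `target_r2` | 0.053 when set | first-stage variance share (F ≈ 208 at this n) |
| `exposure_log_mean` | log 8 | geometric mean ≈ 8 µmol/L |
| `mean_sbp`, `mean_dbp` | 117.4, 73.4 | cohort means, mm Hg |
| `confounder_beta_x`, `confounder_beta_y` | 0.15, 2.0 | chosen so the null-causal observational slope is ≈ +1 mm Hg/SD: slope = $b_{cy} b_{cx}/\mathrm{sd}(\log x)$ ≈ 2×0.15/0.30 |
| `noise_sd_x` | 0.25 | log-exposure residual SD; with the confounder this gives sd(log x) ≈ 0.30, a realistic coefficient of variation for homocysteine |
| `noise_sd_y` | 11 | blood-pressure residual SD, mm Hg |

The study does not publish its homocysteine SD or its confounder
structure, so the last three rows are free parameters fixed once at
field-realistic values; nothing downstream assumes them beyond the ≈ +1
observational slope they induce. When `target_r2` is set, the per-allele
effect is solved analytically from the variance decomposition
(`solve_instrument_beta`), which pins the first-stage strength in
expectation; the per-seed realized $R^2$ then fluctuates with sampling
noise (SD ≈ 0.007 at n = 3701).

Population stratification is modeled as discrete strata with
allele-frequency and outcome offsets, a categorical covariate (`skin`)
that tracks stratum with 15% misclassification, and an observed ancestry
score `pc1` (stratum indicator plus N(0, 0.1) noise) standing in for
genome-wide principal components. The score's noise is deliberately small:
genome-wide PCs separate continental ancestry nearly perfectly, and the
emulated phenomenon — a genotype–covariate association that vanishes after
ancestry adjustment — requires the proxy to capture the stratum almost
completely.

What the generator does **not** emulate: linkage disequilibrium,
imputation error, genotyping batch effects, non-normal blood-pressure
tails, measurement error in the exposure, or folate-dependent effect
modification. Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to those features of
real data.

### Panel generator (`simulate_two_sample_summary`)

Per SNP: $X_k \sim U(0.03, 0.16)$ SD/allele (the span of a genome-wide
significant homocysteine panel),
$\alpha_k = \mu_p + \sigma_p(\rho \tilde X_k + \sqrt{1-\rho^2} Z_k)$ the
direct effect with optional InSIDE violation $\rho$, and
$Y_k = \beta X_k + \alpha_k + N(0, \sigma_y)$ with $\sigma_y = 0.08$
mm Hg/allele (the scale of a > 69,000-participant blood-pressure GWAS;
$\sigma_x = 0.01$). A configurable fraction of records (default 30%) is
stored on the exposure-decreasing allele so harmonization is always
exercised. The directional-pleiotropy recovery scenario used in tests and
the acceptance script fixes $\mu_p = 0.1$, $\sigma_p = 0.05$, $\rho = 0$:
strong enough to displace IVW by an order of magnitude more than its
Monte-Carlo error while Egger remains centred.

## Numerical and design choices

* **Closed-form fits.** OLS/2SLS/DWH use QR/Cholesky solves on the model
  matrix (`lm.fit`-grade numerics); Egger and its bootstrap use a
  closed-form weighted-regression kernel, which keeps the 10,000-iteration
  bootstrap inexpensive. Rank deficiency is detected via QR and reported
  with the names of the collinear columns.
* **Degenerate inputs.** Constant exposure → standardization error;
  constant instrument → 2SLS/DWH error; exposure fully determined by the
  instrument (zero first-stage residual variance) → DWH statistic 0,
  p = 1 by construction; single-study meta-analysis → Q = 0, $I^2$ = 0
  with a logged note; empty genotype class → collapse to a 2-class balance
  model with a warning; k < 2 (IVW) and k < 3 (Egger) are errors.
* **Just-identified IV has no mean.** The single-instrument 2SLS estimator
  is a ratio and possesses no finite moments; its sampling centre is
  tracked by the median. The weak-instrument property test (the median
  2SLS estimate drifts monotonically from the causal value toward the
  observational slope as the instrument weakens) is formulated with
  medians for exactly this reason; at the study's F ≈ 208 the distribution
  is effectively normal and means behave.
* **Coverage checks use the analytic Egger CI.** Nominal-coverage
  simulation (the intercept CI covering 0 in ~95% of null panels) is run
  with the analytic t interval, whose coverage is exact under the
  generator's homoskedastic weights; bootstrapping 10,000 resamples inside
  a 1000-panel simulation would dominate the suite's runtime without
  changing what is being verified.
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state; `run_pipeline` threads one seed through
  simulation and bootstrap, records a config hash (xxHash of the full
  config) in the report and log, and identical configs produce
  byte-identical serialized reports.
* **Figures** are deterministic given the report (fixed ordering, no
  jitter), SVG where cairo is available and PDF otherwise.

## Problem sizes in the test suite

Simulation-based checks use sizes chosen to keep Monte-Carlo error well
below the asserted margins: 1000 18-SNP panels for IVW/Egger recovery
(Monte-Carlo SE of the IVW mean ≈ 0.006 against a 0.01 bias bound), 500
cohorts at the full n = 3701 for one-sample recovery (3-MC-SE bands), 1000
replicates for DWH size and balance-test uniformity, and 50-replicate
loops for the 1e-10 algebraic-identity oracles, where sampling noise is
irrelevant. The acceptance script re-runs the same designs at 200–500
replicates and reports the realized values.

## Known limitations

* The IVW SE deliberately ignores exposure-side uncertainty; with the
  weakest SNPs of a panel contributing $X_k$ near 0.03 SD/allele this is
  an approximation, mitigated by the optional delta-method SE.
* Palindromic SNPs are flagged, not resolved; with real strand-ambiguous
  data the caller must resolve strands upstream.
* `covariate_balance` treats the covariate as a predictor of the 3-class
  genotype; the reverse parameterization (genotype predicting the
  covariate) tests a related but not identical hypothesis.
* One confounder and one ancestry score are the minimal structure that
  makes OLS biased, 2SLS unbiased, and ancestry adjustment effective; real
  confounding is higher-dimensional.
* Robust (HC0) 2SLS SEs exist behind a flag but classical homoskedastic
  SEs are the default and the tested path, matching conventional reporting.
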