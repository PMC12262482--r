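---
title: "Mass-univariate mega- and meta-analysis with per-voxel missingness"
author: "voxelmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mass-univariate mega- and meta-analysis with per-voxel missingness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-site neuroimaging consortia pool thousands of per-subject statistic
volumes (for example seed-based resting-state connectivity Z maps) that have
been preprocessed and normalized to a common grid. Two practical obstacles
dominate group-level analysis at this scale. First, voxel-level data are
missing non-uniformly: signal dropout near air–tissue interfaces, motion,
partial coverage, and site-specific acquisition differences leave each voxel
observed in a different subset of subjects. Pipelines that demand complete
data either discard subjects or discard voxels, losing power and biasing the
spatial extent of reported effects; the correction for multiple comparisons
is then applied over fewer voxels than the brain actually contains. Second,
site heterogeneity requires either stratified (meta-analytic) modeling or a
pooled model with a site random effect, which most voxelwise tools do not
offer at scale.

voxelmeta implements both strategies around a single available-case engine:
at every voxel the configured regression model is fit on exactly the
subjects with observed data there, so the effective sample size and degrees
of freedom vary across the brain and are themselves reported as maps.

## Models and inference

The central model surface is the per-voxel regression

* `Brain ~ Age + Sex + Dx` — Gaussian fixed-effects (OLS), fit by
  closed-form least squares in compiled code;
* `Brain ~ Age + Sex + Dx + (1|Site)` — linear mixed model with a site
  random intercept, fit by REML through `lme4::lmer()`;
* non-Gaussian outcomes via `glm()` (binomial, Poisson).

For fixed-effects models the per-term statistic is `estimate / SE` referred
to Student's t on `n_obs − p` degrees of freedom, where `n_obs` is the
voxel's own observed count. For mixed models the Wald statistic
`estimate / SE` is referred to the standard normal and reported as a signed
Z. A degrees-of-freedom correction (e.g. Satterthwaite) is deliberately out
of scope in this version: with site counts in the tens and subjects in the
thousands the normal reference is standard practice, and the choice is
surfaced here rather than hidden. Signed Z values for all estimators are
derived from the two-sided p-value in log space
(`z = sign(estimate) * qnorm(log(p) - log 2, log.p = TRUE, lower = FALSE)`),
which survives p-values far below double underflow.

Features are skipped — with a recorded reason, never fabricated zeros —
when `n_obs < p_fixed + 3` (a floor that prevents meaningless fits; the
varying-df design itself has no natural floor), when the response is
constant, when the design is rank-deficient on the observed subset, or when
a mixed fit fails to converge. Iterative fits use a relative tolerance of
1e-8 with at most 100 iterations.

Covariates are used as supplied: no centering or standardization is applied,
and text covariates expand through standard treatment contrasts with the
lexicographically first level as reference. Both choices are documented
rather than silently imposed.

### Mega vs meta

`runMega()` pools all subjects in one model (optionally with the site random
intercept). `runMeta()` stratifies: the fixed-effects model is fit per site
(sites below 10 subjects, configurable, are excluded; sites whose design is
rank-deficient for the model — e.g. a single-sex site in a Sex model — are
skipped with a logged reason), and site results are combined feature-wise:

* **Stouffer** (default): `Z = Σ w_i z_i / sqrt(Σ w_i²)` on signed per-site
  Z values; unweighted uses `w = 1`, weighted uses `w = sqrt(n_i)` with the
  voxel-level per-site `n_i`. The literature states sample-size weighting
  without the functional form; `sqrt(n)` is the standard inverse-variance
  analogue and `w = n` is selectable.
* **Fisher**: `X² = −2 Σ log p_i` on `2k` degrees of freedom, applied to
  two-sided p-values. Fisher's method is direction-blind while Stouffer's
  signed combination lets opposite-sign sites cancel; this behavioral
  difference is intrinsic to the methods and documented rather than hidden.

A site missing at a voxel simply drops out there; `k`, the number of
contributing sites, is itself a reported map.

## Multiple-comparison correction

`fdrCorrect()` applies Benjamini–Hochberg over the features actually tested
(finite p), so skipped voxels never dilute the correction; because the
engine tests every in-mask voxel, `m` equals the in-mask count.

`ptfce()` implements probabilistic threshold-free cluster enhancement: a
ladder of cluster-forming thresholds spans the observed Z range; at each
threshold suprathreshold clusters are labeled (26-connectivity) and each
member voxel receives the posterior probability that its height exceeds the
threshold given the observed cluster size, built from Gaussian-random-field
expectations (expected suprathreshold volume; expected cluster count from
the Euler-characteristic densities with the mask's resel counts; an
exponential-form cluster-size distribution matched to the expected size).
Per-threshold `−log` probabilities are summed and converted back to an
enhanced Z. Numerical choices, all exposed as arguments:

* **Threshold ladder.** 100 thresholds, equidistant on the `−log p` scale.
  On this ladder the aggregation
  `−log p = (sqrt(Δ² + 8ΔS) − Δ)/2` is the exact inverse of the accumulated
  null ladder: a voxel whose per-threshold probabilities equal the
  unconditional Gaussian tails maps back to exactly its raw Z, so
  enhancement is measured against a fixed, self-consistent anchor.
* **GRF-validity cutoff** (`zStart = 1.3`). Below roughly Z ≈ 1.3 the
  excursion set of a smooth field percolates into one giant component and
  random-field cluster-size theory does not describe it; those thresholds
  contribute the unconditional tail instead of cluster-conditional
  evidence.
* **Discretization.** The continuous-field expected cluster size is
  augmented by one voxel, since a lattice cluster is never sub-voxel.
* **Smoothness.** When no FWHM is supplied it is estimated from the map's
  per-axis lag-1 spatial autocorrelation
  (`FWHM = sqrt(−2 log 2 / log ρ)`), the natural source when residual maps
  are unavailable.
* **FWER threshold.** The familywise threshold solves `E[EC](u) = 0.05`
  with the cuboid resel counts, then applies a first-order lattice
  correction `u ← u (1 − Σ λ_i / 24)` with `λ_i = 4 log 2 / FWHM_i²`: a
  continuous peak generally falls between voxel centers, and under a
  quadratic peak approximation with a uniform sub-voxel offset the sampled
  maximum is lower than the continuous one by exactly that expected factor.
  Without this correction the threshold is visibly conservative at
  moderate smoothness.

Exact numerical agreement with other implementations of the published
enhancement procedure is not claimed; the construction above is validated
internally by a Monte-Carlo null calibration (500 smooth null fields at
40³, FWHM 3) in the test suite.

`extractClusters()` reports maximal connected components above a cutoff
(default Z ≥ 3.1, the common display threshold; one-sided per sign),
sorted by size with peak |Z| as tie-break, under 26- (default), 18- or
6-connectivity.

## Conjunction rules

`conjunctionMap()` compares two or more aligned signed-Z maps: `overlap`
(logical AND at a threshold, with a bitmask label recording which inputs
pass), `minimum` (the minimum statistic; membership provably identical to
overlap at the same threshold), `conjunction_null` (the minimum-statistic
rule reported as a test that all effects are non-null — numerically the
minimum map, inferentially a different claim), `global`
(`Σ Z_i / sqrt(k)`, a Stouffer-style average so consistent moderate effects
can pass), and `probabilistic` (`Π(1 − p_i)` on one-sided p-values, a
graded score). The source descriptions of the last two name no formula;
the concrete forms here are this package's documented interpretations. All
rules operate one-sided per direction — positive and negative conjunctions
are computed separately, because mixing signs makes "agreement"
ill-defined.

## The synthetic benchmark

`simConfig()` defaults encode the benchmark's study conditions: 1,000
subjects as 50×50×50 standard-normal noise volumes (125,000 voxels); a
central spherical signal region of radius 4 voxels; a binary diagnosis with
50% prevalence; `+0.2` added at signal voxels for cases (Cohen's d = 0.2
against unit noise). The sphere uses the strict lattice rule (distance
*strictly* below the radius): with an integer-voxel center this yields
exactly 251 voxels at radius 4, whereas `<=` would give 257.

`injectMissingness()` applies per-voxel MCAR: at every voxel independently
a uniformly random `round(m·n)` subjects are removed, so each voxel's
observed n is exactly `(1−m)·n` — matching a per-level performance curve
interpretation; listwise (whole-subject) deletion is available behind a
flag. `scoreROC()` ranks voxels by the signed case-greater statistic
(one-sided; this direction is what makes the sensitivity claim consistent
with the noncentrality `d·sqrt(n/4)`); AUC is the Mann–Whitney pairwise
probability with ties counted half, and sensitivity at 5% FPR is the
fraction of signal voxels above the empirical 95th percentile of null
statistics. Complete-case analysis, as a comparator, drops every voxel
with at least one missing subject — under per-voxel MCAR with n in the
hundreds, that is every voxel as soon as `m > 0` — with dropped signal
voxels counted as misses.

### What the generator does and does not emulate

It reproduces iid Gaussian noise, a compact homogeneous effect, exact
per-voxel MCAR and a balanced two-group design. Real data differ: spatial
autocorrelation (the simulator's voxels are independent), site-structured
and spatially patterned missingness (MCAR is the stated benchmark
mechanism, not a realism claim), heterogeneous effect sizes, and covariate
confounding. Passing benchmarks therefore validate the engine's ranking
and its behavior under missingness — not robustness to structured
missingness or unmodeled confounding.

### Problem sizes used in the tests

The test suite exercises the full benchmark grid (1,000 × 125,000) only in
the two headline checks; property tests run on scaled cohorts (tens of
subjects, grids up to 16³, sweeps at n = 400) chosen so each block carries
its Monte-Carlo tolerance comfortably while the whole suite stays quick.
The pTFCE null calibration uses 500 replicates of 40³ fields at FWHM 3,
with the acceptance band from the binomial 95% interval around 0.05.

## File-format and layout conventions

Images are NIfTI-1 (`.nii`/`.nii.gz`, via RNifti); all volumes in an
analysis must share dims exactly and affines within 1e-4 (no resampling is
performed — inputs are assumed pre-normalized). Flattening order is fixed:
column-major over the analysis mask, first axis fastest, so feature order
is a pure function of (dims, mask). Exact zeros are *valid* statistics and
are not treated as missing unless `zeroSentinel = TRUE` — the containment
of an ambiguity: without a subject mask there is no way to distinguish "0
because outside coverage" from a true zero, so the default never destroys
data and the flag is available when a pipeline is known to zero-fill.
Subject identity is the composite `fID = SiteID_SubjectID`; images live in
site subdirectories and are matched by a literal filename suffix.

Run configuration accepts a YAML text file (canonical, fully tested) or a
tabbed spreadsheet with `data_path` / `data_pattern` / `predictors` /
`models` sheets; both parse to the identical structure — spreadsheet
support is an accessibility feature, not a separate code path. Outputs are
NIfTI maps named `<term>_<kind>.nii.gz` plus `fit_<measure>.nii.gz`
(including `n_obs` always), cluster tables and legends as CSV, and a
static HTML report with per-site demographics, cluster tables, and
orthogonal-slice images.

## Known limitations

* No imputation, FIML, MAR/MNAR mechanisms, longitudinal or survival
  designs; random effects are intercept-only; no permutation inference or
  classical TFCE.
* Mixed-model maps at full voxel counts are fit feature-by-feature through
  `lme4` and are substantially slower than the compiled OLS path.
* The pTFCE null calibration is validated on stationary isotropic fields;
  strongly nonstationary smoothness violates the cuboid resel
  approximation.
* Meta-analysis pools Z statistics, not effect sizes; random-effects
  meta-analysis (e.g. DerSimonian–Laird) is out of scope.
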