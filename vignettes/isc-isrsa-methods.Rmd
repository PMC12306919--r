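---
title: "Intersubject correlation and stress-coupled similarity: models and methods"
author: "iscrsa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersubject correlation and stress-coupled similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscrsa)
```

## The analysis problem

When many people watch the same video in the scanner, regions that track the
stimulus produce time courses that are correlated *across* subjects even
though no model of the stimulus exists. Intersubject correlation (ISC)
quantifies this: for a region of interest (ROI) and a viewing condition, the
Pearson correlation $r_{ij}$ is computed between the ROI time series of every
pair of subjects $i, j$. High pairwise ISC means the stimulus drives a
consistent response; near-zero ISC means responses are idiosyncratic.

Intersubject representational similarity analysis (IS-RSA) asks a second
question: does a *trait* explain who synchronizes with whom? It correlates
two subject-by-subject matrices — the neural ISC matrix and a behavioral
similarity matrix built from trait scores — using a Spearman rank
correlation over their vectorized upper triangles.

The package implements this workflow for a design with three experimental
videos plus one control video, a 16-ROI set of stress-processing regions
defined as 6-mm spheres at MNI coordinates, and a 6-item perceived-stress
scale; all pieces are generic in the number of subjects, ROIs and runs.

## The Anna Karenina similarity model

The behavioral similarity follows the Anna Karenina (AnnaK) structure: all
high-trait individuals are alike, each low-trait individual is idiosyncratic
in their own way. With trait scores min–max normalized to $\tilde s_i \in
[0,1]$, two variants are provided:

* `annak_mean`: $\mathrm{sim}(i,j) = (\tilde s_i + \tilde s_j)/2$ (default),
* `annak_min`: $\mathrm{sim}(i,j) = \min(\tilde s_i, \tilde s_j)$.

Both make a pair of maximally stressed subjects maximally similar and leave
low-stress pairs dissimilar. The AnnaK framework does not prescribe one
formula; both canonical operationalizations are implemented and selected by
a configuration key, with the pair mean as default because it is the milder
assumption (the pair minimum forces *any* pair containing a low-trait
subject to be dissimilar). Min–max normalization over the analyzed sample is
the default because it keeps the "both high implies similar" geometry on an
interpretable 0–1 scale; rank normalization is available
(`normalize = "rank"`) for heavy-tailed traits.

## Inference

**Subject-wise bootstrap for ISC.** The summary statistic is the mean
Fisher-$z$ value over subject pairs, back-transformed to the $r$ scale
(`median_z` available). Significance uses a subject-wise bootstrap: subject
indices are resampled with replacement, the stored $z$ matrix is re-indexed,
and off-diagonal cells that refer to the same original subject are excluded
(including them would inject $r = 1$ self-pairs and mechanically inflate
synchrony). The null distribution is the set of bootstrap summaries
re-centered by their mean, and the two-sided p-value is
$(1 + \#\{|z^{*}| \ge |z_{obs}|\})/(B + 1)$.

A property of this scheme worth knowing: it treats the subject as the
exchangeable unit, so its null spread reflects between-subject variation in
average correlation. When the true pair correlations are essentially
independent — exactly the situation in a null simulation with no shared
signal — that spread overstates the sampling variance of the pair mean by a
factor of about $\sqrt 2$ in standard deviation, and the test is
conservative (empirically, rejection well below the nominal level). With
real fMRI data, where pairs sharing a subject are strongly dependent, the
subject-level spread is the appropriate yardstick; the conservative behavior
under pair independence is the price of that robustness, and it is why the
package's own calibration simulations bound the type-I error from above
rather than asserting nominal attainment.

**Friedman and Wilcoxon across conditions.** Omnibus differences in ISC
across the three videos are tested per ROI with a Friedman test whose
observation unit is the unordered subject pair: each pair contributes one
Fisher-$z$ value per condition, ranked within pair, with tie correction.
Post-hoc video-pair comparisons use the Wilcoxon signed-rank test on the
same pair-level values ($W = \min(W^+, W^-)$, normal approximation with
tie-corrected variance). Pairs sharing a subject are not independent, so
pair-level p-values are anticonservative; the package reports the procedure
as published practice and flags the dependence here rather than modeling it.
The pair-level unit also matches the magnitude of published signed-rank
statistics for this design (values near 850–900 are only attainable with
hundreds of observations, i.e. pairs, not dozens of subjects).

**Mantel-style permutation for IS-RSA.** The IS-RSA score is Spearman's
$\rho$ between the two upper triangles (average ranks for ties). Its p-value
comes from permuting subject labels of the behavioral matrix — rows and
columns jointly — and recomputing $\rho$; permuting triangle entries
independently would break the dependence between entries sharing a subject
and is not offered. Two-sided p with the same $+1$ smoothing. The default
permutation count is 5000, matching the bootstrap count for internal
consistency. How the original analysis obtained IS-RSA p-values is not
documented anywhere we could follow; subject-level permutation is the
standard choice and is a design decision of this package, not a
reconstruction.

**Multiple testing.** Benjamini–Hochberg FDR (via `stats::p.adjust`) is
applied across the ROI family (16 by default) within each analysis; the
cross-video post-hoc family is the significant-ROI × video-pair set.

## ROI geometry

"6-mm" spheres are taken as 6-mm *diameter*, hence radius 3 mm. A voxel
belongs to the mask when its center lies within the radius (inclusive
boundary) — the simplest reproducible convention; any-overlap dialects can
be compared by changing the radius. The affine is authoritative for the
voxel-to-mm mapping (NIfTI convention, 0-based indices); no axis-flipping
heuristics are applied. Spatial reduction over mask voxels is the unweighted
mean, the most common default where the original report is silent; the first
eigenvariate is deliberately not implemented. The bundled 16-ROI table
stores published coordinates exactly as printed, including two internally
inconsistent entries (a left amygdala at $z = +14$ mirroring a right
amygdala at $z = -14$, and one left/right label pair whose $x$ signs are
swapped); the CSV comments flag them, and repeated region names carry a
numeric suffix because labels must be unique.

## The synthetic generator

No participant data accompany the design this package targets, so every
stage is validated against a generator with known ground truth
(`synthetic_config()`, `generate_timeseries()`, `generate_dataset()`).

**Neural model.** Subject $i$'s series in ROI $v$, run $r$ is

$$x_{i}(t) = \sqrt{w_i}\, c(t) + \sqrt{1 - w_i}\,\varepsilon_i(t),$$

with a common stimulus-locked signal $c$ per ROI and run, idiosyncratic
noise $\varepsilon_i$, both stationary unit-variance Gaussian AR(1)
processes, and

$$w_i = \mathrm{clip}\big(w_0 + \beta\,\tilde s_i,\ 0,\ 0.95\big),$$

where $\tilde s_i$ is the subject's latent stress min–max normalized to
$[0,1]$. The closed-form oracle $\mathbb E[r_{ij}] = \sqrt{w_i w_j}$ drives
the parameter-recovery tests. Choices and rationale:

* **AR(1) with coefficient 0.3** on both signal and noise mimics fMRI
  temporal smoothness. ISC itself is insensitive to shared temporal
  autocorrelation, but resampling-based inference is not, so calibration
  tests run under autocorrelation rather than white noise.
* **Clipping at 0.95** keeps generated pairs away from $r = 1$, which would
  be degenerate under the Fisher transform.
* **Min–max normalization of stress before coupling** keeps the clipping
  interpretable: $\beta$ is exactly the weight range swept across the
  sample. A constant stress vector maps to the midpoint 0.5.
* **$\beta = 0$ by default**: the default dataset embodies the
  no-stress-coupling regime; AnnaK-structured synchrony is switched on
  explicitly in power simulations.
* **Default $w_0 = 0.05$**: published concatenated ISC values for this ROI
  set are of order 0.005–0.013; 0.05 keeps default simulations in the weak-
  synchrony regime while remaining comfortably detectable at simulation
  sizes.

**Behavioral model.** The 6 Likert items come from a single-factor
equicorrelated Gaussian ($y_{ik} = \sqrt\rho\, u_i + \sqrt{1-\rho}\,
e_{ik}$) discretized at equal-probability normal cut points into 1..5.
Discretizing attenuates correlations; the generator corrects the latent
$\rho$ by the analytic first-Hermite factor
$\big(\sum_j \phi(\tau_j)\big)^2 / \mathrm{Var}(\text{categories}) \approx
0.888$ for five levels, so the *observed* inter-item correlation matches the
request and Cronbach's $\alpha$ follows the Spearman–Brown prophecy
$k\bar r/(1 + (k-1)\bar r)$. The default `interitem_corr = 0.4` therefore
yields $\alpha \approx 0.80$ with six items. Post-experiment variables
(viewing frequency skewed low, familiarity rates near 71/11/5 percent,
even willingness split) mirror typical self-report distributions for this
population.

**What the generator does not emulate.** No hemodynamic response model, no
voxel-level spatial structure (series are generated at the ROI level), no
motion or physiological artifacts, no inter-ROI correlation beyond what the
per-ROI shared signals induce, and Gaussianity throughout — the generator is
a stand-in for the statistical structure the analysis assumes, not a claim
about real data. Passing recovery tests therefore demonstrates correctness
of the estimators under their own assumptions, not robustness to realistic
artifacts.

## Numerical conventions

* Correlations are clipped to $\pm(1 - 10^{-7})$ before $\mathrm{atanh}$;
  duplicated series stay finite.
* Ties receive average ranks everywhere (Spearman, Wilcoxon, Friedman).
* All permutation/bootstrap p-values use $+1$ smoothing, so the smallest
  attainable p is $1/(B+1)$ and p never equals 0.
* Every randomized routine takes an explicit seed, restores the caller's
  RNG state, and records the seed in its result; the pipeline derives
  per-stage seeds deterministically from one master seed, so a report is
  reproducible from its manifest.
* Degenerate inputs fail loudly: constant time series name the subject,
  constant trait vectors refuse normalization, all-zero difference vectors
  warn and return p = 1, fully tied Friedman input returns $\chi^2 = 0$.
* A fully tied resample in the bootstrap (all off-diagonal cells excluded)
  is redrawn and counted in the result.

## Problem sizes used by the test-suite simulations

Parameter recovery uses 30 subjects at 540 time points (10 replicate
datasets); bootstrap calibration uses 200 null datasets of 20 subjects ×
200 time points with 1000 iterations; IS-RSA power uses 50 datasets of 40
subjects × 300 time points with weights spanning 0.05–0.45 and 500
permutations; null calibration uses 200 datasets of 25 subjects × 150 time
points; cross-video detection uses 50 datasets of 30 subjects × 16 ROIs ×
3 runs of 180 time points. These sizes were chosen so each check has clear
statistical resolution while the full suite runs in a couple of minutes on
one core.

## Known limitations

* Pair-level Friedman/Wilcoxon p-values ignore pair dependence
  (anticonservative); they replicate published practice and are labeled as
  such.
* The subject-wise bootstrap is conservative when pair correlations are
  nearly independent (see above).
* Listwise exclusion is the only missing-data policy for behavioral items;
  no imputation is offered, and reports carry explicit denominators.
* Group ISC comparisons require at least 3 subjects per group and refuse to
  run otherwise — small familiarity subgroups are reported as skipped, not
  estimated.
* No leave-one-out ISC, voxel-level ISC maps, sliding-window ISC, or
  partial-Mantel covariate adjustment.

## A minimal worked run

```{r example, eval = FALSE}
cfg <- analysis_config(
  input = "synthetic",
  synthetic = synthetic_config(n_subjects = 24, run_lengths = rep(120L, 4),
                               n_rois = 4, base_shared_fraction = 0.10,
                               annak_coupling = 0.3, seed = 7L),
  n_bootstrap = 1000L, n_permutations = 1000L, seed = 7L)
bundle <- run_pipeline(cfg)
bundle$isc_table        # per-ROI concatenated ISC with bootstrap p and q
bundle$isrsa_table      # Spearman rho per ROI x condition with Mantel p, q
bundle$friedman_table   # cross-video omnibus per ROI
```
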