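---
title: "Methods: threshold-based muscle quantification and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold-based muscle quantification and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

`musclemap` quantifies abdominal skeletal muscle on a single axial
proton-density fat-fraction (PDFF) map at the level of the lower endplate of
the L3 vertebra. The map carries intensities on a 0–1000 scale that maps
linearly onto 0–100 % fat fraction, so intensity 200 corresponds to 20 %
fat. Eight binary compartment masks (left/right psoas major, quadratus
lumborum, rectus abdominis, autochthonous back muscles) are *inputs*:
segmentation itself, manual or automatic, is out of scope and the masks are
trusted.

Three quantities follow from the voxel counts:

* **Total CSA** counts every mask voxel regardless of intensity and
  multiplies by the squared in-plane pixel spacing. Fatty septa inside the
  fascia belong to the muscle's total cross-section by definition.
* **Fat-free CSA** applies the threshold rule
  $CSA_{ff} = CSA_{tot} \cdot N_{\le 200} / N_{\le 1000}$. The biological
  assumption is a two-class voxel model: even myocytes loaded with
  intramyocellular lipid stay at or below ~20 % fat fraction, so any voxel
  above the threshold must contain extramyocellular adipose tissue and is
  excluded. We read the comparison inclusively (a voxel exactly at 200 is
  fat-free) because the excluded class is described by exceeding the
  threshold. The denominator $N_{\le 1000}$ is the count of voxels at or
  below the top of the intensity scale; intensities are clamped to
  [0, 1000] on ingest (with a logged count of clamped voxels), so it equals
  the full mask count and the rule reduces to counting fat-free voxels.
* **Myosteatosis** ($PDFF_{muscle}$) is the mean fat fraction over the
  *total* mask, septa included — it is defined on the same segmented
  compartments as the area measures, not on the fat-free subset. Whether
  the original workflow excluded septum voxels is not documented; we record
  the inclusive reading as a design choice rather than assert it.

Areas are normalized to body height squared (AMMI, mm²/m²), heights being
carried in metres; the Janssen BIA equation uses centimetres internally,
matching each formula's printed units. Only in-plane spacing enters CSA;
slice thickness never does. The ratio $100 \cdot AMMI_{ff} / AMMI_{tot}$
summarizes the contractable fraction; note that the ratio of two cohort
*means* differs from the cohort mean of per-subject ratios — the package
always reports the latter at cohort level.

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| `threshold` | intensity (0–1000) | 200 | 20 % fat; upper bound of intramyocellular lipid |
| `pixel_spacing` | mm | 1.5 | plausible in-plane resolution for a 256×256 abdominal matrix; carried as metadata, never hard-coded |
| `grid_size` | voxels | 256 | matches the acquisition matrix |
| `septum_fat_fraction_range` | % | (20.2, 33) | septa must exceed the 20 % threshold by definition; see below for why the mass hugs the threshold |
| `obese_fraction` | — | 95/335 | emulated cohort's stratum weights |
| `male_fraction` | — | 136/240, 52/95 | per-stratum sex weights |

## What the synthetic generator emulates

Individual-level data from the emulated population study are not public, so
the generator is the package's data substrate and is itself first-class,
tested code. It emulates:

* **Stratified marginals.** Four cells (obesity × sex) with obesity-split
  means/SDs for anthropometry, BIA indices and adiposity, and additionally
  sex-split marginals for the MRI indices, where the study tables print
  them. Sampling is two-stage: stratum first (obese with probability
  95/335, sex with the stratum's male fraction), then the continuous
  vector from a Gaussian copula.
* **Correlation structure.** Within-stratum correlation targets are chosen
  so that the *pooled* cohort-level Pearson correlations land on the
  published concordance values (e.g. total index vs lean body mass index
  r ≈ 0.70; fat-free index vs BIA muscle index r ≈ 0.58), with distinctly
  stronger within-stratum coupling in non-obese than obese cells. The
  pooled correlation decomposes into within-cell covariance plus
  between-cell mean structure; the within-cell targets were solved from
  that decomposition analytically before any acceptance check was run.
* **Mutual consistency of derived fields.** BMI comes from a
  moment-matched truncated normal on the correct side of the 30 kg/m²
  cut-off, so the obese *flag* (BMI rule) and the obese *stratum* agree by
  construction and the expected flagged fraction is exactly 95/335.
  Weight is BMI × height²; the BIA resistance is obtained by algebraically
  inverting the Janssen equation so the stored muscle index is reproduced
  by the forward equation to machine precision.
* **Per-subject images.** Each subject's targets (total CSA, fat-free
  ratio, muscle PDFF) are drawn inside the copula jointly with
  anthropometry, then rendered: eight disjoint filled ellipses (exact voxel
  counts by largest-remainder allocation and radius-ordered selection),
  septum voxels grown as contiguous clusters around random seeds, and
  intramyocellular intensities drawn from a bounded Beta on [0, 200] whose
  mean is solved in closed form so the mask-wide mean matches the target
  PDFF.

Features of real data it does **not** emulate: partial-volume effects at
muscle boundaries, fat–water swaps and motion artefacts, anatomic mask
shapes, inter-observer segmentation variability, 3-D context, and any
non-Gaussian marginal shape beyond the truncations described. Passing
tests therefore demonstrate that the *quantification and statistics* are
correct and that the generator is calibrated — not that the pipeline is
robust to real-world image degradation.

## Numerical choices

* **PSD reconciliation.** The raw correlation targets (printed pairs plus
  physiologically plausible fillers) form an indefinite matrix. We make it
  positive semi-definite by Dykstra alternating projections between the PSD
  cone and the affine set that fixes the unit diagonal and the 15
  calibration-critical pairs, so the targeted entries are preserved exactly
  while neutral fillers absorb the adjustment. User-supplied matrices are
  handled by plain eigenvalue clipping (projection to the nearest PSD
  correlation matrix).
* **Transform attenuation.** Truncated-normal marginals (BMI at the
  obesity cut-off; VAT/SAT at zero) are monotone transforms of the latent
  Gaussian, which attenuates Pearson correlations. The latent matrix is
  pre-compensated by each margin's attenuation factor
  $\lambda = \mathrm{cor}(g(Z), Z)$, computed by quadrature, and
  re-projected to PSD.
* **Septum feasibility.** Under the two-class voxel model a (ratio, PDFF)
  pair is only attainable if the septum contribution
  $(1 - ratio) \cdot \bar{f}_{sep}$ does not already exceed the target
  PDFF. The septum distribution mean is therefore solved per subject
  within the configured range (always above 20 %); pairs that remain
  infeasible even with septa at the bottom of the range are resolved by
  moving the PDFF to the nearest feasible value. Every projection is
  logged per subject and aggregated into the run manifest, mirroring how a
  real pipeline must surface quality events rather than silently proceed.
  At the default calibration roughly a quarter of subjects carry such
  inherently infeasible drawn pairs — a direct consequence of printed
  cohort means sitting close to the feasibility boundary.
* **Voxel rounding.** The voxel budget is `round(CSA / s²)`, so generated
  slices reproduce the target CSA to within one voxel area; septum counts
  are `round((1 - ratio) · V)`, bounding the recovered ratio error by
  1/(2V).
* **Degenerate inputs.** Constant variables, empty strata and too-few
  cases produce warnings and NA rows in the report tables instead of
  errors; empty masks make the total CSA zero with a warning but the mean
  PDFF an error (an undefined mean, not a zero quantity).

## Statistical conventions

Group comparisons default to the Welch unequal-variance t-test (a
`student` switch restores the pooled test) and to the χ² test without
continuity correction for 2×2 counts. Standardization subtracts the mean
and divides by the sample SD (n − 1); the binary sex indicator is
standardized like any other covariate in adjusted models. Confidence
intervals are Wald intervals with t critical values on the residual
degrees of freedom. Missingness is handled complete-case per analysis.
Bonferroni adjustment is the plain multiplication rule, applied where the
report tables are stratified by sex (three tests). Unadjusted standardized
simple regression equals the Pearson correlation, which the test suite
asserts to 1e-12; all fits are checked against an explicit
normal-equations oracle.

The generator calibrates *unadjusted* correlations only. Age- and
sex-adjusted standardized estimates depend on the real covariance of each
measure with age and sex, which the published tables do not fully
determine; the package computes them but makes no claim that their values
match the study's adjusted estimates.

## Problem sizes used by the test suite

Calibration checks average 10 cohorts of n = 10 000 (marginals and
within-cell correlations) and 20 end-to-end image cohorts of n = 335
(cohort statistics); the statistical-validity simulations use 2000
replicates at n = 335. These sizes keep Monte-Carlo error a factor of
several below each asserted tolerance.

## Known limitations

* The two-class intensity model cannot represent subjects whose printed
  (ratio, PDFF) combination is infeasible; the feasibility projection
  biases the realized cohort mean PDFF slightly upward relative to the
  drawn targets.
* Heights are obesity-stratified but sex-blind (the source tables print no
  sex-split heights); a modest within-cell height–index correlation
  compensates at the CSA level.
* Adjusted-regression estimates are exploratory outputs, not calibrated
  targets.
* Single-slice, single-timepoint: no 3-D volumes, no longitudinal change,
  no sarcopenia classification or cut-off derivation.
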