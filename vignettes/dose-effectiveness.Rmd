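---
title: "Per-fraction dose effectiveness in gated lung radiotherapy: models, features and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-fraction dose effectiveness in gated lung radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eudgate)
```

## The problem

In image-guided, exhale-gated radiotherapy of locally advanced lung cancer,
the clinical target volume (CTV) is deformed a little differently at every
treatment fraction. The planned dose distribution is optimized on a planning
target volume (PTV) — the CTV plus a setup margin, typically 5 mm — so small
residual deformations are harmless, but occasionally a part of the CTV
drifts into the dose falloff and the fraction delivers a markedly less
effective dose. `eudgate` implements the analysis chain that quantifies this:
per-fraction effectiveness measures, geometric deformation features,
deformable dose accumulation, and cross-validated models that ask which
features predict a cold fraction.

Because clinical imaging cannot be redistributed, the package ships a seeded
synthetic cohort generator that reproduces the statistical structure of such
a treatment series; every stage of the pipeline runs on it end to end.

## Effectiveness measures

Both measures operate on the dose-volume histogram (DVH) of the deformed
CTV under the *static dose cloud* approximation: the planned dose
distribution is assumed spatially fixed while the anatomy moves through it
(the package's gamma-analysis utilities exist to check exactly this
approximation).

**Power-law gEUD.** For differential DVH volume fractions $v_i$ at doses
$D_i$,
$$\mathrm{gEUD} = \Big(\sum_i v_i D_i^{a}\Big)^{1/a}, \qquad a = -20
\text{ for tumor,}$$
the generalized power mean. With $a = -20$ cold spots dominate: gEUD lies
between the minimum and the mean dose and approaches $D_\min$ as
$a \to -\infty$. `compute_dvh()` stores the exact mean dose per bin, so the
identity $\mathrm{gEUD}(\text{uniform } D) = D$ holds to floating-point
accuracy rather than to bin resolution.

**Cell-survival EUD.** The surviving fraction per fraction of dose $d$
follows the linear-quadratic model parameterized by the survival at the
reference fraction dose $d_{\mathrm{ref}} = 2$ Gy:
$$s(d) = \mathrm{SF}_2^{\;(d/d_{\mathrm{ref}})\,
  \frac{\alpha/\beta + d}{\alpha/\beta + d_{\mathrm{ref}}}},
  \qquad \alpha/\beta = 4\ \mathrm{Gy}.$$
Repeating the fraction's dose distribution for a standardized course of
$n = 30$ fractions gives the course survival
$S = \sum_i v_i\, s(d_i)^{n}$, and `eud_sf()` returns the uniform total dose
with the same survival, found by monotone root-finding. The fraction-size
correction is the default; a pure $\mathrm{SF}_2^{d/2}$ scaling is available
(`fraction_size_correction = FALSE`), but note that without the correction
the $\alpha/\beta$ parameter would be inert, so the corrected form is the
one under which quoting $\alpha/\beta = 4$ Gy is meaningful.

$\mathrm{SF}_2$ itself is calibrated from the Poisson tumor control model:
$\mathrm{TCP} = \exp(-N_0 \mathrm{SF}_2^{\,n})$ with $N_0 = 10^8$ clonogens
of uniform density, solved for 50% control at 60 Gy in 2 Gy fractions:

```{r sf2}
calibrate_sf2(tcp_target = 0.5, total_dose = 60, dose_per_fraction = 2,
              n0 = 1e8)
```

## Geometric deformation features

For each fraction $i$ with deformed CTV$_i$ and displacement field $u_i$
(planning $\to$ fraction geometry, mm):

* **HDD$_i$** — the directed Hausdorff distance, realized as the radius of
  the minimal isotropic expansion of CTV$_\mathrm{plan}$ containing
  CTV$_i$. Computed from the Euclidean distance transform of
  CTV$_\mathrm{plan}$ (anisotropic spacing respected in mm), max-sampled
  over CTV$_i$; the achieving voxel is the Hausdorff point HDP$_i$. The
  directed form is used literally: a CTV$_i$ shrinking inside the planning
  CTV has HDD $= 0$.
* **HDP$_\mathrm{worst}$** — HDP of the fraction with the largest HDD over
  the series; $\Delta L_i$-HDP$_\mathrm{worst}$ is $|u_i|$ at that point
  (mapped to planning geometry).
* **PD$_\mathrm{min,global}$** — the fraction $x$ with the smallest minimum
  CTV$_i$ dose is found, and its minimum-dose voxel is mapped back to
  planning geometry through the inverse displacement. Per fraction the
  point is propagated forward ($p + u_i(p)$, trilinear interpolation), the
  dose there recorded, and the projection
  $\mathrm{Scalar}_i = u_i(p) \cdot u_x(p)/|u_x(p)|$ measures the
  deformation component along the direction in which the global minimum was
  produced — a surrogate for motion along the steepest dose gradient.

$D_\min$ is deliberately the *voxel-level* minimum, not a DVH percentile;
the feature table also carries D99.9/D99/D98/D50 so that
`dmin_surrogate_correlation()` can quantify how quickly near-minimum
percentiles lose the information in $D_\min$.

Ties in argmin/argmax are broken by the lowest linear voxel index; all
point evaluations interpolate fields and doses trilinearly; single-point
inversion iterates $p \leftarrow q - u(p)$ to 0.01 mm (at most 50
iterations).

## Dose accumulation and its verification

Under uniform fractionation the per-fraction dose is the planning dose
divided by the number of fractions. The tissue element at planning voxel
$p$ receives, at fraction $i$, the planned dose at its displaced position
$p + u_i(p)$; summing these pulled-back doses on the planning grid is
algebraically the same as deforming each fraction's dose cube with the
inverse displacement field and summing. `invert_field()` performs the
inversion by per-voxel fixed-point iteration and reports the composition
residual (accepted below 0.1 mm RMS); `gamma_pass_rate()` implements the
global-normalization gamma index (3%/3 mm by default, low-dose threshold
10%, exhaustive lattice search within three times the
distance-to-agreement) used to check dose-warping steps.

## The synthetic cohort

`cohort_config()` defaults describe the emulated study conditions: 10
patients, 11–40 imaged fractions each, CTV volumes 149.3–344.2 cm³,
prescription 60 Gy, 5 mm PTV margin, cranio-caudal dose gradients drawn from
5–12.5 %/mm and axial gradients from 1.5–6.25 %/mm per patient.

**Dose model.** The plan is a flat plateau of 1.02 × prescription inside
the PTV (clinical plans run a few percent hot inside the target; the ICRU
homogeneity window) with linear anisotropic falloff outside, realized by a
single distance transform under a metric whose z-spacing is scaled by the
gradient ratio. There is no penumbra shoulder and no dose recalculation: the
falloff starts at the PTV surface at the configured rate.

**Deformation model.** Displacement fields are sums of
(i) a per-patient *systematic* smooth field, fixed across the patient's
fractions, (ii) a per-fraction *random* smooth field, and (iii) with small
probability a localized outward excursion bump (amplitude 8–12 mm, Gaussian
width 8 mm) anchored at a random CTV surface point — the mechanism that
produces the occasional genuinely cold fraction, consistent with
per-fraction effectiveness remaining stable up to roughly 8 mm of local
deformation and declining steeply beyond. Smooth fields are white noise
smoothed by a Gaussian kernel of 20 mm correlation length (generated on a
coarse lattice and trilinearly upsampled; the kernel choice is a modelling
convention — the spatial correlation structure of real fields is not
reported). Warp invertibility is enforced by a sampled Jacobian check with
amplitude damping.

A modelling point worth being explicit about: the configured systematic
(1.7/3.0/2.3 mm) and random (3.0/3.3/3.9 mm) components are defined — as in
interfraction-motion analyses of this kind — as statistics of the
*difference* of deformation vectors between two distant points of the CTV,
per patient and over patients respectively. For a field whose spatial
correlation is short relative to that separation, a difference of two
nearly independent values with pointwise SD $\sigma$ has SD
$\sigma\sqrt{2}$; the generator therefore uses pointwise SD
$\mathrm{sd}/\sqrt{2}$ so the two-point difference statistics reproduce the
configured values. A constant translation would cancel in those differences
(and is largely removed by online rigid matching anyway), which is why the
systematic component is a fixed *pattern*, not a bulk shift. Under this
reading the generated series also reproduce realistic per-fraction
Hausdorff distances (medians of a few mm) rather than implausibly large
ones. `generate_fraction_field()` itself keeps plain pointwise semantics:
its `random_sd` argument is the voxelwise SD of the component it generates,
and its `systematic_offset` argument is a constant translation.

**Deformed CTVs** are produced by nearest-neighbour resampling of the
planning CTV through the inverted field; partial-volume effects are out of
scope. CTV shapes are unions of perturbed overlapping ellipsoids rescaled by
bisection to the target volume (within 0.5%); no attempt is made at
realistic anatomy or image intensities, and fields are generated, never
estimated from images.

**What passing tests do and do not show.** The synthetic cohort reproduces
the *statistical geometry* of a gated series — margins, gradients,
deformation magnitudes, cold-fraction frequency — so tests on it validate
the implementation and the qualitative claims (accumulation robustness,
feature behaviour). They cannot validate clinical effect sizes: real
correlation coefficients and per-patient EUD values depend on patient
imaging that the cohort does not emulate.

## Prediction study

The regression target is the normalized per-fraction gEUD. Sample weights
emphasize the clinically relevant tail: 10 below 0.90, 2 in [0.90, 0.95),
1 otherwise. Two model families are evaluated with leave-one-patient-out
(LOPO) cross-validation, so every fraction is scored by a model that never
saw its patient:

* **Random forest** (`lopo_random_forest()`, via `ranger`): 500 trees,
  `mtry = ceiling(sqrt(p))`, minimum node size 5, case weights as above;
  variable importance is out-of-bag permutation importance (MSE loss
  reduction) averaged over folds. The published hyperparameters of the
  original high-performance procedures are not available; these are
  standard defaults, seeded.
* **Multilayer perceptron** (`nested_lopo_mlp()`, via `nnet`): one hidden
  layer of 8 units, weighted least squares, weight decay $10^{-2}$. Because
  the perceptron needs a validation set for model selection, the CV is
  nested: within each outer fold the training patients are repeatedly split
  two-thirds/one-third (six/three at the reference cohort size, 12 random
  splits — the original count is unpublished), candidates are trained on
  the inner training set, and the candidate with the best correlation over
  the full outer-training set scores the held-out patient. Inputs and
  target are standardized with outer-training statistics.

`patient_id` enters one-hot encoded; a held-out patient's indicator columns
are all zero in its training folds (the unseen-category convention).
Performance is summarized by the Pearson correlation between observed and
held-out predicted gEUD with a Fisher-transform CI, and by cross-validated
variance explained $VE_{cv} = 1 - \mathrm{SSE}/\mathrm{SST}$ (the standard
held-out form; it can be negative). Correlations of two feature sets with
the same observed values are compared with Steiger's Z for dependent
correlations; distributional comparisons use Kruskal–Wallis, Spearman and
Wilcoxon signed-rank tests via the corresponding `stats` routines.
`stepwise_poly_fit()` reproduces the univariate dose-effect fits: raw
polynomials of increasing degree, keeping the highest degree whose leading
coefficient is significant, with an early stop once a fit is numerically
exact.

## Numerical choices and problem sizes

* Grid: 2 mm isotropic by default, axes (x = left-right,
  y = anterior-posterior, z = cranio-caudal), arrays stored `dim = shape`
  with x fastest (R's column-major order), voxel-center world convention.
* DVH bin width: 0.1% of prescription; gEUD/EUD$_\mathrm{SF}$ use exact
  per-bin mean doses; Dx percentiles interpolate between bin edges.
* Field inversion: fixed-point, initialized at $-u$, per-voxel tolerance
  $10^{-3}$ mm, at most 30 sweeps; out-of-grid samples clamp to the
  boundary value and are counted.
* Gamma: exhaustive lattice search (no sub-voxel refinement), search radius
  3 × DTA, global normalization to the maximum reference dose unless a
  normalization dose is given.
* Degenerate inputs fail loudly (empty masks, constant targets, grid
  mismatches) except where a convention is stated: zero-dose bins with
  $a<0$ give gEUD 0 with a warning, a degenerate reference direction gives
  projection 0 with a warning, identical values give Kruskal–Wallis p = 1
  with a warning.
* Test and example problem sizes are deliberately modest (40³–64³ grids,
  cohorts of 3–10 patients) so the whole suite runs in minutes on one core;
  all sizes are parameters of `cohort_config()`.

## Known limitations

* The static dose cloud approximation is assumed, not re-verified against a
  dose engine; `gamma_pass_rate()` provides the comparison tool.
* Nearest-neighbour mask warping quantizes CTV boundaries to the voxel
  grid; sub-voxel surface motion is invisible.
* The synthetic dose model has no penumbra shoulder, no heterogeneity
  corrections and no beam geometry; gradients are constant per direction.
* The survival model has no repopulation or time factors, and uniform
  clonogen density.
* `VE_cv` uses the standard held-out variance-explained form; the original
  methodology reference for it prints no formula.
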