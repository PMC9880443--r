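# eudgate

Interfraction stability of the delivered dose in exhale-gated lung
radiotherapy: per-fraction equivalent-uniform-dose analysis, geometric
deformation features, deformable dose accumulation, and cross-validated
prediction of cold fractions.

## Who this is for

Medical physicists and methodologists who want to reproduce, on synthetic
but statistically realistic data, the analysis chain used to ask: *when the
clinical target volume (CTV) deforms a little at every fraction, how often
does a fraction deliver a markedly less effective dose, does the accumulated
dose over the series stay robust, and which per-fraction quantities predict
the effectiveness loss?*

## The models at the core

**Power-law gEUD.** For differential DVH volume fractions `v_i` at doses
`D_i`:

    gEUD = ( Σ_i v_i · D_i^a )^(1/a),   a = −20 for tumor

a generalized power mean that emphasizes cold spots; it lies between the
minimum and the mean dose and tends to D_min as `a → −∞`.

**Cell-survival EUD (EUD_SF).** Per-fraction survival under the
linear-quadratic model parameterized by SF2 (surviving fraction at 2 Gy)
and α/β = 4 Gy:

    s(d) = SF2 ^ [ (d/2) · (α/β + d) / (α/β + 2) ]

Repeating a fraction's dose distribution for a 30 × 2 Gy course gives the
course survival `S = Σ_i v_i · s(D_i)^30`; EUD_SF is the uniform total dose
with the same survival. SF2 is calibrated from the Poisson tumor control
model `TCP = exp(−N0 · SF2^n)` — 50% control at 60 Gy in 2 Gy fractions with
`N0 = 1e8` clonogens gives SF2 = 0.534598229.

**Geometric features per fraction:** the directed Hausdorff distance of the
deformed CTV from the planning CTV (minimal containing isotropic
expansion, via a 3-D anisotropic distance transform), the deformation
length at the worst Hausdorff point, the dose at the propagated global
minimum-dose point, and the projection of the local deformation onto the
direction that produced the global minimum.

**Dose accumulation** pulls each fraction's dose back to planning geometry
through the displacement field (equivalently: deforms the dose cube with
the inverse field, computed by fixed-point iteration and verified by its
composition residual) and sums; gamma-index analysis (3%/3 mm, global
normalization) is provided to validate dose-warping steps.

**Prediction study:** weighted random-forest and single-hidden-layer
perceptron regressors of per-fraction gEUD under leave-one-patient-out
(nested, for the perceptron) cross-validation, with out-of-bag permutation
importance, Fisher-interval Pearson correlations, cross-validated variance
explained, and Steiger's Z for comparing dependent correlations.

Everything runs on a seeded synthetic cohort (`cohort_config()` /
`generate_cohort()`) that emulates the study conditions: 10 patients with
11–40 fractions, CTV volumes 149–344 cm³, a ≥ prescription plateau on
CTV + 5 mm, anisotropic falloff of 5–12.5 %/mm cranio-caudally and
1.5–6.25 %/mm axially, systematic/random deformation components of
1.7/3.0/2.3 and 3.0/3.3/3.9 mm (defined through two-point deformation
differences), and rare large surface excursions that produce genuinely cold
fractions.

## Worked example

```r
library(eudgate)

cfg <- cohort_config(n_patients = 3, fractions_range = c(8, 10),
                     ctv_volume_range = c(120, 200),
                     grid = grid_spec(c(48, 48, 48), c(2.5, 2.5, 2.5)),
                     large_excursion_prob = 0.1, seed = 7L)
cohort <- generate_cohort(cfg)
cohort[[1]]
#> <patient_series P01: <grid 48x48x48 @ 2.5x2.5x2.5 mm>, CTV 199.1 cm^3, 9 fractions, Rx 60 Gy>

feats <- extract_cohort_features(cohort)
head(feats[, c("patient_id", "fraction", "d_min", "geud", "eud_sf",
               "hdd_mm", "scalar_pdmin_mm")], 5)
#>   patient_id fraction d_min  geud eud_sf hdd_mm scalar_pdmin_mm
#> 1        P01        1 1.020 1.020  1.020  3.536          -2.103
#> 2        P01        2 0.969 1.020  1.020  6.124          -2.911
#> 3        P01        3 0.918 1.019  1.019  7.500          -2.934
#> 4        P01        4 0.791 1.016  1.016 10.308          10.661
#> 5        P01        5 0.948 1.020  1.020  7.500          -0.140
```

Doses are normalized to prescription. Fraction 4 of patient P01 is a cold
fraction: its minimum CTV dose dropped to 79% of prescription, the deformed
CTV reached 10.3 mm outside the planning CTV, and the 10.7 mm projection
onto the worst-deformation direction flags motion into the dose falloff —
yet its gEUD (1.016) barely moves because the cold volume is tiny.

```r
acc <- accumulate_dose(cohort[[1]])
sprintf("accumulated gEUD: %.3f of prescription; accumulated D_min: %.1f%%",
        acc$geud_acc_norm, 100 * acc$d_min_acc_norm)
#> "accumulated gEUD: 1.020 of prescription; accumulated D_min: 99.5%"

kruskal_wallis_groups(feats$geud, feats$patient_id)
#> interpatient gEUD heterogeneity: H = 12.5, p = 0.0019

lopo_random_forest(feats, feature_set("A"), seed = 1)
#> <cv_result: 26 held-out predictions, R = 0.949 (95% CI 0.888-0.977), VE_cv = 0.856>
#> importance (OOB permutation, fold average):
#> d_min
#> 5e-04
```

The accumulated distribution stays at the planned effectiveness (gEUD 1.02
of prescription) even though individual fractions dip — deformations rarely
hit the same spot twice. The leave-one-patient-out random forest predicts a
held-out fraction's gEUD from its minimum dose alone with R = 0.949 here.

`run_pipeline()` drives the whole chain (simulate → features → accumulate →
gamma check → predict) from a config object or YAML file and writes CSV
tables, NIfTI volumes and a `metrics.json` with the seed and config
checksum; see `vignettes/dose-effectiveness.Rmd` for the methods.

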