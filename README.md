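# shapefeature

Shape-based quantification of beta-amyloid PET/CT for discriminating
Alzheimer's-disease-like from non-AD-like scans.

Clinically, amyloid-positive scans show smooth, confluent cortical
tracer uptake, while negative scans show a thin, convoluted
white-matter pattern; atrophy additionally roughens the cortical
surface. `shapefeature` turns both observations into numbers by
comparing surface areas against the minimum-area sphere of equal
volume:

- **CASS** (cerebral amyloid smoothing score): the amyloid volume of
  interest (VOI) is segmented from PET at *k* times the mean of the
  strictly positive SUV voxels (validated operating point *k* = 6),
  and scored as
  `CASS = A_sphere(V_VOI) / A_VOI`, where
  `A_sphere(V) = (36*pi)^(1/3) * V^(2/3)`.
  Smooth compact uptake gives CASS near 1, thin ribbons much less.
- **BAI** (brain atrophy index): `BAI = A_brain / A_sphere(V_brain)`
  for a CT-derived brain parenchyma mask; it is at least 1 and grows as
  sulci deepen.
- **Shape feature** `= CASS x BAI`, the combined amyloid + atrophy
  biomarker.

The package provides NIfTI-1 I/O, the VOI/brain-mask extraction steps,
closed-mesh and voxel-face surface estimators, synthetic PET/CT
phantoms with known geometric ground truth, and the cohort statistics
used to evaluate such markers (Mann-Whitney tests, ROC analysis with
DeLong comparison of paired curves, Youden cut-offs, Spearman
correlation, threshold-multiple sweeps). See the methods vignette
(`vignettes/shapefeature-methods.Rmd`) for the model, numerical
choices, and limitations.

## Worked example

Quantify one synthetic AD-like case (smooth filled uptake, 4 mm
atrophy) end to end:

```r
library(shapefeature)

spec <- phantom_spec(uptake_pattern = "filled_smooth",
                     atrophy_depth = 4, seed = 42)
anat   <- make_brain_ct(spec)               # CT + ground-truth brain mask
pet    <- make_pet(spec, anat$brain_mask)   # blurred, noisy PET
scores <- quantify_case(pet, anat$brain_mask, k = 1.5)
scores
#> <shape_scores> k = 1.5, surface method mesh
#>   SUV mean (non-zero) 1.209, threshold 1.813
#>   VOI:   1.748e+05 mm^3, 1.506e+04 mm^2  ->  CASS 1.004
#>   brain: 2.314e+05 mm^3, 1.822e+04 mm^2  ->  BAI  0.9995
#>   shape feature 1.003, SUVr 1.11
```

The VOI of this case is nearly spherical (CASS 1.004, at the
isoperimetric ceiling), so the shape feature is high. The same seed
with the non-AD `cortical_ribbon` pattern yields CASS 0.502 and shape
feature 0.497: the thin shell carries far more surface per unit
volume, and the score separates the two archetypes cleanly. (The
phantom intensity scale is compressed relative to clinical SUV images,
so `k = 1.5` plays the role of the clinical `k = 6`; see the
vignette.)

Cohort-level analysis mirrors a clinical evaluation:

```r
cohort <- simulate_cohort(n_pos = 23, n_neg = 27, seed = 17)
run_analyze(cohort)   # medians/IQRs, Mann-Whitney p, AUC + CI,
                      # cut-offs, DeLong comparisons vs SUVr, MMSE rho
```

A thin command-line front-end with `simulate`, `quantify`, `analyze`
and `sweep` subcommands is installed at
`system.file("cli", "shapefeature.R", package = "shapefeature")`.

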