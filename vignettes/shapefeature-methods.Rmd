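---
title: "Shape-based quantification of amyloid PET/CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based quantification of amyloid PET/CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

Amyloid-positive brains tend to show *smooth, confluent* tracer uptake —
gray and white matter merge into one compact region — while negative
scans show a thin, convoluted white-matter pattern. Independently,
neurodegeneration makes the cortical surface more irregular. This
package quantifies both observations with one geometric idea: compare a
region's surface area with the surface area of the sphere holding the
same volume,

$$A_{sphere}(V) = (36\pi)^{1/3} V^{2/3},$$

the minimum possible area for that volume (isoperimetric inequality).

Three scores are computed per case:

* **CASS** (cerebral amyloid smoothing score). The amyloid VOI is the
  set of PET voxels at or above $k$ times the *non-zero mean* SUV
  (the mean over strictly positive voxels; the validated operating
  point is $k = 6$). Then
  $\mathrm{CASS} = A_{sphere}(V_{VOI}) / A_{VOI}$.
  Smooth, blob-like uptake gives CASS near 1; thin ribbons give small
  values.
* **BAI** (brain atrophy index), the reciprocal normalization applied
  to a brain parenchyma mask:
  $\mathrm{BAI} = A_{brain} / A_{sphere}(V_{brain}) \ge 1$, increasing
  as sulci deepen.
* **Shape feature** $= \mathrm{CASS} \times \mathrm{BAI}$, the combined
  amyloid + atrophy biomarker.

## The `scale_sigma` reporting scale

Historically reported CASS values in the thousands and BAI values near
$10^{-4}$ are impossible for the dimensionless ratios above — the
isoperimetric inequality forces CASS $\le 1$ and BAI $\ge 1$ — yet
their *product* lands exactly in the plausible range of the combined
score. This implies a hidden unit or scale factor that multiplies CASS,
divides BAI, and cancels in the product. The package computes the
honest dimensionless ratios and exposes `scale_sigma` (default 1)
purely as a display scale for readers used to legacy magnitudes;
`shape_feature()` is provably independent of it, and the test suite
asserts the cancellation to machine precision.

# Geometry estimation

**Volumes** are voxel counts times the physical voxel volume, because
the score definitions pair "volume" with the segmented voxel set
itself. Mesh-enclosed volume is not used.

**Surface areas** have two estimators:

* `mesh` (default): the mask is zero-padded, smoothed with a Gaussian
  of `smoothing_sigma = 1.25` voxels per axis, and the 0.5-level
  iso-surface is triangulated by marching tetrahedra on the Kuhn
  6-tetrahedra cell decomposition. The decomposition is
  translation-consistent, so every extracted surface is closed
  (asserted edge-by-edge in the tests). The pre-smoothing gives
  sub-voxel vertex placement: without it, midpoint interpolation on a
  binary field overestimates curved areas by several percent and does
  not converge. With it, the error for digitized balls decreases
  monotonically with radius (about $-2\sigma^2/r^2$ from curvature,
  plus a small interpolation ripple) and is below 2% at $r = 40$
  voxels. The value 1.25 balances the two error terms; it is defined in
  voxel units, so with anisotropic spacing the physical smoothing is
  anisotropic too.
* `voxel_faces`: counts voxel faces adjoining background, weighted by
  physical face area. It is *exact* for axis-aligned boxes (the test
  oracle role) but overestimates curved surfaces by a staircase factor
  around 1.5 and never converges; it is kept as an independent
  cross-check and as a fallback for structures too thin to mesh.

**Degenerate masks.** A one-voxel-thick structure is washed below the
0.5 level by the smoothing; `mask_mesh()` reports this as an error
rather than returning a meaningless surface, while `voxel_faces`
still serves such masks. The same resolution limit means thin cortical
ribbons should be at least \~3 voxels thick after thresholding for the
mesh pathway; the phantom tests choose their geometry accordingly.

**Thresholding** is inclusive (`>=`), so a uniform positive image at
$k = 1$ selects everything rather than nothing. The VOI keeps all
supra-threshold voxels by default (`min_component_voxels = 0`):
multiple components simply sum their areas and volumes, which is the
only choice that uses all segmented signal. Components are
26-connected. Negative PET values (scatter-correction artifacts) are
clipped at load time so that "non-zero mean" means strictly positive.

**CT brain mask stub.** In production the brain mask should come from a
proper segmentation; the built-in stub (`brain_mask_from_ct()`) is an
intensity window (default 0–80, the soft-tissue Hounsfield band)
followed by largest-component selection and 3-D hole filling. Whether
the mask is gray+white combined or gray only is left to the supplier
of the mask; the stub produces the combined parenchyma, which is what
the BAI contract needs. NIfTI orientation is read but not used: every
score is rotation-invariant, so only the voxel spacing enters the
computation.

**SUVr.** Without atlas registration the package computes a plain
mask-based ratio: mean SUV in a target region over mean SUV in a
reference region. `quantify_case()` defaults the reference to the
whole brain (global normalization); the phantom cohort instead passes
the non-brain background as a nonspecific-uptake reference, playing the
role of a cerebellar region.

# The phantom generator

Phantoms are star-shaped surfaces
$r(u) = R\,(1 + \textstyle\sum_i a_i B_i(u))$ with Gaussian bump basis
functions $B_i$ on random directions, voxelized by comparing each
voxel's radius against $r(u)$. Ground-truth area and volume come from a
densely sampled parametric surface (240 x 480 in latitude/longitude),
fully independent of any voxel estimator. The bump part is rescaled so
the enclosed volume stays at $\tfrac{4}{3}\pi R^3$: amplitude then
raises area at fixed volume, which is the clean way to dial surface
irregularity. Atrophy subtracts narrow sulcus-like indentations of a
given depth in mm (24 sulci of angular width 0.22 rad by default),
which also removes volume, as real atrophy does.

A case consists of:

* a CT with parenchyma at intensity 40 inside a skull shell at 1000
  following the *unatrophied* outer surface (deepening sulci widen the
  subdural space). Intracranial non-brain space is air-like (−1000), a
  deliberate synthetic simplification — real CSF sits near 15 HU and
  could not be separated from parenchyma by a window — chosen so the
  documented stub recovers the ground-truth mask exactly;
* a PET with background 1.0 everywhere and either a *filled-smooth*
  pattern (uniform 2.5 inside the brain eroded by 3 mm; the AD-like
  archetype) or a *cortical-ribbon* pattern (2.0 on a 6 mm shell under
  the brain surface; the non-AD archetype), followed by a Gaussian blur
  of 6 mm FWHM (point-spread emulation) and additive Gaussian noise
  (sd 0.05), clipped at zero.

Because this intensity scale is compressed relative to clinical SUV
images (where most non-zero voxels are far below cortical uptake), the
threshold multiple playing the role of the clinical $k = 6$ operating
point is $k = 1.5$ for phantoms; the cohort simulator uses it as its
default while the pipeline configuration keeps $k = 6$ for real data.

`simulate_cohort()` generates 23 positive vs 27 negative cases by
default — the group sizes at which the downstream statistics are meant
to operate — on a 52 x 52 x 32 grid at 2 x 2 x 3.75 mm (the axial
spacing follows the clinical CT slice thickness; the in-plane 2 mm is
an assumption, as typical for PET reconstructions, since no in-plane
value is published). The base radius of 40 mm is a scaled-down brain
chosen to keep a full cohort quantifiable in tens of seconds; all
geometric claims are scale-free, and the suite verifies invariance
under uniform spacing rescaling explicitly. The separation parameter
`effect` (default 0.8) mixes the archetypes (a positive case draws the
filled pattern with probability $0.5 + 0.5\,\mathrm{effect}$) and
shifts the atrophy-depth distribution by $1.5\,\mathrm{effect}$ mm;
the default was chosen once so that every marker lands in a plausible
discriminative band (AUC roughly 0.7–0.95) rather than saturating at
1. At `effect = 0` the two groups share one generating distribution —
a flagged null simulation used for calibration. All randomness flows
from one master seed through a fixed per-case splitting rule
(`case_seed = (seed + 104729 * i) mod (2^31 - 1)`), so single cases
can be regenerated in isolation.

What the phantoms deliberately do **not** emulate: real anatomy
(ventricles, hemispheres, gyral geometry), scanner physics (randoms,
scatter, reconstruction artifacts), partial-volume effects beyond the
Gaussian blur, and the clinical SUV scale. Passing tests therefore
demonstrate that the estimators and statistics are correct and
well-calibrated on controlled geometry — not that the biomarker
separates real patients.

# Statistical conventions

* **Mann–Whitney**: $U$ counts pairs with $a > b$ (half for ties).
  The p-value is exact (null distribution of $U$) when
  $n_1 n_2 \le 400$ and the data are tie-free, otherwise the normal
  approximation with tie-corrected variance and continuity correction.
  Published analyses rarely state which variant their software used;
  both variants are validated against permutation enumeration and
  base R in the tests.
* **ROC**: thresholds sweep the observed scores with the
  higher-score-positive convention; polarity is never auto-flipped and
  an AUC below 0.5 is reported as-is with a warning. The AUC is the
  trapezoidal area, identical to $U/(n_1 n_0)$ (asserted to machine
  precision). The optimal cut-off maximizes Youden's $J$, reports an
  *observed* score value (not a midpoint), and breaks ties toward
  higher specificity. The AUC standard error and 95% CI use the DeLong
  placement-value variance.
* **Curve comparison**: correlated AUCs measured on the same cases are
  compared with the DeLong z-test; a stratified paired bootstrap is
  retained as the validation oracle, with decision agreement checked
  over hundreds of simulated cohorts.
* **Spearman**: Pearson correlation of mid-ranks; exact permutation
  p-value for $n \le 8$, t approximation otherwise; constant inputs
  yield a flagged (not erroring) result.
* **Multiplicity**: no correction is applied across the score-versus-
  reference comparisons, matching common practice in the source
  literature for small comparison families; reports state each p-value
  raw.

# Validation problem sizes

The test suite exercises: digitized balls up to $r = 40$ voxels for
convergence; 50 random star phantoms for the isoperimetric bounds
(CASS $\le 1.05$, BAI $\ge 0.95$ at `scale_sigma = 1`); 100 random
cohorts for the AUC–U identity; 2000 score-level null cohorts of
23 vs 27 for Mann–Whitney size; 500 cohorts for DeLong-vs-bootstrap
agreement (2000 resamples each); a full seeded 23 vs 27 image-level
cohort for group separation and the threshold-multiple sweep; and 20
reduced-scale image-level null cohorts for end-to-end exchangeability.
These sizes were chosen as the smallest that make the binomial error
bars meaningful for each claim.

# Known limitations

* Thin structures (one to two voxels) cannot be meshed; the voxel-face
  estimator applies but carries its staircase bias.
* The smoothing is defined in voxel units, so strongly anisotropic
  voxels smooth anisotropically in physical space; with the default
  3.75 mm slices, fine axial detail (sulci shallower than about one
  slice) is attenuated.
* The CT stub is an intensity window, not a tissue segmentation; real
  CT requires a proper parenchyma mask for trustworthy BAI values.
* Voxel-count volume and mesh area are different discretizations; their
  ratio makes CASS overshoot 1 slightly for near-spherical masks (the
  documented tolerance is 5%).
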