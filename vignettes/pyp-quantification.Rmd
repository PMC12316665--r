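---
title: "Quantifying myocardial Tc-99m-PYP uptake: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial Tc-99m-PYP uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pypquant)
```

## The measurement model

`pypquant` operates on *reconstructed* SPECT volumes: 3D count grids with
isotropic voxel spacing. Everything upstream of reconstruction — projection
physics, ordered-subset reconstruction, scatter and attenuation correction —
is outside the package's scope; its net effect on a reconstructed image is
emulated in the phantoms by a Gaussian point-spread function followed by
Poisson count noise. This is the right level of abstraction because every
index the package computes is defined on reconstructed images, and it keeps
the phantom ground truth exact.

Counts become body-weight standardized uptake values through two factors:

$$\mathrm{SUV} = \frac{\text{counts/voxel} \times \mathrm{CCF}}
                      {\text{dose [Bq]} / \text{weight [g]}}$$

The cross-calibration factor CCF is measured on a uniform cylinder of known
activity concentration (16 cm diameter, 15 cm height, 3016 mL). Two
conventions are worth making explicit:

* **Calibration mask erosion.** The mean count is taken over the cylinder
  interior after eroding the geometric mask by one PSF FWHM (default 8 mm).
  Voxels near the cylinder wall are dimmed by partial volume; averaging over
  the eroded interior removes that bias. The erosion distance is a
  parameter (`erode_mm`), and setting it to 0 recovers the naive mean.
* **No decay correction.** The injected dose is used as given; no
  decay correction between injection and acquisition is applied. Callers
  who need it should decay-correct `dose_bq` before conversion. The
  protocol helper `pyp_dose_mbq()` implements the weight-standardized
  administration rule (555 × weight/60 MBq, capped at 555 MBq).

Negative reconstructed counts (possible after some reconstruction filters)
are clamped to zero at conversion, with a message reporting the count.

## Volumes of interest and the differentiation metrics

The whole-heart VOI is an ellipsoid placed to *include the entire heart* —
myocardium, chambers and blood pool alike. The aortic reference is the
unweighted mean of three cylinder-VOI means along the descending aorta,
each 19.5 mm tall (five 3.9 mm pixels), with a per-subject diameter.
Conventions:

* **Voxel membership** is by voxel-center inclusion; no partial-volume
  weighting. This makes VOI means exactly reproducible and translation
  invariant for whole-voxel shifts.
* **Mean of means.** SUV_Ao averages the three cylinder means rather than
  pooling their voxels, so a wider cylinder does not dominate the
  reference. (With per-subject constant diameters the two readings differ
  only through voxel-count differences at the cylinder boundary.)
* **Ties positive.** `classify_uptake()` calls a subject positive when the
  metric is at or above the cutoff. A fixed convention matters more than
  its direction; this one is documented and tested.
* **H/CL geometry.** The planar ratio uses equal-area circular ROIs, the
  lung ROI mirrored across the image midline at the heart's height —
  standard clinical practice. ROI radius defaults to 30 mm.

The heart-to-aorta ratio rSUV_H/Ao is a *ratio of means*, so it is exactly
invariant to global rescaling of the SUV volume — miscalibration of the CCF
cancels out. That is the property that makes it a robust discriminator, and
it is asserted as a test invariant.

## Polar map construction

Short-axis slices are extracted orthogonal to the LV long axis by trilinear
interpolation at the native in-plane resolution, ordered base to apex. Per
slice, the LV center defaults to the centroid of pixels above 50% of the
slice maximum (an explicit override is accepted; the threshold rule mimics
what clinical packages do automatically). Each slice is then reduced to a
profile of *maximal* SUV along radial rays — the maximum over the ray is
insensitive to exactly where the shell sits radially, which is what makes
the polar map robust to wall-position and wall-thickness variation.

Sampling parameters, with defaults and rationale:

| parameter | default | rationale |
|---|---|---|
| `n_rays` | 60 | 6° angular pitch, finer than the voxel footprint at typical radii |
| `step_px` | 0.5 | sub-voxel radial sampling; guarantees a sample inside every fully-interior bilinear cell |
| `n_rings` | 30 | ring boundaries land exactly on the 30/60/90% level fractions (below) |
| `apex_cap_frac` | 0.1 | innermost 10% of rings form the apex cap |
| `suv_ceiling` | 4.0 | display ceiling for rendered maps |

**Parcellation.** Rings are labelled by the AHA 17-segment model: the apex
cap (segment 17) takes the innermost `ceil(0.1 * n_rings)` rings at all
angles, and the remaining rings split into equal basal, mid and apical
levels — six 60° sectors each for basal/mid (segments 1–6, 7–12), four 90°
sectors for apical (13–16). The angular origin is the anterior wall, with
angles increasing toward the septum. The phantom generator labels shell
*voxels* with the same rule (deepest 10% of the LV length = cap, thirds of
the remaining 90%), so polar-map parcellation and geometric ground truth
agree and parameter-recovery tests are meaningful. When the stack has fewer
slices than rings, each ring takes the profile of the nearest slice, so
even a minimal 3-slice stack yields all 17 segments.

**SD denominator.** Segmental SD uses the population form (divide by *n*):
the segment's cells are the complete set whose dispersion the segmental COV
describes, not a sample from a larger population. The choice is switchable
(`sd_type = "sample"`) and both paths are tested.

## Regional indices

All indices operate on the 17 segment means (not on pooled cells),
following the summed-SUV definition
$\text{Summed SUV}_\text{region} = \sum_i \text{SUV}_{\text{segment},i}$:

* total cardiac SUV = sum over all 17 segment means;
* COV = $\sum_{s=1}^{17} \mathrm{SD}_s / \mathrm{mean}_s \times 100$;
* %DS = (septal − lateral)/total × 100 with septal = {2, 3, 8, 9, 14},
  lateral = {5, 6, 11, 12, 16};
* %BA = (basal − apical)/total × 100 with basal = 1–12, apical = 13–17.

"Total" is the sum over all 17 segments in both ratio denominators — the
only reading under which the packaged patient table's basal + apical
columns reproduce its total column (they do, to the 0.02 tolerance implied
by 2-decimal rounding, which the test suite asserts for all 20 rows).

Two structural facts to keep in mind when interpreting values: a perfectly
uniform ventricle has %BA = (12 − 5)/17 × 100 ≈ 41.2 (the regions contain
unequal numbers of segments), and COV/%DS/%BA are exactly invariant to
global rescaling while total cardiac SUV scales linearly — so the
heterogeneity indices are calibration-free but the burden index is not.

## The statistics layer

Group comparisons use the Kruskal–Wallis test (base R, tie-corrected) with
Steel–Dwass all-pairs post-hoc comparisons. The Steel–Dwass implementation
computes, per pair, the jointly-ranked tie-corrected standardized rank-sum
statistic and refers $\sqrt{2}\,|t|$ to the studentized-range distribution
with $k$ groups and infinite degrees of freedom — the asymptotic convention
of commercial packages. Because small-sample behaviour of that reference is
not obvious, the package also ships an exact mode (`method = "exact"`,
compiled enumeration) that enumerates every partition of the pooled data
into the observed group sizes and reports the tail probability of the
maximal pairwise statistic; it is feasible up to roughly n = 8 per group at
k = 3 and serves as the oracle in the test suite. At k = 2 the asymptotic
form reduces exactly to the two-sided normal-approximation Wilcoxon test.
Groups of size 1 are accepted with a warning that asymptotic p-values are
unreliable.

Fisher tests are exact enumerations (Freeman–Halton for 2 × k); pairwise
2 × 2 p-values are Bonferroni-multiplied by the number of pairs and capped
at 1. Pearson correlations drop incomplete pairs (pairwise-complete
deletion), matching how cohorts with partially missing echo parameters are
analysed.

## What the phantoms emulate — and what they do not

`make_cardiac_phantom()` builds a truncated half-ellipsoidal LV shell
(closed apex, open base; default outer semi-axes 45 × 45 × 65 mm, inner
30 × 30 × 50 mm — a hypertrophic-range wall) over a blood-pool cavity, two
low-uptake lung boxes and a posterior descending-aorta cylinder, on a
128³ grid of 3.9 mm voxels (the matrix and pixel pitch implied by a
19.5 mm = five-pixel convention; tests use smaller grids for speed, stated
per test). Uptake levels are specified in SUV-like units relative to a
unit blood pool. The map is blurred with an 8 mm FWHM Gaussian and
Poisson-sampled at `count_scale` expected counts per unit concentration;
one seed drives all randomness, making fixtures bit-reproducible.

For differentiation cohorts, amyloid-like subjects draw voxel-level
myocardium-to-blood ratios uniformly from 3.2–5.5. This range is derived
from the published group statistics rather than assumed: a whole-heart VOI
is roughly 40% myocardium, so its mean dilutes the voxel-level contrast by
more than half, and ratios of 3.2–5.5 are what produce whole-heart means
near 1.8 SUV and heart-to-aorta ratios near 1.85 ± 0.5 over a unit blood
pool. (A nominal ratio of 1.5, although clearly "positive" at the voxel
level, yields a whole-heart VOI ratio near 1.2 — below the upper
conventional cutoff — purely through blood-pool dilution; separation claims
are therefore only meaningful for cohorts calibrated to realistic uptake
levels.) Controls draw ratios from 0.6–1.0.

The phantoms deliberately omit: ribs and skeletal uptake (a known planar
confounder — planar H/CL values on phantoms run higher than clinical ones
because no soft-tissue background overlies the lung ROI), anthropomorphic
anatomy, respiratory/cardiac motion, projection-domain simulation, and
vendor-specific reconstruction behaviour. Passing the phantom suite
therefore validates the geometry, calibration algebra, parcellation and
index definitions — not robustness to anatomical variation or
reconstruction artefacts in real patients.

## Numerical choices and degenerate inputs

* Trilinear/bilinear interpolation returns 0 outside the grid; radial
  profiles therefore decay to 0 beyond the field of view rather than
  erroring.
* Gaussian kernels are truncated at 3σ and edge-renormalized: constants
  are preserved exactly away from boundaries, and a centered delta keeps
  its total mass to machine precision.
* Radial maxima are exact (up to floating point) wherever a sample lands in
  a bilinear cell whose four corners share one value; with 0.5-pixel steps
  this holds for any uniform band at least ~1.5 pixels wide. At *angular*
  uptake discontinuities, bilinear mixing across the sector boundary biases
  the sampled maximum toward the hotter side; the bias scales with the
  contrast. At clinically mild gradients (segment multipliers ≤ ~1.4,
  matching the %DS range of the packaged patient table) noiseless recovery
  of %DS is accurate to well under 1 percentage point; at an extreme 2×
  step the recovered %DS understates the true value by roughly 10%
  relative. Recovery tests state which regime they exercise.
* Zero segment means make COV undefined: `total_cov()` errors with the
  offending segment id, and `compute_indices()` reports `NA` for COV while
  still returning the sums and ratios.
* An all-zero total errors in %DS/%BA (division by zero); an empty polar
  segment errors in `segment_stats()` (parcellation bug, not data).
* Exact Steel–Dwass refuses group-size combinations beyond ~5 × 10⁶
  partitions rather than silently running for hours.

## Problem sizes used in validation

The test suite and the acceptance script run phantoms at 64³–96³ voxels
(3.9 mm pitch) rather than the full 128³ default, 20 + 20 subject
differentiation cohorts, and exact Steel–Dwass enumeration at k = 3, n = 5
(756 756 partitions). These sizes keep the complete validation run short
while leaving every algorithmic path identical to full-resolution use.

## Known limitations

* VOI placement is explicit input; there is no CT-guided automatic
  segmentation of heart or aorta.
* Single static volumes only — no gated/4D analysis, wall motion or
  thickening.
* Body-weight SUV only (no lean-mass or BSA variants).
* The exact correspondence of this polar-map implementation to any
  particular commercial package's maps is unverifiable (ray counts, apex
  handling and center-finding are proprietary there); the implementation is
  instead validated against geometric phantom ground truth.
* Echocardiographic parameters are *inputs* (or synthetic correlates for
  testing); the package does not compute strain or diastolic indices.
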