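# pypquant

Quantitative analysis of technetium-99m pyrophosphate (⁹⁹ᵐTc-PYP) SPECT/CT
for transthyretin amyloid cardiomyopathy (ATTR-CM).

⁹⁹ᵐTc-PYP is a bone-avid tracer that also binds myocardial amyloid
deposits. Planar scintigraphy (Perugini grading, heart-to-contralateral-lung
ratio) is the traditional readout but suffers from overlap of ribs and
blood pool. Quantitative SPECT/CT converts reconstructed counts to
standardized uptake values (SUV), which makes both **differentiation**
(amyloid-positive vs. negative hearts) and **regional characterization**
(how heterogeneously the tracer distributes over the left ventricle)
measurable on an absolute scale. `pypquant` implements that full pipeline
for nuclear-cardiology researchers, together with seeded digital phantoms
so every step can be validated against known ground truth.

## What it computes

**SUV calibration.** Counts are converted by

```
SUV = pixel value [count/voxel] × CCF [(Bq/mL)/(count/voxel)]
      ─────────────────────────────────────────────────────────
             injected dose [Bq] / body weight [g]
```

where the cross-calibration factor (CCF) is estimated from a uniform
cylinder acquisition (16 cm diameter, 15 cm height, 3016 mL) of known
activity concentration: `estimate_ccf()`, `counts_to_suv()`.

**Differentiation metrics.** `differentiation_metrics()` measures the mean
SUV of an ellipsoidal whole-heart VOI (SUV_H), the mean of three
cylindrical VOIs along the descending aorta (SUV_Ao, each 19.5 mm tall),
their ratio rSUV_H/Ao, and the planar H/CL ratio from mirrored circular
ROIs. `classify_uptake()` applies the conventional cutoffs (rSUV_H/Ao
1.1–1.3, H/CL 1.3; ties positive).

**Polar map and regional indices.** `reslice_short_axis()` +
`build_polar_map()` sample the maximum SUV along radial rays of each
short-axis slice and arrange the profiles concentrically (base outermost,
apex at the center), parcellated into the AHA 17-segment model. From the
per-segment means and SDs (`segment_stats()`), `compute_indices()` derives

- **total cardiac SUV** — sum of the 17 segment means (disease burden),
- **COV** — sum over segments of within-segment SD/mean × 100 (heterogeneity),
- **%DS** — (septal − lateral summed SUV)/total × 100 (septal predominance),
- **%BA** — (basal − apical summed SUV)/total × 100 (base-to-apex gradient).

**Cohort statistics.** `kruskal_wallis()`, `steel_dwass()` (asymptotic
studentized-range reference plus an exact enumeration mode for small
groups), `fisher_pairwise_bonferroni()`, `pearson()`, `sens_spec()`.

**Phantoms and reference data.** `make_cylinder_phantom()` and
`make_cardiac_phantom()` generate seeded acquisitions (ellipsoidal LV shell
with per-segment uptake multipliers, blood pool, lungs, descending aorta,
Gaussian PSF, Poisson counts) with exact ground-truth labels and indices.
`load_regional_suv_reference()` ships the published per-patient regional
results of a
20-patient ATTR-positive cohort (15 wild-type, 5 variant).

## Worked example

Reproducing the published relationship between regional heterogeneity and
disease burden from the packaged per-patient table:

```r
library(pypquant)
tab <- derive_reference_indices(load_regional_suv_reference())
burden_correlations(tab)
#>   subset  index       r       p  n
#> 1    all    cov -0.2540 0.27978 20
#> 2    all pct_ds -0.2960 0.20510 20
#> 3    all pct_ba -0.0989 0.67820 20
#> 4     wt    cov -0.3850 0.15651 15
#> 5     wt pct_ds -0.7279 0.00209 15
#> 6     wt pct_ba  0.2257 0.41864 15
#> 7      v    cov -0.7399 0.15290  5
#> 8      v pct_ds -0.0407 0.94821  5
#> 9      v pct_ba -0.4860 0.40651  5
```

In wild-type disease, %DS falls sharply as total cardiac SUV rises
(r = −0.73, p = 0.002): heavier amyloid burden goes with more homogeneous,
less septal-predominant uptake.

End-to-end on a synthetic amyloid-like heart with 1.4× septal enhancement:

```r
sp  <- phantom_spec(grid_shape = c(64, 64, 64),
                    segment_multipliers =
                      replace(rep(1, 17), c(2, 3, 8, 9, 14), 1.4),
                    seed = 7)
ph  <- make_cardiac_phantom(sp)
cal <- cross_calibration(1 / sp$count_scale, source = "simulated cylinder")
suv <- counts_to_suv(ph$volume, cal, dose_bq = 1, weight_g = 1)

vois <- phantom_vois(sp)
differentiation_metrics(suv, vois$heart, vois$aorta,
                        planar = project_planar(ph$volume, "y"),
                        heart_center_mm = sp$lv_center_mm[c(1, 3)])
#> <differentiation_result> SUV_H 1.424 | SUV_Ao 0.880 | rSUV_H/Ao 1.617 | H/CL 2.814

cardiac_indices(suv, sp$lv_axis, sp$lv_center_mm,
                extent_mm = sp$myo_outer_radii[3])$indices
#> <regional_index_set> total 55.46 | COV 166.95 | %DS 9.54 | %BA 43.60
```

The ratio 1.62 is well above every conventional cutoff (an
amyloid-positive call), the COV of 167 sits inside the published patient
range (86–315), and the recovered %DS of 9.5 tracks the phantom's true
septal gradient (%DS 10.5 in the noiseless ground truth;
`ph$truth$true_indices`).

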