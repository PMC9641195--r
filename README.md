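# chambervol

Cardiac chamber volumetry from surface meshes and segmentation masks,
with the paired method-agreement statistics used to compare volumetry
methods.

Clinical platforms estimate ventricular volumes by the clinical
"Simpson's rule" — per-slice voxel area × slice thickness, summed over
a stack of parallel slices — while mesh-based pipelines segment the
chamber surface, store it as an STL triangle mesh, and compute the
enclosed volume by **signed tetrahedron (polygon) summation**:

$$V = \frac{1}{6} \sum_i \vec p_{i,1} \times \vec p_{i,2} \cdot \vec p_{i,3}$$

where $(p_{i,1}, p_{i,2}, p_{i,3})$ are the vertices of triangle $i$
and the winding decides each term's sign (normals pointing away from
the origin count positive). The two conventions also segment different
borders: smoothed contours include trabeculae and papillary muscles in
the luminal volume; an inner-blood-pool contour excludes them and is
systematically smaller. `chambervol` implements both engines, STL and
NIfTI I/O with watertightness/orientation diagnostics, a
synthetic-ventricle phantom generator with known ground-truth volumes,
Lin's concordance correlation coefficient with CI, Bland–Altman limits
of agreement, paired MSE and paired t — bundled into a classed
`agreement` object — and an end-to-end phantom study harness.

It is intended for researchers comparing volumetry pipelines (slice- vs
mesh-based, smoothed vs blood-pool segmentation) who need validated
volume engines and a reproducible agreement workflow, without patient
data.

## Worked example

```r
library(chambervol)

mesh_volume(cube_mesh(10))        # 10 mm cube
#> Volume: 1.0000 cm^3 (signed 1.0000 cm^3)
#>   method: mesh_polygon_summation over 12 faces

# a 20-subject synthetic LV cohort measured by three methods
cohort <- make_cohort(n = 20, seed = 20)
head(cohort, 3)
#>   subject_id     shape truth_cm3  pdp_cm3 vrps_cm3 vribp_cm3
#> 1        S01 bullet_lv  164.7088 163.6479 166.5994  156.7134
#> 2        S02 bullet_lv  169.0527 177.5615 167.6518  161.1768
#> 3        S03 bullet_lv  137.7574 138.4578 142.5326  128.7235

agreement(cohort, x_col = "pdp_cm3", y_col = "vrps_cm3")
#> Method agreement: pdp_cm3 vs vrps_cm3 (n = 20, differences = pdp_cm3 - vrps_cm3)
#>   Lin's rho_c: 0.9779 (95% CI 0.9464, 0.9910)
#>   mean difference: 1.953 cm^3 (SD 6.521), limits of agreement (-10.829, 14.734)
#>   MSE: 44.210 cm^6
#>   paired t = 1.339, df = 19, p = 0.1964; mean-diff CI (-1.099, 5.004)
#>   Shapiro-Wilk W = 0.9493, p = 0.3559

agreement(cohort, x_col = "vribp_cm3", y_col = "vrps_cm3")
#> Method agreement: vribp_cm3 vs vrps_cm3 (n = 20, differences = vribp_cm3 - vrps_cm3)
#>   Lin's rho_c: 0.9105 (95% CI 0.8250, 0.9553)
#>   mean difference: -12.058 cm^3 (SD 5.778), limits of agreement (-23.382, -0.734)
#>   MSE: 177.112 cm^6
#>   paired t = -9.334, df = 19, p = 1.579e-08; mean-diff CI (-14.762, -9.354)
#>   Shapiro-Wilk W = 0.9803, p = 0.9378
```

Reading of the output: the slice engine (`pdp`) and the mesh engine on
the same smoothed contour (`vrps`) agree almost perfectly (ρc = 0.978,
mean difference ≈ 2 cm³, not significant), while the inner-blood-pool
volumes (`vribp`) are significantly smaller than the smoothed-contour
volumes (mean deficit ≈ 12 cm³, paired t = −9.3, p ≪ 0.001) — the
pattern expected when trabeculae and papillary muscles are excluded
from the lumen.

`plot(agreement(...))` draws the Bland–Altman plot. `run_study()` (or
`exec/chambervol study --config cfg.json`) runs the whole three-method
design over LV- and RV-like strata and writes per-subject CSV, summary
table, agreement JSONs and a run log.

See `vignettes/chamber-volumetry.Rmd` for the model details, generator
design and numerical choices.

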