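# rvecv

Quantification of right-ventricular (RV) myocardial extracellular volume
(ECV) from cardiac MRI T1 maps.

## The problem

Diffuse myocardial fibrosis expands the extracellular space, and the
expansion can be measured non-invasively: gadolinium contrast distributes
in the extracellular compartment, so the contrast-induced change in the
longitudinal relaxation rate R1 = 1/T1 of myocardium, referenced to blood
and scaled by the plasma fraction, yields the extracellular volume
fraction

```
ECV = (1 - hematocrit) * (1/T1_myo_post - 1/T1_myo_pre)
                       / (1/T1_blood_post - 1/T1_blood_pre)
```

For the left ventricle this is routine: draw a region of interest (ROI) in
the wall, average T1, apply the formula. The RV free wall, however, is
only about one to two pixels thick on clinical T1 maps, so a planimetric
contour that strays by a single pixel blends myocardium with blood and
corrupts the estimate. `rvecv` implements a centerline alternative — a
"line of interest" (LOI) drawn along the mid-wall whose *crossed pixels*
are averaged, with no wall contouring at all — together with conventional
ROI planimetry, quality/wall-thickness grading with feasibility rules, a
synthetic short-axis phantom with exactly known ground truth, and the
agreement statistics (Pearson/Spearman correlation, Bland–Altman,
observer-variability tables) used to validate LOI against ROI.

Who it is for: image-analysis researchers working on thin-structure
quantification in parametric maps, and anyone who needs a fully synthetic,
ground-truthed test bed for ECV measurement pipelines.

## What is inside

| Area | Functions |
| --- | --- |
| Map / geometry I/O | `read_t1map`, `write_t1map` (text + single-frame DICOM), `read_geometry`, `write_geometry` |
| Sampling | `trace_loi_pixels` (supercover), `rasterize_polygon` (even-odd, top-left rule), `loi_stats`, `roi_stats`, `max_wall_thickness_px`, `wall_grade` |
| ECV | `compute_ecv`, `derive_post_t1_myo`, `assess_feasibility`, `subject_ecv_table`, `ecv_cohort_summary` |
| Phantom | `phantom_spec`, `render_phantom`, `simulate_molli`, `fit_t1_molli`, `apply_misregistration`, `estimate_and_correct_misregistration`, `cohort_generator` |
| Agreement | `ecv_correlation`, `bland_altman`, `observer_variability` |
| Experiments | `run_feasibility_experiment`, `run_loi_vs_roi_experiment` |

A thin command-line front end (`exec/ecv`) wraps the same functions:
`ecv phantom`, `ecv compute`, `ecv compare`,
`ecv experiment feasibility|loi-vs-roi`.

## Worked example

Render a noisy phantom with a 1.5-pixel RV wall, sample its centerline,
and compute ECV:

```r
library(rvecv)

ph <- render_phantom(phantom_spec(grid = c(96, 96),
                                  rv_wall_thickness_px = 1.5,
                                  noise_sd = 0.02,
                                  supersample_factor = 8, seed = 42))
loi      <- loi_stats(ph$native, ph$geometry$lois$rv_loi)
loi_post <- loi_stats(ph$post,   ph$geometry$lois$rv_loi)
bl       <- roi_stats(ph$native, ph$geometry$rois$blood_roi)
bl_post  <- roi_stats(ph$post,   ph$geometry$rois$blood_roi)
print(loi)
#> sample_stats: n = 64, mean T1 = 986.4 ms, SD = 132.1 ms (0 NaN excluded)
compute_ecv(loi$mean_t1, loi_post$mean_t1,
            bl$mean_t1, bl_post$mean_t1, hematocrit = 0.43)
#> LOI RV ECV = 0.333   (planted ground truth 0.31)
```

The centerline crossed 64 pixels; at a 1.5-pixel wall some of them are
blood-blended, which is why the measurement lands slightly *above* the
planted 0.31 — exactly the partial-volume overestimation that makes walls
below one pixel unmeasurable. The wall grade confirms the regime:

```r
reg <- rasterize_polygon(ph$geometry$rois$rv_roi, dim(ph$native$values))
max_wall_thickness_px(ph$truth$rv_mask * 1, reg, 8)
#> max wall thickness 1.48 px -> grade 2
```

Method comparison on a small synthetic cohort:

```r
run_loi_vs_roi_experiment(n_subjects = 10, seed = 7, grid = c(96, 96))
#> LOI vs ROI on 9 measurable subjects (seed 7)
#> Bland-Altman: ROI - LOI (n = 9)
#>   bias -0.00457 (SD 0.006225), 95% CI [-0.009355, 0.0002156]
#>   limits of agreement [-0.01677, 0.007632]
#>   Pearson r = 0.9957 (p = 1.68e-08)
```

One of the ten subjects drew a wall graded below one pixel and was
excluded by the feasibility rule; the remaining nine agree strongly
between methods.

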