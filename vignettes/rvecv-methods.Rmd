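---
title: "Measuring right-ventricular ECV with centerline sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring right-ventricular ECV with centerline sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvecv)
```

## The measurement model

Gadolinium contrast distributes in the extracellular space, shortening T1
in proportion to its local concentration. With T1 of myocardium and blood
measured before and after contrast, and the hematocrit converting the
blood distribution volume to plasma, the extracellular volume fraction is

$$\mathrm{ECV} = (1-\mathrm{hct})\;
\frac{1/T1_{\mathrm{myo,post}} - 1/T1_{\mathrm{myo,pre}}}
     {1/T1_{\mathrm{blood,post}} - 1/T1_{\mathrm{blood,pre}}}.$$

The model assumes equilibrium contrast distribution between blood and
interstitium at acquisition time, a common field strength/sequence for all
four T1 values, and a hematocrit drawn close to the scan. `compute_ecv()`
works in ms and forms rates in 1/ms; the ratio cancels the unit, and a
test asserts invariance under rescaling all four T1 values. Its closed-form
inverse `derive_post_t1_myo()` solves the same equation for the
post-contrast myocardial T1 — that is how the phantom plants a ground-truth
ECV that is exact by construction rather than approximately calibrated.

Degenerate inputs are handled explicitly rather than clipped: a
non-positive blood $\Delta R_1$ (post T1 not shorter than native) is an
acquisition failure and errors; a negative myocardial $\Delta R_1$ returns
a flagged negative ECV with a warning so that the record can be excluded
with a recorded reason, mirroring how unquantifiable cases are handled in
reading studies.

## Two samplers, one statistic

Both measurement methods reduce to "average T1 over a pixel set":

* **ROI (planimetric standard).** `rasterize_polygon()` selects the pixels
  whose *centers* fall inside the operator contour under the even-odd
  rule. A center lying exactly on an edge is resolved by the top-left
  rule, implemented by nudging the test point by $2^{-32}$ pixels toward
  the bottom-right; the convention is arbitrary but fixed, documented, and
  tested, so two implementations of the package agree on boundary ties.
* **LOI (centerline).** `trace_loi_pixels()` returns exactly the pixels
  whose open interior is crossed by the polyline (supercover traversal),
  each once, in first-crossing order. Pixels touched only at a corner or
  only along a shared edge are *excluded*: the crossing must have positive
  length inside the open pixel square. This makes the diagonal-through-
  corners case deterministic and lets an independent brute-force oracle
  (per-pixel segment clipping, plus dense point sampling) verify the
  traversal exactly in the test suite.

Coordinates follow one convention everywhere: continuous $(row, col)$ with
the origin at the top-left corner of pixel $(0,0)$, pixel $(r,c)$ owning
the half-open square $[r,r+1)\times[c,c+1)$. Sub-pixel geometry in a
1–2-pixel wall is meaningless without this kind of pin-down.

`loi_stats()`/`roi_stats()` report the unweighted mean and the
*population* SD (divide by $n$) of the finite sampled values; NaN pixels
are excluded and counted. The unweighted mean is the most literal reading
of "use the pixels crossed by the line"; a chord-length-weighted variant
(`length_weighted = TRUE`) is provided for sensitivity analysis because
drawing tools could plausibly weight by traversed length, but it is not
the default. When an ROI encloses exactly the pixels an LOI crosses, the
two statistics are identical — the formal link between the methods, and a
test.

Geometry is validated against the acquisition protocol: myocardial
geometry must be at least 10 mm long (`validate_min_length()`), measured
as path length for an LOI and as the longest vertex chord for an ROI,
since the protocol prescribes a *length*, not an area. Anisotropic pixel
spacing is honored throughout (traversal in pixel units, lengths in mm).

## Wall thickness and feasibility

RV measurability is graded twice: image quality (grade 1–2 usable, 3 not)
and maximum wall thickness per ROI in pixels (grade 1: > 2 px, grade 2:
1–2 px, grade 3: < 1 px). `assess_feasibility()` declares a measurement
feasible iff both grades are ≤ 2 and both maps exist; failures carry
machine-readable reasons (`insufficient_contrast`, `wall_below_1px`,
`missing_map`), and `subject_ecv_table()` logs every exclusion so cohort
accounting stays auditable.

Thickness itself is measured on a supersampled binary myocardium mask as
the diameter of the largest inscribed disc: the maximum of the Euclidean
distance transform (EBImage's `distmap`) over the region, doubled. The
EDT maximum is attained on the medial axis, so no explicit skeletonization
is needed. Because `distmap` measures center-to-center distances, a band
$w$ subpixels wide yields $\max d = (w+1)/2$ for odd $w$ and $w/2$ for
even $w$; the estimator $(2\max d - 1)/f$ (supersample factor $f$) is
exact for odd counts and one subpixel low for even counts, i.e. the
resolution is $1/f$ map pixels — with the default $f = 8$, an eighth of a
pixel, ample for thresholds at 1 and 2 px. In phantoms the ground-truth
mask is used; for real maps without a mask the native map is thresholded
at the blood/myocardium midpoint T1 as an automated stand-in for the
visual grading a human reader would do (it is labelled as the package's
own automation, not part of the original reading protocol).

## What the phantom emulates

`phantom_spec()`/`render_phantom()` build a midventricular short-axis
slice: a circular LV annulus around a blood cavity, and the RV free wall
as a **concentric annular sector of constant width** whose thickness
(0.25–4 px) is the experiment's main dial, with RV cavity blood filling
the gap to the LV epicardium. A crescent between two *offset* circles
would look more anatomical but makes "the" wall thickness ill-defined;
the constant-width sector keeps the planted thickness exact and
guarantees disjoint tissue masks, which the truth invariants test. The
offset field is retained for future use.

Default tissue parameters are representative patient-level values at
1.5 T: native myocardium 1018 ms, native blood 1492 ms, post-contrast
blood 531 ms, hematocrit 0.43, target RV ECV 0.31. The default grid is
192×192 at 1.9 mm — a typical MOLLI in-plane resolution, declared as an
assumption since acquisition matrices vary; everything is configurable,
and wall thickness is specified in pixels precisely because the grading
thresholds are.

Pixels are formed from a supersampled tissue-label image (factor ≥ 4; 4–8
used throughout) in one of two partial-volume modes:

* `r1_domain`: area-weighted average of subpixel $R_1$, then invert —
  the closed-form model of fast-exchange mixing; noiseless rendering uses
  it directly.
* `signal_domain`: mix the subpixel MOLLI *signals* within the pixel,
  then fit T1 — what a scanner actually does. The two modes agree on pure
  pixels to fit tolerance and differ genuinely on boundary pixels (both
  tested).

The MOLLI machinery is faithful at the signal level: scheme 3(3)5 with
3-beat pauses, base TIs 120/200/280 ms, RR 1000 ms (a literal reading of
the 3b(3b)3b(3b)5b shorthand; the true TI spacing of any given scanner is
unknown, and every recovery test is against planted truth, not protocol
fidelity). Signals are signed (phase-sensitive reconstruction), noise is
additive Gaussian on signal — not Rician, which magnitude reconstruction
would need — and `fit_t1_molli()` recovers $(A, B, T1^*)$ per pixel by
variable projection: the two linear parameters are profiled out, and
$T1^*$ is found by a log-spaced grid search (48 points over 30–5000 ms)
plus 45 vectorized golden-section iterations, then corrected with the
Look-Locker factor $T1 = T1^*(B/A - 1)$. Defaults $A = 1$, $B = 1.95$
keep the correction non-trivial (with $B = 2A$ the factor degenerates to
1, which a test exploits as an algebraic identity). Non-physical fits
($A \le 0$, $B/A \le 1$, fewer than 3 finite samples) return NaN rather
than a number.

Inter-frame misregistration is modeled as integer translations with NaN
edge fill, and corrected by maximizing the absolute normalized
cross-correlation of magnitude images against the last-TI frame —
magnitude because frames near the signal null flip sign, which makes
signed correlation unstable; ties break toward the smallest shift.
Recovery is exact in the noiseless case and survives 2 % signal noise in
≥ 95 % of seeded trials (both tested).

**What the phantom does not emulate:** trabeculation, epicardial fat,
through-plane motion, B1/off-resonance MOLLI bias, Rician noise floors,
and operator variability in drawing. Passing tests therefore demonstrate
correctness of the *measurement machinery* under controlled geometry and
noise — not clinical accuracy on patient images, where those confounders
dominate the residual error.

## The synthetic cohort and the two experiments

`cohort_generator()` draws per-subject truth: RV ECV from a truncated
normal (mean 0.31, SD 0.05, bounds 0.15–0.55 — patient-level dispersion),
hematocrit 0.43 ± 0.05 (0.20–0.60), native myocardial/blood and
post-contrast blood T1 around 1018 ± 30, 1492 ± 88 and 531 ± 73 ms, wall
thickness uniform on 1–3 px, with hematocrit redrawn where a draw would
violate ECV < 1 − hct. Every stage is seed-deterministic; the parameter
draws are exposed separately (`cohort_parameters()`) so their
distributions can be checked without rendering images.

`run_feasibility_experiment()` sweeps wall thickness 0.5–3.0 px in 0.25
steps, ten noise realizations each at signal SD 0.02, and tabulates the
absolute ECV error by method. Below one pixel the error inflates and the
measured ECV is biased *upward*, toward the blood limit $1-\mathrm{hct}$
— the computational embodiment of the ≥ 1 px feasibility rule and of the
partial-volume overestimation concern. The sweep runs on a 64×64 grid
(supersample 8): the phantom radii are resolution-independent, so the
smaller canvas changes nothing but runtime.

`run_loi_vs_roi_experiment()` measures every cohort subject with both
samplers and reports the correlation and Bland–Altman agreement between
ROI-ECV and LOI-ECV. On the default 40-subject cohort (128×128 grid,
supersample 4) the methods correlate at r ≥ 0.9 with |bias| ≤ 0.01 — the
synthetic analogue of the strong ROI/LOI agreement that motivates the
centerline method. One systematic effect is worth stating plainly: at
walls near one pixel the LOI's supercover picks up edge pixels that an
inset ROI contour avoids, so LOI runs very slightly hot and the ROI−LOI
bias is a small negative number close to the 0.01 boundary; it is a real
property of centerline sampling in sub-2-pixel walls, not a bug, and it
disappears as walls thicken (the noiseless thick-wall phantom recovers
truth to < 0.005 by both methods).

## File formats and numerical conventions

* **Text maps**: header `rows cols spacing_r spacing_c phase orientation`,
  then whitespace-separated values with `nan` for invalid pixels — fully
  diffable fixtures at full precision. The six-token header cannot carry a
  subject id or contrast delay; those ride only in the DICOM dialect.
* **DICOM**: minimal single-frame Explicit VR Little Endian with
  PixelSpacing, unsigned 16-bit pixels under RescaleSlope/Intercept
  (default slope 0.1 ms ⇒ worst-case quantization 0.05 ms), NaN stored as
  the sentinel word 0xFFFF. Missing PixelSpacing is a hard error. Values
  outside the 0–5000 ms plausibility band are NaN'd on load and counted
  in a load report; a plausible value is never silently altered.
* **Geometry sidecars**: JSON with vertex lists in continuous pixel
  coordinates and a tissue tag per item; lossless round trip.
* Self-intersecting polygons load with a warning (the even-odd rule still
  defines their interior); polylines under 2 or polygons under 3 vertices
  are hard errors, as is a polygon enclosing no pixel center.

## Problem sizes

Simulation sizes are chosen so the whole validation suite runs on a
laptop-class single core: phantoms 64–96 px for sweeps and unit checks,
128 px for the cohort, supersample 4–8, 40-subject default cohort, 1000
draws for the algebraic round-trip property, 100 random polylines/polygons
against the geometry oracles. They are the package's own defaults, and
all of them are arguments.

## Known limitations

* The wall-thickness estimator's parity bias (one subpixel for even-count
  bands) is bounded by $1/f$ map pixels; choose $f \ge 8$ if grading near
  the 1 px or 2 px thresholds matters.
* The DICOM dialect is deliberately minimal — single frame, one transfer
  syntax, no sequences; it is not a general DICOM library.
* The misregistration model is integer, in-plane, per-frame; rotation and
  sub-pixel motion are out of scope.
* The automated blood/myocardium-midpoint threshold used to grade wall
  thickness without a truth mask is a stand-in for visual grading and
  degrades with noise and adjacent structures of similar T1.
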