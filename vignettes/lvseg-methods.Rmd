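---
title: "Segmenting the left ventricle: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the left ventricle: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

lvseg segments the endocardial and epicardial boundaries of the left
ventricle (LV) on short-axis cine cardiac MR, slice by slice, with no user
interaction. This vignette explains the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic
phantom does and does not establish about real data.

## The segmentation schema

Short-axis cine MR stacks show the LV blood pool as a bright disc inside the
darker myocardial annulus. Segmentation starts at the mid-ventricular slice,
where the cavity is most reliably near the image center, and marches
independently toward the base and toward the apex. Each segmented slice
passes its endocardial center, blood-pool mask, endocardial region and
epicardial region to the next slice as context: the next ROI is centered on
the previous endocardial centroid, the LBF model is initialised from the
previous endocardial region, and the previous epicardial region (dilated)
restricts the epicardial search. A failed slice forwards the last successful
context rather than aborting the march, since downstream evaluation scores
per contour.

## Blood-pool localisation: the LBF model

The local binary fitting (LBF) model is a region-based level set whose
fitted inside/outside intensities are *local* — Gaussian-weighted averages
around each pixel:

$$f_i(x) = \frac{K_\sigma * (M_i(\phi)\, I)}{K_\sigma * M_i(\phi)},\qquad
M_1 = H_\varepsilon(\phi),\; M_2 = 1 - H_\varepsilon(\phi),$$

with $H_\varepsilon(z) = \tfrac12\big(1 + \tfrac2\pi \arctan(z/\varepsilon)\big)$.
Locality makes the model robust to the slowly varying receive-coil bias that
defeats global two-phase models. The evolution adds an arc-length
regulariser (weight $\nu$) and a distance regulariser (weight $\mu$) that
keeps $\phi$ well-conditioned without re-initialisation, which is why a
binary $\pm 2$ step initialisation suffices.

Parameters (all in `lv_config()`): $\lambda_1 = \lambda_2 = 1$ (neither
region favoured), $\sigma = 3$ px (locality scale: about half a wall
thickness), timestep $0.1$, $\varepsilon = 1$ px,
$\nu = 0.003\,(\text{intensity range})^2$ (scales the curvature force to the
squared-intensity units of the data force), $\mu = 1$, at most 300
iterations or a mean $|\Delta\phi|$ below $10^{-3}$. These are standard
choices for this model family; none were fitted to data.

Two details matter in practice:

* **Component selection.** A converged two-phase LBF labels *every* locally
  bright structure (RV pool, fat) positive. The blood pool is the connected
  component of $\{\phi > 0\}$ that overlaps the initialisation mask; only it
  is passed downstream.
* **Initialisation radius.** The mid-slice initialisation is a centred
  circle. Its radius (default 10 px at 1.25 mm/px) must sit *inside* the
  end-systolic mid-cavity: an initialisation larger than the cavity starts
  the front inside the wall, and the region floods across it. Ten pixels
  (12.5 mm) is comfortably inside a normal end-systolic mid-cavity.

## Threshold refinement

The LBF region guides an exhaustive threshold search: 24 candidate
thresholds between the ROI's 5th and 95th intensity percentiles; for each,
the ROI is binarised and the 8-connected component best overlapping the LBF
region is the blood-pool hypothesis. The chosen threshold maximises the
overlap curve, with plateau ties broken toward the Otsu threshold (Otsu is
the natural default but is biased when class variances differ, which is the
point of the search). Overlap is measured as the Dice coefficient between
component and LBF region rather than the raw intersection count: with raw
intersection, any threshold low enough to merge the pool into the
background component scores at least as high as the correct one whenever
the LBF region slightly overcovers the pool, so the search degenerates
toward its lowest candidate. Dice penalises the merged component's size and
restores a well-defined maximum; on clean two-value fixtures the two
metrics choose identically (a constant plateau resolved at Otsu). The raw
intersection remains available as `overlap_metric = "intersection"`.

Holes in the selected component (papillary muscles) are filled, since the
convention here includes papillary muscles and trabeculations in the
cavity.

## Endocardium and the outflow tract

Away from the base, the endocardial contour is the convex hull of the
blood-pool boundary — convexity bridges papillary-muscle notches.

At the basal slice the left ventricular outflow tract (LVOT) locally erases
the wall and the thresholded pool leaks toward the aorta. Marching
basally, a slice is flagged as LVOT when the major axis of the pool hull's
moment-equivalent ellipse exceeds the previous slice's by a ratio
above 1.2 (strict inequality; the ratio is scale-free). The flagged slice is
re-contoured using context: the binary ROI is masked with the previous
pool dilated by 3 px, boundary points go to polar form about the previous
center, an algebraic (Kåsa) circle fit prunes points more than 3 px beyond
the fitted radius (the leak), and the survivors' convex hull is smoothed.
The Kåsa fit is used because it is closed-form and deterministic; one
outlier among 36 circle samples moves its radius by well under 10%. The
hull (not the raw pool) supplies the major axis because the hull is what
the endocardial contour will be; both choices are config-exposed
(`lvot_ratio_threshold`, `pool_dilation_px`, `circle_outlier_px`).

## Epicardium: region-constrained dynamic programming

The ROI is resampled to polar coordinates about the endocardial centroid
(180 angular columns, 1 px radial rows by default), where the closed
epicardial boundary becomes a left-to-right path. The path cost comes from
a non-maxima-suppressed gradient magnitude, min-max normalised to $[0,1]$:
suppression thins each radial edge to a single row. On an exact plateau of
equal gradients the *first* row along the gradient direction survives
(strictly greater than the preceding neighbour, no smaller than the
following), so step edges yield exactly one ridge row and pure ramps yield
none; the first and last radial rows are boundary artifacts and are zeroed.

The admissible region starts one row beyond the endocardial radius of each
column (`endo_margin_rows`), excludes bright cells (thresholded at the
blood-pool threshold: RV pool, pericardial and abdominal fat), and, when a
previous slice is available, stays inside its dilated epicardial footprint.
A fully blocked column reopens at the two rows adjacent to the endocardium
so a path always exists.

The dynamic programme minimises
$$\sum_{j=1}^{N} w\,\big(1 - F(i_j, j)\big) + \gamma\,|i_N - i_1|,$$
subject to $|i_{j+1} - i_j| \le \delta$ *and* $|i_N - i_1| \le \delta$
(defaults $\delta = 2$, $w = 1$, $\gamma = 0.1$). The cost increment
$w(1-F)$ encodes "small values mark likely edges" with an infinite barrier
outside the admissible set. The closure penalty is applied *exactly*: the
recursion runs once per admissible first-column row and the penalty uses
each chain's own start row, rather than approximating with a single global
sweep — at $N \le 360$ the $O(M^2 N \delta)$ cost is negligible. Closure is
also enforced as a hard $\delta$-jump between last and first column, which
is what makes the $\gamma \to \infty$ limit produce exactly closed
(equal-endpoint) paths. Every minimisation breaks ties toward the smaller
row index, making the optimum unique and the whole pipeline deterministic.

## Contour smoothing

Two smoothers serve different geometry. Near-circular contours are smoothed
by an ideal low-pass filter on the periodic sequence of center distances:
$\rho' = \mathrm{IFFT}(H \cdot \mathrm{FFT}(\rho))$, keeping the DC term and
the first `keep_harmonics` harmonics (default 8 — enough for the mild
ovality of a ventricle, and the mean radius is preserved exactly).
Polygonal contours are smoothed by a closed least-squares piecewise-cubic
fit (a periodic uniform cubic spline; every span is an exact cubic Bezier
arc with better-than-C1 joins) and resampled uniformly. The pipeline
applies the FFT smoother to the endocardium and the Bezier fit to the
epicardium; the assignment is a config switch
(`smoothing_assignment`) because the two conventions appear interchangeably
in practice, and the LVOT branch additionally Bezier-smooths its own
contour as part of its construction.

## Evaluation metrics

The average perpendicular distance (APD) is directed from the automatic to
the expert contour (mean over automatic vertices of point-to-segment
distance, scaled to mm); a symmetric variant exists but is off by default,
matching the challenge tool. A contour is *good* when APD < 5 mm
(strict); APD and Dice are pooled over good contours only. Volumes are
slice summations of exact polygon (shoelace) areas times slice spacing;
EF $= (EDV - ESV)/EDV \times 100$; LV mass is the end-diastolic myocardial
volume times a density of 1.05 g/mL (the conventional myocardial density;
configurable). Center-to-center slice spacing is used throughout.
Agreement between two raters of EF or mass is summarised by OLS regression
($R^2$) and Bland-Altman bias with 1.96 SD limits.

## The phantom: what it emulates, and what it does not

The generator builds, per phase and slice, a bright cavity disc (intensity
200) inside a myocardial annulus (60) on a brighter background (110 — the
ordering that makes the epicardial edge the weak one), an adjacent RV
crescent (190), a pericardial fat arc hugging the epicardium (230), radii
tapering linearly base (22 px) to apex (9 px), a deterministic in-plane
center drift (±2 px), an end-systolic phase with cavity radii scaled by
0.7 (analytic EF $= 1 - 0.7^2 = 51\%$), an optional basal LVOT opening (a
70° arc of cavity-bright signal breaching the wall out to 2.1 cavity
radii), a multiplicative low-order polynomial bias (±10%) and additive
Gaussian noise (SD 8, i.e. a contrast-to-noise ratio of about 10 on the
weak epicardial edge's 50-unit step). Geometry (128² images at 1.25 mm,
8 slices at 9 mm spacing) matches a typical 256² / 320 mm acquisition
downsampled by two to keep the full suite fast; all values are
`phantom_spec()` fields.

Truth masks and contours are drawn before noise; the object is a stack of
discs, so its volume has the closed form $\sum_i \pi r_i^2\,\Delta z$ and
the analytic EF is exact. Noise is Gaussian rather than Rician, there is no
papillary-muscle texture, no motion artifact, no trabeculation, and
tissue boundaries are step edges under a smooth bias. Passing the phantom
therefore establishes the pipeline's *mechanics* — propagation, LVOT
branching, DP optimality, metric arithmetic, determinism — not clinical
accuracy on patient data, which requires expert-contoured studies.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, `(x = column, y = row)`, pixel centers at
  integers; contour files store `x y` per line in that convention
  (ambiguity in the source data's base is resolved to 0-based and
  documented). Files are written with 6 decimals so a read/write round trip
  is exact to 1e-6.
* Contours are normalised counter-clockwise in image coordinates (negative
  shoelace sum with y pointing down); rasterisation uses even-odd
  crossing-number fill with a half-open edge rule.
* Convolutions replicate the boundary; the Gaussian kernel is truncated at
  half-width $\lfloor 2\sigma \rfloor + 1$ and renormalised. Local-fit
  denominators are floored at $10^{-10}$.
* Degenerate inputs raise informative errors rather than propagating NaN:
  collinear circle fits, empty pools, sub-3-point contours, thresholds that
  erase the pool, infeasible DP columns, over-aggressive FFT cutoffs.
* Apical termination: a refined pool below `min_pool_area` (20 px) marks
  the slice `skipped_small_pool` — the apical cavity genuinely vanishes and
  pretending otherwise produces noise contours.
* The mid-slice index defaults to the middle of the stack and is
  config-overridable; how the mid-cavity slice is best chosen is left to
  the data source.
* DICOM is not parsed (no reader among this package's dependencies);
  studies enter through a documented plain-text+TIFF fixture format that any
  DICOM toolchain can export, keeping every test and example free of
  binary inputs.

## Problem sizes used by the test suite

The suite validates the DP against exhaustive enumeration of all
δ-feasible closed paths on ≥200 random 5–8 × 6–10 maps (with an exact
shortest-path cross-check standing in where enumeration would exceed ~10⁷
paths), LBF recovery on twenty 64² noisy biased disks, and the full
pipeline on the default 8-slice two-phase phantom, twice (with and without
the LVOT opening), plus a byte-level determinism run. These sizes keep the
complete suite within a coffee break on one CPU while exercising every
stage at the geometry the phantom encodes.

## Known limitations

Real basal slices can show simultaneous LVOT and RV inserts that this
schema handles only through the previous-slice mask; very small apical
pools are skipped, not segmented; the LBF component selection assumes the
initialisation overlaps the true cavity (grossly off-center acquisitions
would need a localisation front-end); and the epicardial search assumes the
boundary is star-shaped about the endocardial centroid, which fails for
strongly non-convex epicardia.
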