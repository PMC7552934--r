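---
title: "Choroidal thickness and vascularity from widefield OCT volumes: methods"
author: "choroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choroidal thickness and vascularity from widefield OCT volumes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroquant)
```

## The problem

The choroid is the vascular layer between retina and sclera. Two
quantities summarize its state in OCT volume scans: the **choroidal
thickness** (ChT), the axial distance in micrometres from the retinal
pigment epithelium (RPE) to the choroidal–scleral interface (CSI), and
the **choroidal vascularity index** (CVI), the percentage of choroidal
voxels classified as vessel lumen. Vessel lumina are hyporeflective and
stroma hyperreflective, so the lumen/stroma split is an intensity
binarization problem. `choroquant` computes both metrics over a
magnification-corrected extended ETDRS grid from a volume scan plus
choroidal segmentation surfaces, and provides the repeatability
statistics appropriate for intersession study designs, together with a
synthetic phantom that makes the whole pipeline testable against known
ground truth.

## Geometry and magnification correction

A volume is indexed `[bscan, ascan, depth]`; depth index 1 is the
vitreous side. Axial distances convert from pixels to micrometres with
the factor `depth_um / depth_px` (1.953125 µm/px for a 3000 µm scan
sampled on 1536 pixels). Lateral distances depend on the eye's optics:
one en-face pixel spans

$$p_{mm} = \frac{(l_a - \Delta_{cp})\,\theta_{air}}{d_p\, n_B}$$

where $l_a$ is the axial eye length (mm), $\Delta_{cp} = 1.82$ mm the
cornea-to-principal-plane distance, $\theta_{air}$ the scan angle in air
(40° here, converted to radians), $d_p$ the en-face extent in pixels and
$n_B = 1.336$ the bulk refractive index. For a 24.83 mm eye on a
1024-pixel axis this gives 0.011742 mm/px. When the two en-face axes
have different voxel counts over the same scan angle, each axis gets its
own scale (`lateral_pixel_scales()`); the grid is then circular in mm
even on anisotropic grids.

## The extended ETDRS grid

Thirteen regions: a central disc of radius 0.5 mm and three rings
(0.5–1.5, 1.5–3.0, 3.0–5.0 mm) split into superior, inferior, temporal
and nasal quadrants at the ±45° diagonals. Analysis is confined to the
10 mm disc even when the scan covers 12 mm. Numerical conventions, all
chosen so the assignment is an exact partition:

* ring bands are half-open in the pixel-centre distance,
  $r_{in} \le r < r_{out}$;
* sector boundaries are half-open angle intervals ([−45°, 45°) and so
  on), so diagonal pixels belong to exactly one sector;
* for left eyes the horizontal coordinate is mirrored before the
  assignment, which makes OD and OS grids bit-exact mirror images,
  half-open boundaries included;
* the optic nerve head is excluded by a configured circle
  (pixel-centre test, boundary included), specified as centre+radius or
  two diameter endpoints — no interactive selection, so runs are
  reproducible headless;
* when the 10 mm disc exceeds the scanned frame the regions are
  clipped, a `truncated` flag is set and a warning raised; region
  statistics then reflect the clipped masks.

The fovea defaults to the geometric scan centre (the acquisition
protocol centres the volume on the fovea) and can be overridden.

## Binarization into lumen and stroma

Four stages, all deterministic:

1. **Liquid norm.** The vitreous baseline intensity is sampled in the
   two central cross-sectional planes at 50% of the slice width and 25%
   of the depth from the image top (the vitreous side), and averaged.
   This anchors intensities against scan-to-scan brightness drift. The
   sampling cannot verify that the point is in the vitreous; callers
   can override the value.
2. **Normalization.** Voxels below the liquid norm are set to 0 and the
   rest rescaled linearly so the volume maximum maps to 255. Anchoring
   at the liquid norm keeps the fluid baseline at zero.
3. **Median blur.** A 3×3 median per B-scan slice (replicate padding)
   to suppress speckle outliers.
4. **Niblack thresholding.** Per pixel, over a *circular* window of
   radius 20 px clipped at the image borders,
   $T = m + k\,\sigma$ with $k = 0.2$, where $m$ and $\sigma$ are the
   window mean and *population* standard deviation. Intensities
   strictly above $T$ are stroma (1); ties and everything below are
   lumen candidates (0), since lumina are hyporeflective.

Binarization runs on whole slices; the choroidal mask is applied
afterwards, so window statistics near the choroid boundary include the
real neighbouring tissue. The circular-window filter is implemented in
C++ with per-row prefix sums (exact for integer-valued images, so it is
bit-identical to a naive double loop; the test suite asserts this
against an independent brute-force oracle).

Known behaviour worth keeping in mind: in windows that contain
essentially one tissue class, $T$ sits just above the local mean, so
Niblack splits even homogeneous regions roughly in half (constant
slices are all-0 by the tie rule). The method therefore relies on every
window containing both phases; see *Limitations*.

## CVI and ChT

With the region-of-interest volume spanned per column from the rounded
RPE depth over the rounded thickness (half-open; fractional surface
values are rounded half-up), the column CVI is
$CVI_{col} = n_v / n_{ROI} \times 100$ (lumen voxels over ROI voxels in
that A-scan column, `NA` when the column has no ROI), and the regional
CVI sums the counts over the in-region, non-ONH columns:
$CVI_{reg} = N_v / N_{ROI} \times 100$. Regional CVI is therefore the
ROI-weighted mean of its column CVIs, and the region partition
conserves voxel counts exactly — both are asserted in the tests.
Regional ChT is the arithmetic mean of the per-column thickness over
the same columns, times the axial factor; the mean (rather than median)
is the conventional ETDRS sector statistic. ONH exclusion applies to
both metrics.

## Repeatability statistics

The study design the statistics serve: three consecutive scans per day
on three separate days, several subjects, 13 regions.

* **Quartile-based CV**: $(Q_{75} - Q_{25})/(Q_{75} + Q_{25}) \times
  100$. All quantiles in the package use linear interpolation of order
  statistics at positions $(n-1)q$ (`stats::quantile` type 7); this
  convention exactly reproduces the published across-region CVs from
  the bundled reference tables (`choroid_reference()`), which pins it.
* **Coefficient of repeatability** (nonparametric, intersession): per
  subject, each day's three replicates collapse to the daily median;
  the deltas of the daily medians from the subject's three-day mean are
  pooled across subjects; the 2.5th/97.5th percentiles of the pooled
  deltas are multiplied by 3/2 (the correction for mean-centred
  triples: centring three i.i.d. values removes 1/3 of the variance,
  and the factor restores the scale of a between-day difference); the
  CR is half the length of the resulting interval. For i.i.d. normal
  daily medians with standard deviation $\sigma_M$ this converges to
  $1.96\sqrt{2/3}\cdot\tfrac{3}{2}\,\sigma_M \approx 2.400\,\sigma_M$,
  which the tests verify by simulation at 10,000 subjects (within 2%)
  and at the study's n = 14 (within ±35% in ≥95% of seeds). Centring is
  per subject; replicates within a day are never compared directly
  (intersession only).
* **Spearman rank correlation**: Pearson correlation of mid-ranks
  (average ranks for ties) with a two-sided *t*-approximation p-value
  on $n-2$ degrees of freedom, for correlating regional values with
  axial eye length.
* **Topography**: all nine scans are averaged per subject first; the
  across-subject median and IQR summarize each region.

## The synthetic phantom

The phantom emulates exactly the structures the pipeline assumes: a
dark vitreous (mean 10) for the liquid norm, a retina (110), a bright
RPE line (220, 3 px), a choroidal band of stroma (140) with vessel
lumina (40) at a controlled volume fraction, a scleral base (90), and
unit-mean multiplicative gamma speckle (shape 4, i.e. 50% intensity
CV, a plausible surrogate for lightly averaged OCT speckle). The RPE
surface is a paraboloid; the thickness profile is flat by default (a
30%-style nasal thinning is available as a parameter when topographic
realism matters more than controlled recovery experiments). Ground
truth — surfaces and the lumen mask — is returned alongside the volume,
and everything is reproducible from the seed.

Vessels are tubes of radius 5–7 px that run along the B-scan axis (in
two half-extent slots) and bend with the band, placed at (A-scan,
relative-depth) positions from per-pass regular grids whose offsets and
depths follow a low-discrepancy sequence with a random phase, with
proposals thinned in proportion to the local band thickness and the
tube radius capped by the remaining volume in the closing passes. The
design goal is a *spatially homogeneous* realized lumen fraction
(within ±0.01 of the target globally, within a few percentage points in
every grid region): real vascular beds are evenly spaced rather than
Poisson-scattered, and an uneven phantom would conflate placement noise
with binarization bias in recovery experiments. Tube radii are chosen
so vessels survive the 3×3 median blur (structures under ~4 px are
erased by it) while keeping many vessels per grid region.

What the phantom does **not** emulate: OCT signal roll-off with depth,
the point-spread function, spatially correlated speckle, retinal-vessel
shadows (available as an option, off by default), anatomically
realistic vessel networks (Haller/Sattler calibre stratification,
bifurcations), or motion artifacts. Passing recovery tests on the
phantom therefore demonstrates the correctness and calibration of the
*pipeline*, not performance on device data.

## Problem sizes used in the tests

The test suite and validation battery run phantoms at 64 × 128 × 256
voxels (a scaled-down counterpart of the 1024 × 1024 × 1536 device
format), repeatability simulations at 10,000 subjects for the
asymptotic law and 14 subjects for the study-size check, and oracle
equalities on 15×15 and 31×31 slices; these sizes are the package's
choice of a desk-scale validation battery.

## Limitations

* **Low lumen fractions bias high.** With $k = +0.2$ the Niblack
  threshold sits above the class valley when stroma dominates a window,
  so the recovered lumen fraction overshoots the truth as the true
  fraction falls below ~0.65; at the healthy-choroid range (≈0.70–0.75)
  the full pipeline recovers regional truth within ±5 percentage
  points, while at a fraction of 0.60 the worst-region error exceeds
  that band (the validation battery computes and reports the exact
  figure). This is a property of the binarization method, not of its
  implementation — the brute-force oracle shows the same behaviour.
* **Band-edge windows are contaminated.** Within a window radius of the
  RPE or CSI, the threshold is inflated by bright out-of-band tissue;
  at the scaled-down test geometry (band ≈ 100 px vs. a 41 px window)
  this affects a larger share of the choroid than at device resolution.
* **Vessel walls flip under the median blur.** The 3×3 median
  reassigns a one-voxel staircase layer at lumen/stroma interfaces, so
  even zero-noise phantoms are recovered at ~98% voxel agreement
  rather than perfectly; the tests assert that the disagreements are
  confined to the wall layer.
* No ocular-curvature correction is applied to peripheral distances,
  and retinal-vessel shadows are not compensated.
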