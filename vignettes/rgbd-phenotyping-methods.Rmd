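---
title: "Methods: depth quality metrics and metric size estimation for close-range RGB-D phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth quality metrics and metric size estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbdpheno)
```

This vignette documents the models and procedures the package implements, the
conventions and parameter choices behind them, what the synthetic scene
generator does and does not emulate, and the known limits of the measurements.

## The measurement model

All measurements rest on the pinhole back-projection of a depth pixel to a
camera-frame 3D point,

$$X = D_{x,y}\,\frac{c_x - x}{f_x},\qquad
  Y = D_{x,y}\,\frac{c_y - y}{f_y},\qquad
  Z = D_{x,y},$$

with depth $D_{x,y}$ in millimetres, focal lengths in pixel units and 0-based
pixel coordinates. Two conventions matter:

* **Sign.** The $(c - x)$ form mirrors the more common $(x - c)$; it only
  flips the axis directions, and every quantity we derive is a distance, so
  nothing downstream changes. We keep it as the package's canonical form.
* **Z-depth.** Depth is taken as the Z-coordinate of the surface point, not
  the ray length; the renderer stores exactly this quantity, so rendered and
  measured geometry agree by construction.

The metric span of a pixel pair (`pair_distance()`) back-projects *both*
pixels at the **mean of their two depth readings** and then takes the 3D
Euclidean distance. With a shared depth the span reduces to
$\bar D\sqrt{(\Delta x/f_x)^2 + (\Delta y/f_y)^2}$ — translation-invariant and
robust to the strong per-pixel depth fluctuations at object silhouettes. This
averaged-depth convention is used for ball diameters and stem widths alike,
because the stem measurement is defined as "the same computation as the ball
diameter".

Object diameters are the average of **two** pixel-pair spans. Where a human
operator would pick the pairs on opposite sides of the perimeter, the package
uses a deterministic stand-in: the leftmost/rightmost set pixels on the row
through the mask centroid, and the topmost/bottommost on the column through
the centroid. This preserves the manual protocol's intent (two roughly
orthogonal diameters) while being reproducible; it is *not* sub-pixel edge
localization, which is deliberately out of scope.

**Endpoint depth screening.** Perimeter pixels are exactly where depth
dropout and background bleed-through concentrate. An endpoint's depth reading
is accepted only if it is non-zero and (when an object mask is available)
inside the ±250 mm object window around the mask's *median* non-zero depth —
the same window the background-removal step uses, with the median because the
fringe can contaminate a mean. A rejected reading is replaced by the nearest
accepted reading up to 3 px inward along the pair's axis; the pixel
*coordinates* are kept, so the measured span is unchanged and only the depth
scale is sourced from the object's surface. If a pair has no usable depths it
is dropped (with a warning) and the estimate falls back to the remaining
pair.

Error metrics against a known size $\Phi$ are
$\mathrm{RMSE} = \sqrt{\tfrac1N\sum_i (d_i - \Phi)^2}$ and the mean relative
average error $\mathrm{MRAE} = \tfrac1N\sum_i |d_i - \Phi| / \Phi$; for a
single estimate $\mathrm{MRAE} = \mathrm{RMSE}/\Phi$.

## Fill rate, lighting bands, background removal

A depth pixel in a region of interest is **valid** if non-zero and within 3
standard deviations of the mean of the ROI's non-zero depths; the **fill
rate** is the valid fraction. Two choices the definition leaves open are fixed
as: the *sample* SD ($n-1$ denominator), and a *single pass* (no
re-estimation after excluding outliers). With fewer than two non-zero pixels
the rule degenerates to the non-zero test.

Illuminance is banded as sunrise ($<1{,}000$ lx), overcast
($1{,}000$–$10{,}000$), full daylight ($10{,}000$–$32{,}000$) and direct
sunlight ($\ge 32{,}000$); bands are half-open with the upper band claiming
the boundary ("32,000 lux and above"), and they tile $[0,\infty)$.

Background removal keeps color pixels whose depth lies within ±25 cm of the
known object distance and rescues any pixel with an in-band neighbour within
a 10-pixel radius, so object pixels with missing or corrupted depth survive.
"Radius" is interpreted as Euclidean distance in pixel units
($\Delta x^2 + \Delta y^2 \le 10^2$).

## The stem-width pipeline

Given a stem detection box and a pluggable segmenter (any function mapping a
crop to a same-size binary mask — a learned instance segmenter in production,
a label-mask thresholder on synthetic data):

1. crop color and depth to the box;
2. segment; estimate orientation as the incline of the line joining the
   topmost and bottommost mask pixels (ties broken toward the leftmost
   pixel), measured from vertical in $(-90^\circ, 90^\circ)$;
3. rotate the crop by that angle to bring the stem upright — color
   bilinearly, depth and labels nearest-neighbour (depths must never be
   blended across an object boundary); out-of-canvas pixels become 0;
4. segment again on the canonized crop;
5. for each row of the **middle third** of the mask's occupied row range,
   take the leftmost→rightmost span; drop rows whose pixel length deviates
   from the mean by more than 3 sample SDs (single pass; interior mask holes
   are ignored by construction); average the surviving spans' metric lengths
   (averaged-depth convention, same endpoint screening as the diameters).

"Middle area" is implemented as the middle third of the occupied rows —
symmetric, scale-free, and away from both the leaf collar and the soil line
in practice. Orientation deliberately uses the extreme-pixel line rather
than PCA, matching the field protocol it reproduces; it is more sensitive to
silhouette noise, which the inclination-recovery tests quantify (errors stay
below $0.7^\circ$ on synthetic stems of $\ge 100$ px height).

Failures (empty masks, degenerate geometry, no usable depths) are recorded
per stem; remaining detections are still processed.

## The synthetic scene generator

`render_frame()` ray-casts spheres, finite open cylinders and planes, one
center ray per pixel for **depth** (the Z of the nearest hit; 0 where
nothing is hit) — so depth images have crisp, unsmoothed silhouettes — and a
5-subray (center + footprint corners) **conservative rasterization** for the
**label mask**, so the mask covers the object's full image footprint the way
an annotator would outline it. The distinction is deliberate:

* the depth silhouette (non-zero pixels) is unbiased for area quantities
  (a sphere's silhouette pixel count tracks $\pi (r f_x / Z_c)^2$);
* the label-mask extremes give a center-to-center pixel span whose
  expectation equals the true projected diameter $2R$, where a center-ray
  mask would be biased one pixel low — on a 12 px silhouette, a 1.7 px
  (−15 %) systematic error that no averaging removes. Label fringe pixels
  whose center ray misses the object carry background (or zero) depth,
  exactly as real sensors behave at silhouettes, and are handled by the
  endpoint screening described above.

The default experiment layout mirrors the outdoor protocol: two reference
balls of 50 mm and 7.8 mm diameter, a row of vertical 8-mm-wide stems
(radius 4 mm — the smaller ball is described as comparable to a young maize
stem), an optional background stem row, and a backdrop plane 1 m behind the
targets, at seven distances from 0.2 to 1.5 m. The exact seven positions are
not prescribed; the package fixes `c(200, 400, 600, 800, 1000, 1200, 1500)`
mm once. Twelve acquisition cycles with a plausible sunrise-to-sunset lux
curve are the default replication structure.

`apply_sensor()` degrades an ideal frame with, in order: the working-range
cut; additive zero-mean Gaussian noise with $\sigma(Z)$ constant, linear
(time-of-flight behaviour) or quadratic (triangulation behaviour) in depth;
a range re-check (negatives and out-of-range values become missing);
independent per-pixel dropout with probability `base + slope × band index`
(lighting affects fill rate far more than accuracy in field reports, so lux
enters as a dropout modifier only, with noise lux-independent by default);
and a fraction of gross outliers. Published sources pin the noise *families*
but not per-device magnitudes, so the presets (`sensor_preset()`) carry the
documented ranges and resolutions with free, plausible coefficients — they
are emulations for exercising the analysis machinery, not calibrated device
models. Everything is deterministic given the profile and an explicit seed;
the experiment runner derives per-frame seeds from the config seed by a
frame counter, so enlarging an experiment never perturbs existing frames.

What the generator does **not** emulate: photometric realism, IR speckle,
leaf/canopy geometry, occlusion, multi-sensor interference, and lens
distortion (frames are treated as registered and distortion-free). Passing
the synthetic recovery suite therefore demonstrates the correctness of the
*computations* under controlled degradation — not field accuracy on real
plants, which depends on segmentation quality and sensor behaviour outside
this model. In particular the field benchmark for stem width (caliper
comparisons) is outside what synthetic data can certify.

## Statistics for sensor comparison

Fill rates (and squared size errors) are compared across sensors per object
class with:

* **Levene's test**, mean-centered (the classic form, not the
  Brown–Forsythe median variant), as the homogeneity-of-variance gate;
* **Welch's one-way ANOVA** for unequal variances, with its standard
  approximate degrees of freedom; at $k=2$ it equals the squared Welch
  t-test;
* **Games–Howell** post hoc pairwise comparisons:
  $t = |\bar x_i - \bar x_j| / \sqrt{s_i^2/n_i + s_j^2/n_j}$ with
  Welch–Satterthwaite df, referred to the studentized-range distribution
  with $k$ groups at $q = t\sqrt2$ (the standard formulation; reported $t$
  is the absolute value, and reductions at $k=2$ recover the two-sided
  Welch t-test p-value exactly). The studentized-range CDF is base R's
  `ptukey()`.

Error distributions are summarised by bias, SD, moment skewness and a
histogram, supporting the judgement of whether per-object errors are
Gaussian enough for averaging to sharpen population estimates.

## Numerical choices and degenerate inputs

* Depth unit is the millimetre everywhere; 0 encodes missing. Files:
  16-bit single-channel TIFF for depth, 8-bit PNG for color and masks, CSV
  for tables.
* Validity/line filters use sample SD and a single pass; zero spread keeps
  everything.
* Masks that span fewer than 2 rows/columns (pair selection), 2 rows
  (orientation) or 3 rows (width lines) raise typed errors rather than
  returning degenerate measurements; the pipeline converts them into
  per-stem failure records.
* Rotation never invents depth values: nearest-neighbour lookup only, so a
  rotated depth raster contains only input values and 0.
* `estimate_diameter()` falls back from two pairs to one with a warning;
  `measure_stem_width()` skips lines without usable depths and errors only
  when none survives.

## Validation design and problem sizes

The test suite validates each operation against independent brute-force
oracles (back-projection, spans, RMSE/MRAE, fill rate, line filter),
recovers injected parameters (dropout rates within 3 binomial standard
errors on 200×200 frames), and checks behavioural properties: diameter RMSE
growing with range under depth-proportional noise (500 Monte-Carlo
replicates at 0.4/0.8/1.2 m, fixed seeds, noise coefficient 0.005 — a
typical time-of-flight figure of 0.5 % of range, fixed a priori), stem
width and orientation recovery across 0.3–1.5 m and inclinations up to
30°, and the statistical identities plus a 2000-replicate null calibration
of the Welch test at the 0.05 level. These sizes keep the whole suite in a
few CPU-minutes while leaving the binomial/Monte-Carlo tolerances
meaningful.

## Known limitations

* **Pixel quantization floors the far-range width accuracy.** An 8 mm stem
  at 1.5 m under a 600 px focal length subtends 3.2 px; the mask span is an
  integer, so a single pixel is a 31 % relative step. Vertical stems are the
  worst case — every mask row quantizes identically, so no averaging over
  rows dithers the error — and per-condition width errors of 6–25 % appear
  beyond ~0.9 m in the validation sweep (orientation recovery is unaffected).
  Sub-pixel edge localization could lift this floor but is intentionally out
  of scope; at close range (≤0.6 m) recovery stays within 5 %.
* The depth-vs-label silhouette conventions above are a model of annotator
  behaviour; real annotation noise is not simulated.
* Games–Howell p-values assume approximately normal group means; with very
  small groups (n < 5) the studentized-range approximation is rough.
* The lux model affects dropout only; sensors whose *accuracy* (not just
  fill rate) degrades in sunlight need a custom profile with lux-dependent
  noise, which the profile structure admits but no preset enables.
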