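# rgbdpheno

Close-range RGB-D plant phenotyping in R: depth-quality metrics, metric size
estimation from depth maps, and the statistics used to compare consumer depth
sensors in the field.

Consumer RGB-D cameras (time-of-flight and triangulation devices in the
Kinect/RealSense class) are attractive for outdoor phenotyping — measuring
stem widths, fruit sizes and canopy structure without touching the plant —
but their depth maps degrade badly at close range, in bright sunlight, and on
thin or reflective targets. This package implements the computational side of
such an evaluation and of the measurement applications built on it, for
researchers who want to quantify depth quality and turn depth maps into
calibrated trait measurements:

- **Pinhole geometry.** A pixel `(x, y)` with depth reading `D` (mm)
  back-projects to camera-frame coordinates
  `X = D(cx − x)/fx`, `Y = D(cy − y)/fy`, `Z = D`.
  The metric span of two pixels is the 3D Euclidean distance after
  back-projecting *both* pixels at the mean of their two depth readings
  (`pair_distance()`), the convention used for every measurement here.
- **Fill rate.** The fraction of region-of-interest pixels with valid depth,
  where valid means non-zero and within three standard deviations of the mean
  non-zero ROI depth (`fill_rate()`, `valid_mask()`), stratified by distance
  and by illuminance band (`categorize_lux()`: sunrise < 1,000 lux, overcast,
  full daylight, direct sunlight ≥ 32,000 lux).
- **Object size estimation.** Diameters from two perimeter pixel pairs
  (`select_perimeter_pairs()`, `estimate_diameter()`), with error summaries
  `RMSE = sqrt(mean((dᵢ − Φ)²))` and `MRAE = mean(|dᵢ − Φ|)/Φ` against the
  known size Φ.
- **Background removal.** Keep color pixels whose depth lies within ±25 cm of
  the known object distance, rescuing pixels that have an in-band neighbour
  within a 10-pixel radius (`remove_background()`).
- **Stem-width pipeline.** Crop a detected stem, segment it (pluggable
  segmenter), estimate orientation from the extreme mask pixels, rotate to
  vertical, re-segment, take leftmost→rightmost spans over the middle third
  of the mask, drop spans more than 3 SD from the mean length, and average
  their metric lengths (`run_pipeline()`).
- **Sensor comparison statistics.** Levene's test (mean-centered), Welch's
  heteroscedastic one-way ANOVA, and Games–Howell pairwise post hoc
  comparisons based on the studentized range (`levene_test()`,
  `welch_anova()`, `games_howell()`), plus signed-error distribution
  summaries (`error_distribution()`).
- **Synthetic ground truth.** A ray-casting RGB-D renderer
  (`render_frame()`) for spheres, cylinders and planes, with sensor noise
  profiles (`sensor_profile()`, `apply_sensor()`) covering range cuts,
  depth-dependent Gaussian noise, lux-dependent dropout and gross outliers —
  so every operation can be validated against known geometry.

## Worked example

Render the 50 mm reference ball at 600 mm with a 640×480, fx = fy = 600 px
camera, and recover its diameter from the depth map alone:

```r
library(rgbdpheno)

intr  <- camera_intrinsics(fx = 600, fy = 600, cx = 320, cy = 240,
                           width = 640, height = 480)
frame <- render_frame(sphere(center = c(0, 0, 600), radius = 25), intr)
mask  <- frame$label == 1

fill_rate(frame$depth, mask)
#> [1] 0.9480019
pairs <- select_perimeter_pairs(mask)
estimate_diameter(intr, frame$depth, pairs, mask = mask)
#> diameter estimate: 49.827 mm from 2 pair(s)
```

The fill rate is below 1 because silhouette-fringe pixels of the label mask
carry no center-ray depth; the diameter comes back at 49.83 mm (−0.35 %, well
inside one back-projected pixel pitch of 1 mm at this range). Degrading the
frame with a time-of-flight-style profile and measuring again:

```r
prof  <- sensor_profile("tof", range = c(100, 5000),
                        noise_family = "linear", noise_coef = 0.005,
                        base_dropout = 0.05)
noisy <- apply_sensor(frame, prof, lux_category = "full_daylight", seed = 7)
estimate_diameter(intr, noisy$depth, pairs, mask = mask)
#> diameter estimate: 49.799 mm from 2 pair(s)
```

A full sensors × distances × lighting-cycles comparison, producing fill-rate,
size-error, stem-width and Games–Howell tables as CSV:

```r
cfg <- experiment_config(sensors = list(sensor_preset("d435_640"),
                                        sensor_preset("kinect2"),
                                        sensor_preset("astra_s")),
                         seed = 1)
res <- run_experiment(cfg, outdir = "results")
head(res$stats_pairwise)
```

A YAML-driven command-line front-end lives at
`inst/scripts/run_experiment.R`.

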