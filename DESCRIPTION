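Package: rgbdpheno
Title: Close-Range RGB-D Plant Phenotyping: Depth Quality Metrics and
    Metric Size Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating consumer RGB-D depth sensors in close-range
    outdoor plant phenotyping and for turning their depth maps into metric
    trait measurements. Implements pinhole back-projection of depth pixels to
    camera-frame 3D points, depth fill-rate analysis with a
    3-standard-deviation validity rule, illuminance (lux) banding, depth-based
    background removal with neighbourhood rescue, object diameter estimation
    from perimeter pixel pairs with RMSE and mean-relative-error summaries, a
    maize stem-width measurement pipeline (crop, segment, canonize, width-line
    extraction and filtering, metric width), and the heteroscedastic comparison
    statistics used to contrast sensors (Levene's test, Welch one-way ANOVA,
    Games-Howell post hoc). A ray-casting synthetic RGB-D scene generator with
    configurable sensor noise, dropout and illuminance effects provides
    ground-truth data for validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    jsonlite
Config/testthat/edition: 3
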