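#' Scene primitives for the synthetic RGB-D renderer
#'
#' Constructors for the three geometric primitives the renderer understands.
#' All coordinates are camera-frame millimetres (X right-to-left following the
#' back-projection sign convention, Y top-to-bottom, Z along the optical
#' axis).
#'
#' @param center Sphere center `c(X, Y, Z)` in mm.
#' @param radius Radius in mm (> 0).
#' @param label Object class, one of `"ball"`, `"stem"`, `"background"`.
#' @param color Flat RGB triple in `[0, 1]`.
#' @param id Optional instance identifier (defaults to an auto-assigned one at
#'   render time).
#' @return A `scene_primitive` object.
#' @name scene_primitives
NULL

new_primitive <- function(kind, geom, label, color, id, true_size) {
  stopifnot(label %in% c("ball", "stem", "background"))
  color <- rep_len(as.numeric(color), 3L)
  if (any(color < 0 | color > 1)) stop("color components must be in [0,1]",
                                       call. = FALSE)
  structure(c(list(kind = kind, label = label, color = color, id = id,
                   true_size = true_size), geom),
            class = "scene_primitive")
}

#' @rdname scene_primitives
#' @export
sphere <- function(center, radius, label = "ball",
                   color = c(0, 0.8, 0), id = NULL) {
  stopifnot(length(center) == 3, radius > 0)
  new_primitive("sphere", list(center = as.numeric(center),
                               radius = as.numeric(radius)),
                label, color, id, true_size = 2 * radius)
}

#' @rdname scene_primitives
#' @param base Cylinder axis base point `c(X, Y, Z)` in mm.
#' @param axis Axis direction (will be normalised to unit length).
#' @param length Axial extent in mm (> 0), measured from `base` along `axis`.
#' @export
cylinder <- function(base, axis, radius, length, label = "stem",
                     color = c(0.2, 0.6, 0.1), id = NULL) {
  stopifnot(length(base) == 3, length(axis) == 3, radius > 0, length > 0)
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("cylinder axis must be non-zero", call. = FALSE)
  new_primitive("cylinder",
                list(base = as.numeric(base), axis = axis / nrm,
                     radius = as.numeric(radius), length = as.numeric(length)),
                label, color, id, true_size = 2 * radius)
}

#' @rdname scene_primitives
#' @param point A point on the plane `c(X, Y, Z)` in mm.
#' @param normal Plane normal (need not be unit length).
#' @export
plane <- function(point, normal = c(0, 0, -1), label = "background",
                  color = c(0.4, 0.3, 0.2), id = NULL) {
  stopifnot(length(point) == 3, length(normal) == 3)
  if (all(normal == 0)) stop("plane normal must be non-zero", call. = FALSE)
  new_primitive("plane", list(point = as.numeric(point),
                              normal = as.numeric(normal)),
                label, color, id, true_size = NA_real_)
}

#' @export
print.scene_primitive <- function(x, ...) {
  cat(sprintf("scene primitive: %s (label %s, size %s mm)\n",
              x$kind, x$label,
              if (is.na(x$true_size)) "-" else format(x$true_size)))
  invisible(x)
}

# ray-primitive intersection, vectorised over rays.
# rays: origin 0, direction (a, b, 1) per pixel (unnormalised), so the ray
# parameter t IS the Z-coordinate of the hit. Returns t (Inf for miss).
intersect_t <- function(prim, a, b) {
  if (prim$kind == "plane") {
    n <- prim$normal
    denom <- n[1] * a + n[2] * b + n[3]
    num <- sum(n * prim$point)
    t <- ifelse(abs(denom) < 1e-12, Inf, num / denom)
    t[t <= 0] <- Inf
    return(t)
  }
  if (prim$kind == "sphere") {
    cc <- prim$center; r <- prim$radius
    vv <- a * a + b * b + 1
    vc <- a * cc[1] + b * cc[2] + cc[3]
    disc <- vc * vc - vv * (sum(cc^2) - r * r)
    t <- rep(Inf, length(a))
    hit <- disc >= 0
    if (any(hit)) {
      s <- sqrt(disc[hit])
      t1 <- (vc[hit] - s) / vv[hit]
      t2 <- (vc[hit] + s) / vv[hit]
      tt <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, Inf))
      t[hit] <- tt
    }
    return(t)
  }
  # finite open cylinder (side surface only)
  p0 <- prim$base; u <- prim$axis; r <- prim$radius; L <- prim$length
  # perpendicular components of ray direction and of -p0
  du <- a * u[1] + b * u[2] + u[3]          # v . u
  Ax <- a - du * u[1]; Ay <- b - du * u[2]; Az <- 1 - du * u[3]
  p0u <- sum(p0 * u)
  Bx <- -p0[1] + p0u * u[1]; By <- -p0[2] + p0u * u[2]; Bz <- -p0[3] + p0u * u[3]
  A2 <- Ax * Ax + Ay * Ay + Az * Az
  AB <- Ax * Bx + Ay * By + Az * Bz
  B2 <- Bx * Bx + By * By + Bz * Bz
  disc <- AB * AB - A2 * (B2 - r * r)
  t <- rep(Inf, length(a))
  hit <- disc >= 0 & A2 > 1e-15
  if (any(hit)) {
    s <- sqrt(disc[hit])
    t1 <- (-AB[hit] - s) / A2[hit]
    t2 <- (-AB[hit] + s) / A2[hit]
    du_h <- du[hit]
    ok_axial <- function(tt) {
      sax <- tt * du_h - p0u   # axial coordinate of hit point
      tt > 1e-9 & sax >= 0 & sax <= L
    }
    tt <- ifelse(ok_axial(t1), t1, ifelse(ok_axial(t2), t2, Inf))
    t[hit] <- tt
  }
  t
}

#' Render a synthetic RGB-D frame by ray casting
#'
#' Casts one depth ray per pixel center through a list of scene primitives and
#' records, per pixel, the Z-coordinate of the nearest hit (0 where no
#' primitive is hit), a flat-shaded color, and an instance label. The label
#' mask is rasterized *conservatively*: a pixel is labeled with an object if
#' any of five subrays (the pixel center plus its four footprint corners)
#' hits it, so the mask covers the object's full image footprint the way a
#' human annotation would. Depth itself is strictly the center-ray sample, so
#' fringe pixels of an object may carry background depth (or 0) — the same
#' situation real sensors produce at silhouettes, and the reason the
#' measurement operations carry an inward depth fallback.
#'
#' @param scene List of [scene_primitives] (a single primitive is accepted).
#' @param intr A [camera_intrinsics()] object.
#' @return An `rgbd_frame`: list with `depth` (h x w matrix, mm, 0 = missing),
#'   `color` (h x w x 3 array in `[0,1]`), `label` (h x w integer matrix,
#'   0 = background), `objects` (data frame: `id`, `class`, `distance_mm`,
#'   `true_size_mm`), and `intrinsics`.
#' @export
render_frame <- function(scene, intr) {
  stopifnot_intrinsics(intr)
  if (inherits(scene, "scene_primitive")) scene <- list(scene)
  if (length(scene) == 0) stop("scene must contain at least one primitive",
                               call. = FALSE)
  if (!all(vapply(scene, inherits, logical(1), "scene_primitive")))
    stop("scene must be a list of scene_primitive objects", call. = FALSE)
  w <- intr$width; h <- intr$height
  xs <- rep(0:(w - 1L), each = h)   # column-major over [h, w]
  ys <- rep(0:(h - 1L), times = w)
  offsets <- rbind(c(0, 0), c(-0.5, -0.5), c(-0.5, 0.5),
                   c(0.5, -0.5), c(0.5, 0.5))
  n <- length(xs)
  k <- length(scene)
  depth <- rep(0, n)
  lab <- integer(n)
  lab_t <- rep(Inf, n)
  for (o in seq_len(nrow(offsets))) {
    a <- (intr$cx - (xs + offsets[o, 1])) / intr$fx
    b <- (intr$cy - (ys + offsets[o, 2])) / intr$fy
    tbest <- rep(Inf, n)
    lbest <- integer(n)
    for (i in seq_len(k)) {
      t_i <- intersect_t(scene[[i]], a, b)
      upd <- t_i < tbest
      tbest[upd] <- t_i[upd]
      lbest[upd] <- i
    }
    if (o == 1L) {
      hit <- is.finite(tbest)
      if (any(tbest[hit] < 1e-6))
        stop("render error: camera inside a primitive", call. = FALSE)
      depth[hit] <- tbest[hit]
      # center ray has priority for the label
      lab[hit] <- lbest[hit]
      lab_t[hit] <- tbest[hit]
    } else {
      # corner subrays only claim pixels with a strictly nearer hit
      upd <- is.finite(tbest) & tbest < lab_t
      lab[upd] <- lbest[upd]
      lab_t[upd] <- tbest[upd]
    }
  }
  depth_m <- matrix(depth, nrow = h, ncol = w)
  label_m <- matrix(lab, nrow = h, ncol = w)
  col <- array(0, dim = c(h, w, 3))
  for (i in seq_len(k)) {
    m <- label_m == i
    if (any(m)) for (ch in 1:3) {
      plane_ch <- col[, , ch]
      plane_ch[m] <- scene[[i]]$color[ch]
      col[, , ch] <- plane_ch
    }
  }
  objects <- data.frame(
    id = seq_len(k),
    class = vapply(scene, `[[`, character(1), "label"),
    distance_mm = vapply(scene, function(p) switch(p$kind,
      sphere = p$center[3],
      cylinder = p$base[3] + p$length / 2 * p$axis[3],
      plane = {
        nv <- p$normal
        d <- sum(nv * p$point) / nv[3]
        if (is.finite(d)) d else NA_real_
      }), numeric(1)),
    true_size_mm = vapply(scene, `[[`, numeric(1), "true_size"),
    stringsAsFactors = FALSE
  )
  structure(list(depth = depth_m, color = col, label = label_m,
                 objects = objects, intrinsics = intr),
            class = "rgbd_frame")
}

#' @export
print.rgbd_frame <- function(x, ...) {
  cat(sprintf("rgbd_frame: %d x %d px, %d object(s), %.1f%% pixels with depth\n",
              ncol(x$depth), nrow(x$depth), nrow(x$objects),
              100 * mean(x$depth > 0)))
  invisible(x)
}

#' Depth-sensor noise and dropout profile
#'
#' Describes how a depth sensor degrades an ideal depth map: a working range
#' outside which no depth is returned, additive zero-mean Gaussian noise whose
#' standard deviation follows one of three families in depth
#' (`constant`: \eqn{\sigma = c}; `linear`: \eqn{\sigma = c Z}, the
#' time-of-flight behaviour; `quadratic`: \eqn{\sigma = c Z^2}, the
#' triangulation behaviour), independent per-pixel dropout whose probability
#' increases with the ambient-light (lux) band, and sporadic gross outliers.
#'
#' @param name Profile name (free text, e.g. `"d435_640"`).
#' @param range Working depth range `c(min, max)` in mm.
#' @param noise_family One of `"constant"`, `"linear"`, `"quadratic"`.
#' @param noise_coef Noise coefficient `c` (mm, unitless, or 1/mm according to
#'   the family); must be >= 0.
#' @param base_dropout Dropout probability in the darkest lux band.
#' @param lux_dropout_slope Added dropout probability per lux-band step above
#'   the darkest band.
#' @param outlier_rate Fraction of surviving pixels replaced by gross values.
#' @param outlier_mag Half-width (mm) of the uniform gross-error distribution.
#' @param resolution Depth raster `c(width, height)` this profile natively
#'   uses (informational; rendering resolution comes from the intrinsics).
#' @return A `sensor_profile` object.
#' @export
sensor_profile <- function(name, range = c(200, 10000),
                           noise_family = c("constant", "linear", "quadratic"),
                           noise_coef = 0, base_dropout = 0,
                           lux_dropout_slope = 0, outlier_rate = 0,
                           outlier_mag = 1000, resolution = c(640L, 480L)) {
  noise_family <- match.arg(noise_family)
  stopifnot(length(range) == 2, range[1] < range[2], noise_coef >= 0,
            outlier_mag >= 0)
  probs <- c(base_dropout, lux_dropout_slope, outlier_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, range = as.numeric(range),
                 noise_family = noise_family,
                 noise_coef = as.numeric(noise_coef),
                 base_dropout = base_dropout,
                 lux_dropout_slope = lux_dropout_slope,
                 outlier_rate = outlier_rate, outlier_mag = outlier_mag,
                 resolution = as.integer(resolution)),
            class = "sensor_profile")
}

#' @export
print.sensor_profile <- function(x, ...) {
  cat(sprintf(
    "sensor_profile '%s': range %g-%g mm, %s noise (c=%g), dropout %g +%g/lux band\n",
    x$name, x$range[1], x$range[2], x$noise_family, x$noise_coef,
    x$base_dropout, x$lux_dropout_slope))
  invisible(x)
}

#' Built-in sensor presets
#'
#' Presets mirroring the working ranges and native depth resolutions of four
#' consumer RGB-D sensors commonly used in close-range phenotyping, plus an
#' `"ideal"` noise-free profile. The noise/dropout coefficients are free
#' parameters of the emulation (the functional families — linear in depth for
#' time-of-flight, quadratic for triangulation — are fixed; published sources
#' do not pin their magnitudes), chosen at plausible magnitudes.
#'
#' @param name One of `"ideal"`, `"kinect2"`, `"astra_s"`, `"sr300"`,
#'   `"d435_640"`, `"d435_848"`, `"d435_1280"`.
#' @return A [sensor_profile()] object.
#' @export
sensor_preset <- function(name = c("ideal", "kinect2", "astra_s", "sr300",
                                   "d435_640", "d435_848", "d435_1280")) {
  name <- match.arg(name)
  switch(name,
    ideal = sensor_profile("ideal", range = c(1, 1e5)),
    kinect2 = sensor_profile("kinect2", range = c(500, 4500),
      noise_family = "linear", noise_coef = 0.004,
      base_dropout = 0.02, lux_dropout_slope = 0.04,
      outlier_rate = 0.002, resolution = c(512L, 424L)),
    astra_s = sensor_profile("astra_s", range = c(400, 2000),
      noise_family = "quadratic", noise_coef = 3e-6,
      base_dropout = 0.30, lux_dropout_slope = 0.20,
      outlier_rate = 0.005, resolution = c(640L, 480L)),
    sr300 = sensor_profile("sr300", range = c(300, 2000),
      noise_family = "quadratic", noise_coef = 2e-6,
      base_dropout = 0.20, lux_dropout_slope = 0.15,
      outlier_rate = 0.003, resolution = c(640L, 480L)),
    d435_640 = sensor_profile("d435_640", range = c(200, 10000),
      noise_family = "quadratic", noise_coef = 1.5e-6,
      base_dropout = 0.03, lux_dropout_slope = 0.02,
      outlier_rate = 0.002, resolution = c(640L, 480L)),
    d435_848 = sensor_profile("d435_848", range = c(200, 10000),
      noise_family = "quadratic", noise_coef = 1.2e-6,
      base_dropout = 0.03, lux_dropout_slope = 0.02,
      outlier_rate = 0.002, resolution = c(848L, 480L)),
    d435_1280 = sensor_profile("d435_1280", range = c(200, 10000),
      noise_family = "quadratic", noise_coef = 1.3e-6,
      base_dropout = 0.04, lux_dropout_slope = 0.02,
      outlier_rate = 0.002, resolution = c(1280L, 720L)))
}

noise_sigma <- function(profile, z) {
  switch(profile$noise_family,
         constant = rep(profile$noise_coef, length(z)),
         linear = profile$noise_coef * z,
         quadratic = profile$noise_coef * z * z)
}

#' Degrade an ideal frame with a sensor profile
#'
#' Applies, in order: the working-range cut (depths outside `range` become 0),
#' additive Gaussian noise with the profile's depth-dependent sigma, a re-check
#' of the range (noised values outside the working range, including negatives,
#' become 0), independent per-pixel dropout with probability
#' `base_dropout + lux_dropout_slope * (lux band index)`, and finally gross
#' outliers replacing a fraction `outlier_rate` of the surviving pixels with
#' values drawn uniformly within `outlier_mag` of the true reading (clamped to
#' the working range). The result is deterministic given `seed`.
#'
#' @param frame An `rgbd_frame` from [render_frame()].
#' @param profile A [sensor_profile()].
#' @param lux_category A lux band as produced by [categorize_lux()] (factor or
#'   band name or index 1-4); the darkest band adds no extra dropout.
#' @param seed Integer seed (mandatory; the RNG state of the caller is left
#'   untouched).
#' @return A new `rgbd_frame` with the degraded depth raster.
#' @export
apply_sensor <- function(frame, profile, lux_category = "sunrise", seed) {
  if (!inherits(frame, "rgbd_frame")) stop("'frame' must be an rgbd_frame",
                                           call. = FALSE)
  if (!inherits(profile, "sensor_profile"))
    stop("config error: 'profile' must be a sensor_profile", call. = FALSE)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  seed <- as.integer(seed)  # force now: the argument may itself draw from the RNG
  band <- lux_band_index(lux_category)
  d <- frame$depth
  d[d < profile$range[1] | d > profile$range[2]] <- 0
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nz <- which(d > 0)
  if (profile$noise_coef > 0 && length(nz)) {
    d[nz] <- d[nz] + stats::rnorm(length(nz), 0, noise_sigma(profile, d[nz]))
    d[d < profile$range[1] | d > profile$range[2]] <- 0
    d[d < 0] <- 0
  }
  p_drop <- min(1, profile$base_dropout + profile$lux_dropout_slope * (band - 1L))
  nz <- which(d > 0)
  if (p_drop > 0 && length(nz)) {
    drop <- stats::runif(length(nz)) < p_drop
    d[nz[drop]] <- 0
  }
  nz <- which(d > 0)
  if (profile$outlier_rate > 0 && length(nz)) {
    sel <- nz[stats::runif(length(nz)) < profile$outlier_rate]
    if (length(sel)) {
      gross <- d[sel] + stats::runif(length(sel), -profile$outlier_mag,
                                     profile$outlier_mag)
      d[sel] <- pmin(pmax(gross, profile$range[1]), profile$range[2])
    }
  }
  out <- frame
  out$depth <- d
  out
}

#' Build the reference-object scenes of the outdoor evaluation
#'
#' Constructs, for each requested camera-to-target distance, a scene holding
#' the two reference balls (50 mm and 7.8 mm diameter by default), a row of
#' vertical (optionally inclined) stems modelled as narrow cylinders, an
#' optional second row of background stems, and a backdrop plane. The layout
#' keeps all objects inside the field of view of the default camera down to
#' 200 mm range.
#'
#' @param distances Target distances in mm (default: the seven positions of
#'   the outdoor protocol, 200-1500 mm).
#' @param ball_diameters Diameters (mm) of the two reference balls.
#' @param n_stems Number of foreground stems.
#' @param stem_radius Stem radius in mm (default 4, i.e. 8 mm width --
#'   comparable to a young maize stem and to the smaller reference ball).
#' @param stem_incline_deg Incline of each stem from vertical, in degrees
#'   (recycled across stems).
#' @param background_offset Distance (mm) from the target row to the backdrop
#'   plane; a back row of stems is placed halfway.
#' @param back_row Logical; include a background row of stems.
#' @return A list with one element per distance: `list(scene, distance_mm,
#'   objects)` where `objects` tabulates the ground truth.
#' @export
make_experiment_scene <- function(distances = c(200, 400, 600, 800, 1000, 1200, 1500),
                                  ball_diameters = c(50, 7.8),
                                  n_stems = 3, stem_radius = 4,
                                  stem_incline_deg = 0,
                                  background_offset = 1000,
                                  back_row = TRUE) {
  if (length(distances) == 0 ||
      (length(ball_diameters) == 0 && n_stems == 0))
    stop("config error: empty object list", call. = FALSE)
  if (any(distances <= 0))
    stop("config error: distances must be positive", call. = FALSE)
  incl <- rep_len(stem_incline_deg, max(n_stems, 1L))
  lapply(distances, function(d) {
    scene <- list()
    # lateral extent visible at the shortest protocol distance (~107 mm at
    # 200 mm with fx = 600): keep |X| <= 85 mm
    half <- 85
    if (length(ball_diameters) >= 1)
      scene <- c(scene, list(sphere(c(0.55 * half, 40, d),
                                    ball_diameters[1] / 2,
                                    color = c(0, 0.8, 0))))
    if (length(ball_diameters) >= 2)
      scene <- c(scene, list(sphere(c(-0.55 * half, -40, d),
                                    ball_diameters[2] / 2,
                                    color = c(0.9, 0.9, 0))))
    if (n_stems > 0) {
      xs <- if (n_stems == 1) 0 else seq(-half, half, length.out = n_stems)
      for (i in seq_len(n_stems)) {
        th <- incl[i] * pi / 180
        # axis leans in the X direction; base below the view, spans it fully
        scene <- c(scene, list(cylinder(
          base = c(xs[i] - 250 * sin(th), -250 * cos(th), d),
          axis = c(sin(th), cos(th), 0),
          radius = stem_radius, length = 500,
          color = c(0.25, 0.55, 0.15))))
      }
      if (back_row) {
        for (i in seq_len(n_stems)) {
          scene <- c(scene, list(cylinder(
            base = c(xs[i] + half / 2, -250, d + background_offset / 2),
            axis = c(0, 1, 0), radius = stem_radius, length = 500,
            label = "background", color = c(0.3, 0.5, 0.2))))
        }
      }
    }
    scene <- c(scene, list(plane(c(0, 0, d + background_offset),
                                 c(0, 0, -1))))
    objs <- data.frame(id = seq_along(scene),
                       class = vapply(scene, `[[`, character(1), "label"),
                       true_size_mm = vapply(scene, `[[`, numeric(1),
                                             "true_size"))
    list(scene = scene, distance_mm = d, objects = objs)
  })
}
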