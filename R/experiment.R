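#' Configuration for a synthetic sensor-comparison experiment
#'
#' Bundles everything [run_experiment()] needs: the camera, the sensor noise
#' profiles to compare, the distance grid (the outdoor protocol places targets
#' at seven positions from 0.2 to 1.5 m), one illuminance reading per
#' acquisition cycle (twelve cycles from sunrise to sunset in the protocol;
#' configurable), the reference-object set and a mandatory base seed. Per-frame
#' random substreams are derived from the base seed by a frame counter, so
#' adding cycles or sensors never perturbs the frames already defined.
#'
#' @param intrinsics A [camera_intrinsics()] (default: 640 x 480, fx = fy =
#'   600 px — a close-range RGB-D geometry).
#' @param sensors List of [sensor_profile()] objects (default: an ideal and a
#'   d435-like profile).
#' @param distances Distance grid in mm, positive ascending.
#' @param cycle_lux Illuminance reading (lux) per acquisition cycle; each
#'   cycle is one replicate of the full distance grid.
#' @param ball_diameters,n_stems,stem_radius Passed to
#'   [make_experiment_scene()].
#' @param seed Mandatory integer base seed.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(intrinsics = camera_intrinsics(600, 600, 320, 240, 640, 480),
                              sensors = list(sensor_preset("ideal"),
                                             sensor_preset("d435_640")),
                              distances = c(200, 400, 600, 800, 1000, 1200, 1500),
                              cycle_lux = c(500, 2000, 8000, 15000, 25000, 40000,
                                            45000, 30000, 20000, 9000, 3000, 800),
                              ball_diameters = c(50, 7.8),
                              n_stems = 3, stem_radius = 4, seed) {
  if (missing(seed)) stop("config error: field 'seed' is mandatory",
                          call. = FALSE)
  stopifnot_intrinsics(intrinsics)
  if (inherits(sensors, "sensor_profile")) sensors <- list(sensors)
  if (!length(sensors) ||
      !all(vapply(sensors, inherits, logical(1), "sensor_profile")))
    stop("config error: field 'sensors' must list sensor_profile objects",
         call. = FALSE)
  if (any(distances <= 0) || is.unsorted(distances, strictly = TRUE))
    stop("config error: field 'distances' must be positive ascending",
         call. = FALSE)
  if (any(cycle_lux < 0))
    stop("config error: field 'cycle_lux' must be non-negative", call. = FALSE)
  structure(list(intrinsics = intrinsics, sensors = sensors,
                 distances = as.numeric(distances),
                 cycle_lux = as.numeric(cycle_lux),
                 ball_diameters = ball_diameters, n_stems = n_stems,
                 stem_radius = stem_radius, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Reads the key-value markup form of [experiment_config()]: top-level keys
#' `intrinsics` (fx, fy, cx, cy, width, height), `sensors` (list of
#' [sensor_profile()] argument sets or preset names), `distances`,
#' `cycle_lux`, `ball_diameters`, `n_stems`, `stem_radius`, `seed`.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$intrinsics)) args$intrinsics <- do.call(camera_intrinsics,
                                                         y$intrinsics)
  if (!is.null(y$sensors))
    args$sensors <- lapply(y$sensors, function(s) {
      if (is.character(s)) sensor_preset(s) else do.call(sensor_profile, s)
    })
  for (k in c("distances", "cycle_lux", "ball_diameters", "n_stems",
              "stem_radius", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(experiment_config, args)
}

frame_seed <- function(base, counter) {
  as.integer((as.numeric(base) + 7919 * counter) %% .Machine$integer.max)
}

#' Run the synthetic sensor-comparison experiment
#'
#' Reproduces the analysis shape of an outdoor sensor evaluation end-to-end
#' on synthetic data: for every sensor x distance x cycle the reference scene
#' is rendered, degraded by the sensor profile under the cycle's lux band,
#' and analysed — per-object fill rates, ball-diameter estimates with RMSE
#' and MRAE, stem widths through the measurement pipeline, and Games-Howell /
#' Welch / Levene comparisons of the sensors' fill rates per object class.
#' Fully deterministic given the config seed. When `outdir` is given, the
#' result tables are written as CSV files (`fillrate.csv`, `sizes.csv`,
#' `size_metrics.csv`, `stemwidth.csv`, `stats_tests.csv`,
#' `stats_pairwise.csv`) without timestamps, so identical configs produce
#' byte-identical outputs.
#'
#' @param config An [experiment_config()].
#' @param outdir Optional output directory for the CSV bundle.
#' @param verbose Log per-stage progress to stderr.
#' @return Invisibly, a list of the result tables (`fillrate`, `sizes`,
#'   `size_metrics`, `stemwidth`, `stats_tests`, `stats_pairwise`).
#' @export
run_experiment <- function(config, outdir = NULL, verbose = FALSE) {
  if (!inherits(config, "experiment_config"))
    stop("config error: 'config' must be an experiment_config", call. = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  intr <- config$intrinsics
  scenes <- make_experiment_scene(config$distances,
                                  ball_diameters = config$ball_diameters,
                                  n_stems = config$n_stems,
                                  stem_radius = config$stem_radius)
  t0 <- proc.time()[3]
  rendered <- lapply(scenes, function(sc) render_frame(sc$scene, intr))
  say("rendered %d scenes in %.1fs", length(scenes), proc.time()[3] - t0)

  fill <- list(); sizes <- list(); stems <- list()
  counter <- 0L
  for (si in seq_along(config$sensors)) {
    prof <- config$sensors[[si]]
    for (ci in seq_along(config$cycle_lux)) {
      band <- categorize_lux(config$cycle_lux[ci])
      for (di in seq_along(config$distances)) {
        counter <- counter + 1L
        d <- config$distances[di]
        ideal <- rendered[[di]]
        fr <- apply_sensor(ideal, prof, band, seed = frame_seed(config$seed,
                                                                counter))
        key <- data.frame(sensor = prof$name, distance_mm = d,
                          lux_category = as.character(band), cycle = ci,
                          stringsAsFactors = FALSE)
        # fill rate per object ROI (ground-truth label mask as ROI)
        for (oi in seq_len(nrow(ideal$objects))) {
          cls <- ideal$objects$class[oi]
          if (cls == "background") next
          roi <- ideal$label == ideal$objects$id[oi]
          if (!any(roi)) next
          fill[[length(fill) + 1L]] <-
            cbind(key, object = ifelse(cls == "ball",
                                       ifelse(ideal$objects$true_size_mm[oi] >= 20,
                                              "ball_large", "ball_small"), cls),
                  object_id = ideal$objects$id[oi],
                  fill_rate = fill_rate(fr$depth, roi))
        }
        # ball diameters from perimeter pairs
        for (oi in which(ideal$objects$class == "ball")) {
          roi <- ideal$label == ideal$objects$id[oi]
          if (sum(roi) < 4) next
          est <- tryCatch(suppressWarnings({
            pairs <- select_perimeter_pairs(roi)
            estimate_diameter(intr, fr$depth, pairs, mask = roi)
          }), error = function(e) NULL)
          if (is.null(est)) next
          sizes[[length(sizes) + 1L]] <-
            cbind(key,
                  object = ifelse(ideal$objects$true_size_mm[oi] >= 20,
                                  "ball_large", "ball_small"),
                  true_mm = ideal$objects$true_size_mm[oi],
                  est_mm = est$value, n_pairs = est$n_pairs)
        }
        # stem widths through the pipeline
        dets <- detect_from_labels(ideal, "stem")
        if (nrow(dets)) {
          meas <- run_pipeline(list(depth = fr$depth, color = fr$color,
                                    label = ideal$label,
                                    objects = ideal$objects,
                                    intrinsics = intr),
                               dets,
                               segmenter = label_segmenter(dets$id),
                               intr = intr)
          ok <- meas[meas$status == "ok", , drop = FALSE]
          if (nrow(ok))
            stems[[length(stems) + 1L]] <-
              cbind(key[rep(1, nrow(ok)), ], stem_id = ok$id,
                    angle_deg = ok$angle_deg, n_lines_kept = ok$n_lines_kept,
                    width_mm = ok$width_mm,
                    true_mm = 2 * config$stem_radius)
        }
      }
      say("sensor %s cycle %d done (%.1fs)", prof$name, ci,
          proc.time()[3] - t0)
    }
  }
  fillrate <- do.call(rbind, fill)
  sizes <- if (length(sizes)) do.call(rbind, sizes) else NULL
  stemwidth <- if (length(stems)) do.call(rbind, stems) else NULL
  rownames(fillrate) <- NULL

  size_metrics <- NULL
  if (!is.null(sizes)) {
    grp <- split(sizes, sizes[c("sensor", "object", "distance_mm")],
                 drop = TRUE)
    size_metrics <- do.call(rbind, lapply(grp, function(g)
      data.frame(sensor = g$sensor[1], object = g$object[1],
                 distance_mm = g$distance_mm[1], n = nrow(g),
                 rmse_mm = rmse(g$est_mm, g$true_mm[1]),
                 mrae = mrae(g$est_mm, g$true_mm[1]))))
    rownames(size_metrics) <- NULL
    size_metrics <- size_metrics[order(size_metrics$sensor,
                                       size_metrics$object,
                                       size_metrics$distance_mm), ]
  }

  # sensor comparison statistics on per-frame fill rates, per object class
  stats_tests <- NULL; stats_pairwise <- NULL
  if (length(unique(fillrate$sensor)) >= 2) {
    tl <- list(); pl <- list()
    for (obj in unique(fillrate$object)) {
      sub <- fillrate[fillrate$object == obj, ]
      gl <- split(sub$fill_rate, sub$sensor)
      gl <- gl[lengths(gl) >= 2]
      if (length(gl) < 2) next
      vars <- vapply(gl, stats::var, numeric(1))
      lev <- tryCatch(levene_test(gl), error = function(e) NULL)
      wel <- if (all(vars > 0)) welch_anova(gl) else NULL
      tl[[length(tl) + 1L]] <- data.frame(
        object = obj,
        levene_F = if (is.null(lev)) NA_real_ else unname(lev$statistic),
        levene_p = if (is.null(lev)) NA_real_ else lev$p.value,
        welch_F = if (is.null(wel)) NA_real_ else unname(wel$statistic),
        welch_df2 = if (is.null(wel)) NA_real_ else unname(wel$parameter["df2"]),
        welch_p = if (is.null(wel)) NA_real_ else wel$p.value)
      if (all(vars > 0)) {
        gh <- games_howell(gl)
        pl[[length(pl) + 1L]] <- cbind(object = obj, as.data.frame(gh))
      }
    }
    if (length(tl)) stats_tests <- do.call(rbind, tl)
    if (length(pl)) stats_pairwise <- do.call(rbind, pl)
  }

  out <- list(fillrate = fillrate, sizes = sizes, size_metrics = size_metrics,
              stemwidth = stemwidth, stats_tests = stats_tests,
              stats_pairwise = stats_pairwise)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) if (!is.null(out[[nm]]))
      utils::write.csv(out[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    say("tables written to %s", outdir)
  }
  invisible(out)
}
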