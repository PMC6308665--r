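#' Crop a detection from an RGB-D frame
#'
#' Extracts matching color, depth and label crops for a detection bounding
#' box. Boxes are 0-based, pixel-inclusive `c(x0, y0, x1, y1)` with
#' `x0 < x1`, `y0 < y1`. The offset of the crop origin is recorded so crop
#' coordinates can be mapped back to the full image (`x_full = x_crop + x0`).
#'
#' @param frame An `rgbd_frame` from [render_frame()] (or any list with
#'   `depth`, `color`, `label` rasters).
#' @param box Bounding box `c(x0, y0, x1, y1)`, 0-based inclusive.
#' @return An `rgbd_crop`: list with `color`, `depth`, `label`, `offset`
#'   (`c(x0, y0)`) and `intrinsics`.
#' @export
crop_detection <- function(frame, box) {
  box <- as.integer(round(box))
  if (length(box) != 4 || box[1] >= box[3] || box[2] >= box[4])
    stop("box must be c(x0, y0, x1, y1) with x0 < x1 and y0 < y1",
         call. = FALSE)
  h <- nrow(frame$depth); w <- ncol(frame$depth)
  if (box[1] < 0 || box[2] < 0 || box[3] >= w || box[4] >= h)
    stop("box outside image bounds", call. = FALSE)
  rows <- (box[2] + 1L):(box[4] + 1L)
  cols <- (box[1] + 1L):(box[3] + 1L)
  structure(list(
    color = frame$color[rows, cols, , drop = FALSE],
    depth = frame$depth[rows, cols, drop = FALSE],
    label = if (!is.null(frame$label)) frame$label[rows, cols, drop = FALSE],
    offset = c(x = box[1], y = box[2]),
    intrinsics = frame$intrinsics), class = "rgbd_crop")
}

#' Stem orientation from mask extremes
#'
#' The incline of the line joining the topmost and the bottommost mask pixels,
#' measured from the vertical image axis in degrees, in `(-90, 90)`. Positive
#' angles lean toward increasing column index going down the image. Among
#' ties on the extreme rows the leftmost pixel is taken.
#'
#' @param mask Logical or 0/1 matrix spanning at least 2 rows.
#' @return Angle in degrees.
#' @export
estimate_orientation <- function(mask) {
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0 || length(unique(idx[, 1])) < 2)
    stop("orientation error: mask must span at least 2 rows", call. = FALSE)
  rtop <- min(idx[, 1]); rbot <- max(idx[, 1])
  ctop <- min(idx[idx[, 1] == rtop, 2])
  cbot <- min(idx[idx[, 1] == rbot, 2])
  atan2(cbot - ctop, rbot - rtop) * 180 / pi
}

# inverse-mapping rotation about the raster center; returns matrix of source
# coordinates (continuous, 1-based) for each destination pixel
rotation_grid <- function(h, w, angle_deg) {
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  xo <- rep(seq_len(w), each = h) - cx
  yo <- rep(seq_len(h), times = w) - cy
  # destination -> source: rotate by -theta (forward map sends the stem axis
  # direction (sin, cos) in (x, y) to vertical)
  xs <- cos(th) * xo + sin(th) * yo + cx
  ys <- -sin(th) * xo + cos(th) * yo + cy
  list(xs = xs, ys = ys)
}

rotate_nearest <- function(m, grid) {
  h <- nrow(m); w <- ncol(m)
  xi <- round(grid$xs); yi <- round(grid$ys)
  ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
  out <- matrix(0, h, w)
  out[ok] <- m[cbind(yi[ok], xi[ok])]
  out
}

rotate_bilinear <- function(m, grid) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(grid$xs); y0 <- floor(grid$ys)
  fx <- grid$xs - x0; fy <- grid$ys - y0
  out <- matrix(0, h, w)
  ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  if (any(ok)) {
    g <- function(r, c) m[cbind(r, c)]
    v <- (1 - fx[ok]) * (1 - fy[ok]) * g(y0[ok], x0[ok]) +
      fx[ok] * (1 - fy[ok]) * g(y0[ok], x0[ok] + 1L) +
      (1 - fx[ok]) * fy[ok] * g(y0[ok] + 1L, x0[ok]) +
      fx[ok] * fy[ok] * g(y0[ok] + 1L, x0[ok] + 1L)
    out[ok] <- v
  }
  out
}

#' Rotate a crop so the stem stands vertical
#'
#' Rotates the crop by the orientation angle about its center: color channels
#' with bilinear interpolation, depth and label rasters with nearest-neighbour
#' lookup — depths are range measurements and must never be blended across an
#' object/background boundary. Pixels mapping outside the canvas become 0
#' (black / missing).
#'
#' @param crop An `rgbd_crop` from [crop_detection()].
#' @param angle Orientation in degrees from vertical, as from
#'   [estimate_orientation()]; must lie in `(-90, 90)`.
#' @return The rotated `rgbd_crop`.
#' @export
rotate_to_vertical <- function(crop, angle) {
  if (!is.finite(angle) || angle <= -90 || angle >= 90)
    stop("angle must lie in (-90, 90) degrees", call. = FALSE)
  if (angle == 0) return(crop)
  h <- nrow(crop$depth); w <- ncol(crop$depth)
  grid <- rotation_grid(h, w, angle)
  out <- crop
  for (ch in seq_len(dim(crop$color)[3]))
    out$color[, , ch] <- rotate_bilinear(crop$color[, , ch], grid)
  out$depth <- rotate_nearest(crop$depth, grid)
  if (!is.null(crop$label)) out$label <- rotate_nearest(crop$label, grid)
  out
}

#' Extract horizontal width lines from the mid-section of a stem mask
#'
#' For every row in the middle third of the mask's occupied row range, emits
#' the leftmost and the rightmost set pixels and the pixel length of the span
#' (`right - left + 1`). Interior holes are ignored — the span always runs
#' leftmost to rightmost. Rows without set pixels are skipped.
#'
#' @param mask Logical or 0/1 matrix spanning at least 3 rows.
#' @return Data frame with columns `row`, `left`, `right` (0-based pixel
#'   coordinates) and `npix`.
#' @export
extract_width_lines <- function(mask) {
  mask <- mask != 0
  occ <- which(rowSums(mask) > 0)
  if (length(occ) == 0 || (max(occ) - min(occ) + 1) < 3)
    stop("measurement error: mask must span at least 3 rows", call. = FALSE)
  rmin <- min(occ); rmax <- max(occ)
  n <- rmax - rmin + 1L
  third <- floor(n / 3)
  mid_rows <- (rmin + third):(rmin + n - third - 1L)
  mid_rows <- intersect(mid_rows, occ)
  if (length(mid_rows) == 0)
    stop("measurement error: no occupied rows in the mid-section",
         call. = FALSE)
  lines <- lapply(mid_rows, function(r) {
    cs <- which(mask[r, ])
    data.frame(row = r - 1L, left = min(cs) - 1L, right = max(cs) - 1L)
  })
  out <- do.call(rbind, lines)
  out$npix <- out$right - out$left + 1L
  out
}

#' Filter width lines by the 3-SD length rule
#'
#' Discards lines whose pixel length deviates from the mean pixel length by
#' more than three sample standard deviations. A single pass; with zero
#' spread (or a single line) all lines are kept. Filtering uses pixel
#' lengths because it precedes the metric conversion in the measurement
#' pipeline.
#'
#' @param lines Data frame from [extract_width_lines()].
#' @return The kept subset of `lines`.
#' @export
filter_lines <- function(lines) {
  if (!is.data.frame(lines) || nrow(lines) == 0)
    stop("'lines' must be a non-empty data frame", call. = FALSE)
  if (nrow(lines) == 1) return(lines)
  m <- mean(lines$npix); s <- stats::sd(lines$npix)
  if (is.na(s) || s == 0) return(lines)
  lines[abs(lines$npix - m) <= 3 * s, , drop = FALSE]
}

#' Metric stem width from kept width lines
#'
#' Averages, over the kept lines, the metric span of each line's endpoints
#' computed exactly as in the ball-diameter estimation: both endpoints are
#' back-projected at the mean of their depth readings and the 3D Euclidean
#' distance taken. Endpoint depths are screened and, when missing or
#' out-of-band, sourced up to `max_inward` pixels inward along the line (see
#' [estimate_diameter()]). Lines with no usable endpoint depths are skipped;
#' if none survives, an error is thrown. Because the averaged-depth
#' convention makes the span depend only on coordinate differences, the
#' result is unaffected by the crop offset; `offset` is accepted for
#' bookkeeping symmetry with [crop_detection()].
#'
#' @param intr A [camera_intrinsics()] object.
#' @param depthimg Depth raster of the (rotated) crop.
#' @param lines Kept lines from [filter_lines()].
#' @param mask Optional stem mask for depth-validity screening.
#' @param offset Crop offset `c(x0, y0)` (unused by the arithmetic; see
#'   Details).
#' @param max_inward Maximum inward search (pixels) for a usable depth.
#' @return Width in mm, with attribute `n_lines` (lines actually used).
#' @export
measure_stem_width <- function(intr, depthimg, lines, mask = NULL,
                               offset = c(0, 0), max_inward = 3) {
  stopifnot_intrinsics(intr)
  if (!is.data.frame(lines) || nrow(lines) == 0)
    stop("measurement error: no width lines", call. = FALSE)
  widths <- vapply(seq_len(nrow(lines)), function(i) {
    p1 <- c(lines$left[i], lines$row[i])
    p2 <- c(lines$right[i], lines$row[i])
    d1 <- resolve_depth(depthimg, p1, p2, mask, max_inward)
    d2 <- resolve_depth(depthimg, p2, p1, mask, max_inward)
    if (is.na(d1) || is.na(d2)) return(NA_real_)
    pair_distance(intr, p1, p2, depthimg, d1 = d1, d2 = d2)
  }, numeric(1))
  if (all(is.na(widths)))
    stop("measurement error: no line with usable endpoint depths",
         call. = FALSE)
  structure(mean(widths, na.rm = TRUE), n_lines = sum(!is.na(widths)))
}

#' Segmenter backed by the synthetic label raster
#'
#' Returns a segmenter honouring the pipeline's pluggable contract (crop in,
#' binary mask of identical size out) by thresholding the crop's ground-truth
#' label raster. Stands in for a learned instance-segmentation model when the
#' pipeline runs on synthetic frames.
#'
#' @param ids Instance id(s) to mark as stem; `NULL` marks any non-background
#'   label.
#' @return A function `(rgbd_crop) -> logical matrix`.
#' @export
label_segmenter <- function(ids = NULL) {
  force(ids)
  function(crop) {
    if (is.null(crop$label))
      stop("label_segmenter requires a crop with a label raster",
           call. = FALSE)
    if (is.null(ids)) crop$label > 0 else
      matrix(crop$label %in% ids, nrow(crop$label), ncol(crop$label))
  }
}

#' Derive detections from a frame's label raster
#'
#' Bounding boxes (0-based inclusive `x0, y0, x1, y1`) of every object of a
#' given class, padded by `pad` pixels and clipped to the image. A synthetic
#' stand-in for a detection network.
#'
#' @param frame An `rgbd_frame`.
#' @param class Object class to box (default `"stem"`).
#' @param pad Padding in pixels around the tight box.
#' @return Data frame with `id`, `x0`, `y0`, `x1`, `y1`.
#' @export
detect_from_labels <- function(frame, class = "stem", pad = 5L) {
  ids <- frame$objects$id[frame$objects$class == class]
  h <- nrow(frame$label); w <- ncol(frame$label)
  boxes <- lapply(ids, function(i) {
    idx <- which(frame$label == i, arr.ind = TRUE)
    if (nrow(idx) == 0) return(NULL)
    data.frame(id = i,
               x0 = max(0L, min(idx[, 2]) - 1L - pad),
               y0 = max(0L, min(idx[, 1]) - 1L - pad),
               x1 = min(w - 1L, max(idx[, 2]) - 1L + pad),
               y1 = min(h - 1L, max(idx[, 1]) - 1L + pad))
  })
  out <- do.call(rbind, boxes)
  if (is.null(out)) out <- data.frame(id = integer(), x0 = integer(),
                                      y0 = integer(), x1 = integer(),
                                      y1 = integer())
  out
}

#' Run the full stem-width measurement pipeline
#'
#' Per detection: crop the color and depth rasters, segment the stem,
#' estimate its orientation from the mask extremes, rotate the crop to bring
#' the stem vertical (canonization), segment again on the rotated crop,
#' extract the mid-section width lines, filter them by the 3-SD length rule,
#' and convert the kept lines to a metric width. A failure in any stage is
#' recorded for that stem and the remaining detections are still processed.
#'
#' @param frame An `rgbd_frame`.
#' @param detections Data frame with columns `x0`, `y0`, `x1`, `y1`
#'   (0-based inclusive) and optionally `id`, e.g. from
#'   [detect_from_labels()]; may be empty.
#' @param segmenter A function `(rgbd_crop) -> logical matrix` of the crop's
#'   size, e.g. [label_segmenter()].
#' @param intr Camera intrinsics (defaults to the frame's).
#' @return A data frame of class `stem_measurements` with one row per
#'   detection: `id`, `angle_deg`, `n_lines_total`, `n_lines_kept`,
#'   `width_mm`, `status` (`"ok"` or the failure message).
#' @export
run_pipeline <- function(frame, detections, segmenter = label_segmenter(),
                         intr = frame$intrinsics) {
  stopifnot_intrinsics(intr)
  if (is.null(detections) || nrow(detections) == 0) {
    out <- data.frame(id = integer(), angle_deg = numeric(),
                      n_lines_total = integer(), n_lines_kept = integer(),
                      width_mm = numeric(), status = character())
    class(out) <- c("stem_measurements", class(out))
    return(out)
  }
  res <- lapply(seq_len(nrow(detections)), function(i) {
    det <- detections[i, ]
    id <- if ("id" %in% names(det)) det$id else i
    row <- data.frame(id = id, angle_deg = NA_real_,
                      n_lines_total = NA_integer_, n_lines_kept = NA_integer_,
                      width_mm = NA_real_, status = "ok",
                      stringsAsFactors = FALSE)
    tryCatch({
      crop <- crop_detection(frame, c(det$x0, det$y0, det$x1, det$y1))
      mask1 <- segmenter(crop)
      if (!identical(dim(mask1), dim(crop$depth)))
        stop("segmenter returned a mask of the wrong size", call. = FALSE)
      angle <- estimate_orientation(mask1)
      row$angle_deg <- angle
      rot <- rotate_to_vertical(crop, angle)
      mask2 <- segmenter(rot)
      lines <- extract_width_lines(mask2)
      row$n_lines_total <- nrow(lines)
      kept <- filter_lines(lines)
      row$n_lines_kept <- nrow(kept)
      wmm <- measure_stem_width(intr, rot$depth, kept, mask = mask2,
                                offset = crop$offset)
      row$width_mm <- as.numeric(wmm)
      row$n_lines_kept <- attr(wmm, "n_lines")
      row
    }, error = function(e) {
      row$status <- conditionMessage(e)
      row
    })
  })
  out <- do.call(rbind, res)
  class(out) <- c("stem_measurements", class(out))
  out
}

#' @export
print.stem_measurements <- function(x, ...) {
  cat(sprintf("stem measurements: %d detection(s), %d measured\n",
              nrow(x), sum(x$status == "ok")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
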