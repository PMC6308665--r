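#' Pinhole camera intrinsics
#'
#' Bundles the focal lengths, principal point and raster dimensions of a
#' registered RGB-D camera. Focal lengths are expressed in pixel units, so a
#' feature of metric extent \eqn{s} at depth \eqn{Z} spans approximately
#' \eqn{s \cdot f_x / Z} pixels.
#'
#' Pixel coordinates are 0-based throughout the package: `x` is the column
#' index in `[0, width)` and `y` the row index in `[0, height)`.
#'
#' @param fx,fy Focal lengths in pixel units; must be positive.
#' @param cx,cy Principal point (column, row) in pixels; must lie inside the
#'   raster.
#' @param width,height Raster dimensions in pixels.
#' @return An object of class `camera_intrinsics`.
#' @examples
#' intr <- camera_intrinsics(fx = 600, fy = 600, cx = 320, cy = 240,
#'                           width = 640, height = 480)
#' backproject_pixel(intr, 120, 240, 1000)
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  stopifnot(is.numeric(fx), is.numeric(fy), length(fx) == 1L, length(fy) == 1L)
  if (fx <= 0 || fy <= 0)
    stop("focal lengths must be positive", call. = FALSE)
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L)
    stop("image dimensions must be positive", call. = FALSE)
  if (cx < 0 || cx >= width || cy < 0 || cy >= height)
    stop("principal point must lie inside the image", call. = FALSE)
  structure(list(fx = as.numeric(fx), fy = as.numeric(fy),
                 cx = as.numeric(cx), cy = as.numeric(cy),
                 width = width, height = height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("Pinhole intrinsics: %d x %d px, fx=%.2f fy=%.2f, c=(%.2f, %.2f)\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

stopifnot_intrinsics <- function(intr) {
  if (!inherits(intr, "camera_intrinsics"))
    stop("'intr' must be a camera_intrinsics object", call. = FALSE)
}

#' Back-project depth pixels to camera-frame 3D points
#'
#' Maps pixels with known depth to metric 3D coordinates under the pinhole
#' model:
#' \deqn{X = D \cdot (c_x - x)/f_x, \quad Y = D \cdot (c_y - y)/f_y, \quad Z = D,}
#' where \eqn{D} is the depth reading in millimetres. The `(c - x)` sign
#' convention mirrors the more common `(x - c)`; it only flips the axes'
#' direction and leaves all pairwise distances unchanged. Depth is taken as
#' the Z-coordinate of the surface point (not the ray length).
#'
#' @param intr A [camera_intrinsics()] object.
#' @param x,y Pixel coordinates (0-based column / row); vectors are accepted.
#' @param depth Depth in millimetres, recycled against `x`/`y`; all values
#'   must be strictly positive (0 encodes a missing measurement and is
#'   rejected).
#' @return A numeric matrix with one row per pixel and columns `X`, `Y`, `Z`
#'   (millimetres, camera frame).
#' @seealso [project_point()] for the inverse map, [pair_distance()] for
#'   metric spans between pixel pairs.
#' @export
backproject_pixel <- function(intr, x, y, depth) {
  stopifnot_intrinsics(intr)
  n <- max(length(x), length(y), length(depth))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  depth <- rep_len(as.numeric(depth), n)
  if (any(!is.finite(depth)) || any(depth <= 0))
    stop("invalid measurement: depth must be positive and finite",
         call. = FALSE)
  cbind(X = depth * (intr$cx - x) / intr$fx,
        Y = depth * (intr$cy - y) / intr$fy,
        Z = depth)
}

#' Project camera-frame 3D points onto the pixel grid
#'
#' Exact inverse of [backproject_pixel()]: `x = cx - X*fx/Z`,
#' `y = cy - Y*fy/Z`, depth `= Z`. Points must lie in front of the camera.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param X,Y,Z Camera-frame coordinates in millimetres; vectors accepted.
#' @return A data frame with columns `x`, `y` (continuous pixel coordinates,
#'   0-based) and `depth` (mm).
#' @export
project_point <- function(intr, X, Y, Z) {
  stopifnot_intrinsics(intr)
  n <- max(length(X), length(Y), length(Z))
  X <- rep_len(as.numeric(X), n)
  Y <- rep_len(as.numeric(Y), n)
  Z <- rep_len(as.numeric(Z), n)
  if (any(!is.finite(Z)) || any(Z <= 0))
    stop("projection error: point must lie in front of the camera (Z > 0)",
         call. = FALSE)
  data.frame(x = intr$cx - X * intr$fx / Z,
             y = intr$cy - Y * intr$fy / Z,
             depth = Z)
}

# depth lookup at a 0-based pixel; returns NA outside the raster
depth_at <- function(depthimg, x, y) {
  h <- nrow(depthimg); w <- ncol(depthimg)
  ok <- x >= 0 & x < w & y >= 0 & y < h
  out <- rep(NA_real_, length(x))
  out[ok] <- depthimg[cbind(y[ok] + 1L, x[ok] + 1L)]
  out
}

#' Metric distance between two depth pixels
#'
#' Measures the 3D Euclidean distance between two pixels of a depth image.
#' Both pixels are back-projected using the *same* depth value — the mean of
#' their two depth readings — before the distance is taken. This averaged-depth
#' convention is used for every metric span in the package (ball diameters and
#' stem widths alike); with a shared depth the result reduces to
#' \deqn{d = \bar{D}\sqrt{(\Delta x/f_x)^2 + (\Delta y/f_y)^2}}
#' and is therefore invariant to translating both pixels by the same offset.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param p1,p2 Pixels as length-2 numeric vectors `c(x, y)` (0-based).
#' @param depthimg Depth raster (numeric matrix, millimetres, 0 = missing),
#'   `height` rows by `width` columns.
#' @param d1,d2 Optional explicit depth readings (mm) overriding the raster
#'   lookup, e.g. after an inward-fallback search.
#' @return Distance in millimetres (single numeric value).
#' @examples
#' intr <- camera_intrinsics(500, 500, 320, 240, 640, 480)
#' img <- matrix(1000, 480, 640)
#' pair_distance(intr, c(300, 240), c(340, 240), img)  # 80 mm
#' @export
pair_distance <- function(intr, p1, p2, depthimg, d1 = NULL, d2 = NULL) {
  stopifnot_intrinsics(intr)
  if (is.null(d1)) d1 <- depth_at(depthimg, p1[1], p1[2])
  if (is.null(d2)) d2 <- depth_at(depthimg, p2[1], p2[2])
  if (is.na(d1) || is.na(d2) || d1 <= 0 || d2 <= 0)
    stop("invalid measurement: both pixels must carry valid (non-zero) depth",
         call. = FALSE)
  dbar <- (d1 + d2) / 2
  a <- backproject_pixel(intr, p1[1], p1[2], dbar)
  b <- backproject_pixel(intr, p2[1], p2[2], dbar)
  sqrt(sum((a - b)^2))
}
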