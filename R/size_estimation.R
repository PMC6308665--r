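#' Select two perimeter pixel pairs from an object mask
#'
#' Deterministic stand-in for manually picking pixel pairs on opposite sides
#' of an object's perimeter: pair 1 is the leftmost and rightmost set pixels
#' on the row through the mask centroid, pair 2 the topmost and bottommost set
#' pixels on the column through the centroid. The centroid is the mean of the
#' set pixel coordinates rounded to the nearest row/column.
#'
#' @param mask Logical or 0/1 matrix delimiting the object.
#' @return A list of two pairs; each pair is a list with `p1` and `p2`,
#'   0-based `c(x, y)` pixels.
#' @export
select_perimeter_pairs <- function(mask) {
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("selection error: empty mask", call. = FALSE)
  rows <- idx[, 1]; cols <- idx[, 2]
  if (length(unique(rows)) < 2 || length(unique(cols)) < 2)
    stop("selection error: mask must span at least 2 rows and 2 columns",
         call. = FALSE)
  crow <- round(mean(rows)); ccol <- round(mean(cols))
  on_row <- cols[rows == crow]
  on_col <- rows[cols == ccol]
  if (length(on_row) < 2 || length(on_col) < 2)
    stop("selection error: centroid row/column degenerate", call. = FALSE)
  # convert 1-based matrix indices to 0-based pixels (x = col-1, y = row-1)
  list(
    list(p1 = c(min(on_row) - 1L, crow - 1L),
         p2 = c(max(on_row) - 1L, crow - 1L)),
    list(p1 = c(ccol - 1L, min(on_col) - 1L),
         p2 = c(ccol - 1L, max(on_col) - 1L))
  )
}

# Depth lookup with validity screening and inward fallback. A reading is
# usable when non-zero and, if a mask is given, within the +/-250 mm object
# window (the depth-based background-removal band) around the mask's median
# non-zero depth: silhouette pixels of a labeled object frequently carry the
# depth of whatever lies behind it, and the median is robust to that fringe.
# If the pixel itself is unusable, steps of 1 px toward `toward` (along the
# dominant axis of the pair) are tried up to `max_inward` px.
resolve_depth <- function(depthimg, p, toward, mask = NULL, max_inward = 3,
                          band = 250) {
  ref <- NULL
  if (!is.null(mask)) {
    vals <- depthimg[mask != 0]
    nzv <- vals[vals > 0]
    if (length(nzv) >= 1) ref <- stats::median(nzv)
  }
  usable <- function(d) {
    if (is.na(d) || d <= 0) return(FALSE)
    if (is.null(ref)) return(TRUE)
    abs(d - ref) <= band
  }
  step <- sign(toward - p)
  # move along the dominant displacement axis only (same row or column)
  if (abs(toward[1] - p[1]) >= abs(toward[2] - p[2])) step[2] <- 0 else step[1] <- 0
  for (k in 0:max_inward) {
    q <- p + k * step
    d <- depth_at(depthimg, q[1], q[2])
    if (usable(d)) return(d)
    if (all(step == 0)) break
  }
  NA_real_
}

#' Estimate an object diameter from perimeter pixel pairs
#'
#' Computes the metric span of each pixel pair with [pair_distance()] (both
#' endpoints back-projected at the mean of their depth readings) and returns
#' the average over the pairs — two pairs in the standard protocol. Endpoint
#' depths are screened for validity (non-zero; inside the +/-250 mm object
#' window around the mask's median non-zero depth when `mask` is supplied)
#' and, when unusable,
#' replaced by the nearest usable reading up to `max_inward` pixels inward
#' along the pair's axis: silhouette pixels are where depth dropout and
#' background bleed-through concentrate, and the substituted reading only
#' feeds the averaged-depth convention while the pixel coordinates keep the
#' measured span. If one pair has no usable endpoint depths the estimate
#' falls back to the remaining pair with a warning; if none survives, an
#' error is thrown.
#'
#' @param intr A [camera_intrinsics()] object.
#' @param depthimg Depth raster (matrix, mm, 0 = missing).
#' @param pairs Pixel pairs as returned by [select_perimeter_pairs()].
#' @param mask Optional object mask used for depth-validity screening.
#' @param max_inward Maximum inward search (pixels) for a usable depth.
#' @return A `diameter_estimate`: list with `value` (mm), `n_pairs` used,
#'   and `pair_values` (mm per pair, `NA` where a pair failed).
#' @export
estimate_diameter <- function(intr, depthimg, pairs, mask = NULL,
                              max_inward = 3) {
  stopifnot_intrinsics(intr)
  if (length(pairs) == 0) stop("at least one pixel pair required",
                               call. = FALSE)
  vals <- vapply(pairs, function(pr) {
    d1 <- resolve_depth(depthimg, pr$p1, pr$p2, mask, max_inward)
    d2 <- resolve_depth(depthimg, pr$p2, pr$p1, mask, max_inward)
    if (is.na(d1) || is.na(d2)) return(NA_real_)
    pair_distance(intr, pr$p1, pr$p2, depthimg, d1 = d1, d2 = d2)
  }, numeric(1))
  if (all(is.na(vals)))
    stop("invalid measurement: no pixel pair with usable depth", call. = FALSE)
  if (anyNA(vals))
    warning("pair(s) without usable depth dropped; falling back to ",
            sum(!is.na(vals)), " pair(s)", call. = FALSE)
  structure(list(value = mean(vals, na.rm = TRUE),
                 n_pairs = sum(!is.na(vals)),
                 pair_values = vals),
            class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat(sprintf("diameter estimate: %.3f mm from %d pair(s)\n",
              x$value, x$n_pairs))
  invisible(x)
}

#' Root mean square error of size estimates
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\sum_i (d_i - \Phi)^2 / N}} for estimates
#' \eqn{d_i} of a known true size \eqn{\Phi}.
#'
#' @param estimates Numeric vector of size estimates (mm), length >= 1.
#' @param phi True size (mm).
#' @return RMSE in mm.
#' @export
rmse <- function(estimates, phi) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0 || anyNA(estimates))
    stop("'estimates' must be a non-empty numeric vector without NAs",
         call. = FALSE)
  sqrt(mean((estimates - phi)^2))
}

#' Mean relative average error of size estimates
#'
#' \eqn{\mathrm{MRAE} = \frac{1}{N}\sum_i \sqrt{(d_i - \Phi)^2} / \Phi}, i.e.
#' the mean absolute error normalised by the true size — useful because an
#' absolute error that is negligible on a large object can be disqualifying
#' on a small one. Equals `rmse(x, phi) / phi` when `N = 1`.
#'
#' @inheritParams rmse
#' @return MRAE as a dimensionless fraction.
#' @export
mrae <- function(estimates, phi) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0 || anyNA(estimates))
    stop("'estimates' must be a non-empty numeric vector without NAs",
         call. = FALSE)
  if (!(is.numeric(phi) && length(phi) == 1 && phi > 0))
    stop("'phi' must be a single positive true size", call. = FALSE)
  mean(abs(estimates - phi)) / phi
}
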