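LUX_LEVELS <- c("sunrise", "overcast", "full_daylight", "direct_sunlight")
LUX_BOUNDS <- c(1000, 10000, 32000)

#' Categorize illuminance readings into lighting bands
#'
#' Maps lux readings to the four lighting bands used to stratify outdoor
#' acquisition conditions: sunrise light (below 1000 lux), overcast lighting
#' (1000 to 10,000 lux), full daylight without direct sun (10,000 to 32,000
#' lux), and direct sunlight (32,000 lux and above). Bands are half-open with
#' the upper band claiming the boundary, so e.g. exactly 32,000 lux is
#' `direct_sunlight`. The bands tile `[0, Inf)` with no gaps.
#'
#' @param lux Non-negative illuminance readings (vectorised).
#' @return A factor with levels `sunrise < overcast < full_daylight <
#'   direct_sunlight`.
#' @examples
#' categorize_lux(c(500, 15000, 32000))
#' @export
categorize_lux <- function(lux) {
  lux <- as.numeric(lux)
  if (any(!is.finite(lux)) || any(lux < 0))
    stop("lux readings must be non-negative", call. = FALSE)
  idx <- findInterval(lux, LUX_BOUNDS) + 1L
  factor(LUX_LEVELS[idx], levels = LUX_LEVELS, ordered = TRUE)
}

# 1-based band index from a factor, band name, or integer
lux_band_index <- function(lux_category) {
  if (is.factor(lux_category)) lux_category <- as.character(lux_category)
  if (is.character(lux_category)) {
    i <- match(lux_category, LUX_LEVELS)
    if (any(is.na(i))) stop("config error: unknown lux category", call. = FALSE)
    return(i)
  }
  i <- as.integer(lux_category)
  if (any(is.na(i)) || any(i < 1L) || any(i > 4L))
    stop("config error: lux band index must be in 1..4", call. = FALSE)
  i
}

check_roi <- function(depthimg, roi) {
  roi <- roi != 0
  if (!identical(dim(roi), dim(depthimg)))
    stop("ROI dimensions must match the depth image", call. = FALSE)
  if (!any(roi)) stop("ROI must contain at least one pixel", call. = FALSE)
  roi
}

#' Depth-validity mask under the 3-SD rule
#'
#' A pixel inside the region of interest is valid when it carries a non-zero
#' depth that lies within three standard deviations of the mean of the
#' non-zero depths in the ROI. The mean and the (sample, n-1 denominator)
#' standard deviation are computed once from the unfiltered non-zero values —
#' a single pass, no re-estimation after exclusions. With fewer than two
#' non-zero pixels the rule degenerates to the non-zero test alone.
#'
#' @param depthimg Depth raster (matrix, mm, 0 = missing).
#' @param roi Logical or 0/1 matrix of the same dimensions with at least one
#'   pixel set.
#' @return Logical matrix of the same dimensions; `TRUE` only on valid ROI
#'   pixels (always `FALSE` outside the ROI).
#' @seealso [fill_rate()]
#' @export
valid_mask <- function(depthimg, roi) {
  roi <- check_roi(depthimg, roi)
  vals <- depthimg[roi]
  nz <- vals > 0
  valid <- nz
  if (sum(nz) >= 2) {
    m <- mean(vals[nz]); s <- stats::sd(vals[nz])
    if (s > 0) valid <- nz & abs(vals - m) <= 3 * s
  }
  out <- matrix(FALSE, nrow(depthimg), ncol(depthimg))
  out[roi] <- valid
  out
}

#' Fill rate of a region of interest
#'
#' Fraction of ROI pixels carrying valid depth measurements under the 3-SD
#' validity rule of [valid_mask()]. Ranges in `[0, 1]` and can only decrease
#' when additional ROI pixels lose their depth.
#'
#' @inheritParams valid_mask
#' @return A single numeric value in `[0, 1]`.
#' @export
fill_rate <- function(depthimg, roi) {
  roi <- check_roi(depthimg, roi)
  sum(valid_mask(depthimg, roi)) / sum(roi)
}

#' Depth-based background removal
#'
#' Blackens every color pixel whose depth lies outside a +/-`band` mm window
#' around the known object distance `d`, except that a pixel with missing or
#' out-of-band depth is rescued (keeps its color) when any pixel within a
#' Euclidean radius of `radius` pixels is in-band. The rescue prevents the
#' removal of object pixels with missing or corrupted depth, which concentrate
#' near silhouettes.
#'
#' @param color Color raster: `h x w x 3` array (or an `h x w` matrix, treated
#'   as a single channel).
#' @param depthimg Depth raster (matrix, mm, 0 = missing) of matching size.
#' @param d Object distance in mm (> 0).
#' @param band Half-width of the kept depth window in mm (default 250).
#' @param radius Neighbourhood rescue radius in pixels (Euclidean, default 10).
#' @return The color raster with non-object pixels set to black (0).
#' @export
remove_background <- function(color, depthimg, d, band = 250, radius = 10) {
  if (!(is.numeric(d) && length(d) == 1 && d > 0))
    stop("'d' must be a positive distance in mm", call. = FALSE)
  dm <- dim(color)
  h <- dm[1]; w <- dm[2]
  if (!identical(dim(depthimg), c(h, w)))
    stop("color and depth dimensions must match", call. = FALSE)
  inband <- depthimg >= d - band & depthimg <= d + band
  keep <- inband | dilate_disc(inband, radius)
  if (length(dm) == 2L) return(color * keep)
  out <- color
  for (ch in seq_len(dm[3])) out[, , ch] <- color[, , ch] * keep
  out
}

# binary dilation with a Euclidean disc structuring element (offsets with
# dx^2 + dy^2 <= r^2), implemented by shifted OR accumulation
dilate_disc <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  r <- floor(radius)
  for (dy in -r:r) for (dx in -r:r) {
    if (dx * dx + dy * dy > radius * radius) next
    src_r <- max(1, 1 - dy):min(h, h - dy)
    src_c <- max(1, 1 - dx):min(w, w - dx)
    out[src_r + dy, src_c + dx] <- out[src_r + dy, src_c + dx] |
      mask[src_r, src_c]
  }
  out
}

#' Aggregate fill-rate records
#'
#' Mean fill rate per group over a long-format record table, e.g. by sensor
#' and distance (the shape used for fill-rate-by-distance and
#' fill-rate-by-lighting summaries).
#'
#' @param records Data frame holding a `fill_rate` column plus grouping
#'   columns such as `sensor`, `object`, `distance_mm`, `lux_category`.
#' @param by Character vector of grouping column names present in `records`.
#' @return Data frame with the grouping columns, `mean_fill_rate` and `n`.
#' @export
aggregate_fill <- function(records, by) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("'records' must be a non-empty data frame", call. = FALSE)
  if (!"fill_rate" %in% names(records))
    stop("'records' must contain a 'fill_rate' column", call. = FALSE)
  missing_keys <- setdiff(by, names(records))
  if (length(missing_keys))
    stop("unknown grouping key(s): ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  agg <- stats::aggregate(records$fill_rate, records[by],
                          function(v) c(mean = mean(v), n = length(v)))
  out <- agg[by]
  out$mean_fill_rate <- agg$x[, "mean"]
  out$n <- as.integer(agg$x[, "n"])
  out[do.call(order, out[by]), , drop = FALSE]
}
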