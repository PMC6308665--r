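#' Read and write depth, color and mask rasters
#'
#' Depth maps are stored as 16-bit single-channel TIFF with one integer
#' millimetre per grey level (0 = missing), the lossless convention used by
#' depth-sensor SDK dumps; color as 8-bit PNG; binary masks as 8-bit PNG with
#' 0/255 levels.
#'
#' @param depthimg Numeric matrix of depths in mm (values 0-65535).
#' @param path File path.
#' @return `read_depth()` returns a numeric matrix in mm; the writers return
#'   `path` invisibly.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_depth <- function(depthimg, path) {
  if (any(depthimg < 0 | depthimg > 65535))
    stop("depth values must fit 16-bit mm (0-65535)", call. = FALSE)
  tiff::writeTIFF(round(depthimg) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname raster_io
#' @export
read_depth <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  round(m * 65535)
}

#' @rdname raster_io
#' @param color `h x w x 3` array in `[0, 1]`.
#' @export
write_color <- function(color, path) {
  png::writePNG(color, path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_color <- function(path) {
  png::readPNG(path)
}

#' @rdname raster_io
#' @param mask Logical or 0/1 matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
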