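#' Read a grayscale image raster
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG into a numeric matrix of
#' intensities on the native integer scale (0..255 or 0..65535). All internal
#' computation in the package is done in floating point on these values.
#'
#' @param path Path to a `.tif`, `.tiff` or `.png` file.
#' @return A numeric matrix (rows = image rows) with attributes `bit_depth`
#'   and `source` (the file path). Multi-channel files are reduced to their
#'   first channel with a warning.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    depth <- if (max(px) > 255) 16L else attr(px, "bits.per.sample") %||% 8L
  } else if (ext == "png") {
    px <- png::readPNG(path)
    # png values come back scaled to [0,1]; restore the integer scale
    depth <- 8L
    px <- px * (2^depth - 1)
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(px)) == 3L) {
    warning("multi-channel image reduced to first channel: ", path)
    px <- px[, , 1L]
  }
  assert_raster(px)
  structure(px, bit_depth = depth, source = path)
}

#' Write a grayscale image raster
#'
#' Writes a numeric matrix as an 8- or 16-bit grayscale TIFF or PNG. Values
#' are rounded and clamped to the integer range of the chosen bit depth, so
#' an integer-valued raster round-trips bit-identically.
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param path Output path; format chosen from the extension.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_raster <- function(pixels, path, bit_depth = 16L) {
  stopifnot(bit_depth %in% c(8L, 16L))
  top <- 2^bit_depth - 1
  x <- pmin(pmax(round(pixels), 0), top) / top
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = bit_depth)
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else {
    stop("unsupported image format: ", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Intensity grids must be rectangular, finite and non-negative.
assert_raster <- function(pixels) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("raster must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("raster intensities must be finite and >= 0")
  invisible(pixels)
}

#' Pair of registered nuclear and polarity-marker images
#'
#' Bundles the two channels of one field of view. The nuclear stain drives
#' segmentation; the polarity-marker channel is profiled.
#'
#' @param condition Condition (treatment group) label.
#' @param field_id Identifier of the field within the condition.
#' @param nuclear,polarity Numeric matrices of identical dimensions.
#' @return An object of class `field_pair`.
#' @export
field_pair <- function(condition, field_id, nuclear, polarity) {
  assert_raster(nuclear); assert_raster(polarity)
  if (!identical(dim(nuclear), dim(polarity)))
    stop("nuclear and polarity rasters must have identical dimensions (",
         condition, "/", field_id, ")")
  structure(list(condition = as.character(condition),
                 field_id = as.character(field_id),
                 nuclear = nuclear, polarity = polarity),
            class = "field_pair")
}

#' @export
print.field_pair <- function(x, ...) {
  cat(sprintf("<field_pair> %s/%s  %d x %d px\n", x$condition, x$field_id,
              nrow(x$nuclear), ncol(x$nuclear)))
  invisible(x)
}
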