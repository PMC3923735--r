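# Reading and writing 8-bit RGB rasters (PNG, TIFF), the four-point text
# file, and the mask TIFF.

#' Read an RGB image from PNG or TIFF
#'
#' Returns an H x W x 3 array in `[0,1]`. An alpha channel is dropped with a
#' warning; grayscale inputs are rejected (the method needs the three color
#' channels to reach LAB).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("input file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_io(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext))
  )
  if (is.matrix(img) || (length(dim(img)) == 3L && dim(img)[3] == 1L)) {
    stop_validation("grayscale images are not supported; an RGB input is required")
  }
  if (length(dim(img)) != 3L) stop_io("unsupported image layout")
  if (dim(img)[3] == 4L) {
    warning("alpha channel dropped", call. = FALSE)
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3] != 3L) {
    stop_validation(sprintf("expected 3 color channels, found %d", dim(img)[3]))
  }
  img
}

#' Write an RGB image to PNG or TIFF
#'
#' Values are clamped to `[0,1]` at write-out (the pipeline itself never
#' clamps intermediates). PNG output is 8-bit; TIFF output is 8- or 16-bit.
#'
#' @param img H x W x 3 array.
#' @param path Output path; format chosen by extension.
#' @param bits Bit depth for TIFF output (8 or 16; PNG is always 8).
#' @export
write_image <- function(img, path, bits = 8) {
  .assert_image3(img, "RGB image")
  img <- clamp(img, 0, 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!bits %in% c(8, 16)) stop_validation("TIFF bit depth must be 8 or 16")
      tiff::writeTIFF(img, path, bits.per.sample = as.integer(bits),
                      compression = "none")
    },
    stop_io(sprintf("unsupported output format: .%s (use PNG or TIFF)", ext))
  )
  invisible(path)
}

#' Write / read an illumination mask as a 32-bit TIFF
#'
#' The installed TIFF writer stores 32-bit integer samples over `[0,1]`, so
#' the deficit mask is stored scaled as `mask / reference` (exact to
#' 1/2^32); `read_mask()` undoes the scaling. Deficits outside
#' `[0, reference]` clamp in the saved file only.
#'
#' @param mask H x W deficit matrix.
#' @param path Output `.tif` path.
#' @param reference Reference lightness used for the scaling (default 100).
#' @export
write_mask <- function(mask, path, reference = 100) {
  tiff::writeTIFF(clamp(mask / reference, 0, 1), path,
                  bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, reference = 100) {
  if (!file.exists(path)) stop_io(sprintf("mask file not found: %s", path))
  tiff::readTIFF(path) * reference
}

#' Read four source points from a plain-text file
#'
#' Format: four lines, each `x y` with 0-based integer pixel coordinates
#' (x = column, y = row, origin top-left).
#'
#' @param path Path to the points file.
#' @return Data frame with columns `x`, `y`.
#' @export
read_points_file <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("points file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) != 4L) {
    stop_validation("points file must contain exactly four 'x y' lines")
  }
  vals <- lapply(lines, function(l) suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]])))
  if (any(vapply(vals, function(v) length(v) != 2L || any(!is.finite(v)), TRUE))) {
    stop_validation("each points-file line must hold two numeric values: x y")
  }
  m <- do.call(rbind, vals)
  data.frame(x = m[, 1], y = m[, 2])
}
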