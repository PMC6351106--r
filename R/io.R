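# Image and table I/O. Channel rasters are plain numeric matrices indexed
# (row, col), 1-based, intensities in [0, 1] on the stored bit depth's scale.

#' Read one grayscale channel from a TIFF or PNG file
#'
#' @param path File path; `.tif`/`.tiff` or `.png`.
#' @return Numeric matrix (row, col) with intensities in \[0, 1\].
#' @export
read_channel <- function(path) {
  assert_that(file.exists(path), "image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, " (", path, ")")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # collapse RGB to first plane
  storage.mode(img) <- "double"
  img
}

#' Assemble a multi-channel image from per-channel files
#'
#' @param blue,green,red Paths to the per-channel rasters; `red` may be `NA`
#'   for single-reporter images (a zero raster is substituted).
#' @param name Identifier carried into result tables.
#' @return A `multichannel_image`: list with `blue`, `green`, `red` matrices
#'   of identical shape plus `name`.
#' @export
read_multichannel <- function(blue, green, red = NA, name = basename(blue)) {
  b <- read_channel(blue)
  g <- read_channel(green)
  r <- if (is.na(red)) matrix(0, nrow(b), ncol(b)) else read_channel(red)
  multichannel_image(b, g, r, name = name)
}

#' Construct a multi-channel image from matrices
#'
#' @param blue,green,red Numeric matrices of identical shape, intensities >= 0.
#' @param name Identifier.
#' @return A `multichannel_image` object.
#' @export
multichannel_image <- function(blue, green, red = NULL, name = "image") {
  if (is.null(red)) red <- matrix(0, nrow(blue), ncol(blue))
  assert_that(all(dim(blue) == dim(green)) && all(dim(blue) == dim(red)),
              "channel shapes differ")
  assert_that(min(blue) >= 0 && min(green) >= 0 && min(red) >= 0,
              "negative intensities")
  structure(list(blue = blue, green = green, red = red, name = name),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  cat(sprintf("<multichannel_image> %s: %d x %d px, 3 channels\n",
              x$name, nrow(x$blue), ncol(x$blue)))
  invisible(x)
}

# Write a [0,1] raster as 16-bit grayscale TIFF.
write_channel_tiff <- function(raster, path) {
  tiff::writeTIFF(matrix(pmin(1, pmax(0, raster)), nrow(raster), ncol(raster)),
                  path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
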