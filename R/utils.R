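#' @keywords internal
"_PACKAGE"

#' @import EBImage
#' @importFrom stats cor median quantile rbinom rnorm rpois runif sd t.test pt
#' @importFrom utils read.csv write.csv
NULL

# Pixel coordinates of the discrete disk of given radius around (row, col),
# clipped to an nr x nc image. Returns a two-column matrix (row, col).
disk_pixels <- function(row, col, radius, nr, nc) {
  r0 <- max(1L, floor(row - radius)); r1 <- min(nr, ceiling(row + radius))
  c0 <- max(1L, floor(col - radius)); c1 <- min(nc, ceiling(col + radius))
  if (r0 > r1 || c0 > c1) return(cbind(row = integer(0), col = integer(0)))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - row)^2 + (g$col - col)^2 <= radius^2
  cbind(row = g$row[keep], col = g$col[keep])
}

# Logical raster with TRUE on the disk.
disk_mask <- function(row, col, radius, nr, nc) {
  m <- matrix(FALSE, nr, nc)
  px <- disk_pixels(row, col, radius, nr, nc)
  if (nrow(px)) m[px] <- TRUE
  m
}

# Mean of a raster over the discrete disk (clipped); NA when disk is empty.
disk_mean <- function(raster, row, col, radius) {
  px <- disk_pixels(row, col, radius, nrow(raster), ncol(raster))
  if (!nrow(px)) return(NA_real_)
  mean(raster[px])
}

# Overlap fraction between two circles: intersection area / smaller circle
# area. Used for non-maximum suppression of blob detections.
circle_overlap_fraction <- function(r1, c1, rad1, r2, c2, rad2) {
  d <- sqrt((r1 - r2)^2 + (c1 - c2)^2)
  if (d >= rad1 + rad2) return(0)
  rmin <- min(rad1, rad2); rmax <- max(rad1, rad2)
  if (d <= rmax - rmin) return(1)
  # lens area of two intersecting circles
  a1 <- rad1^2 * acos(pmin(1, pmax(-1, (d^2 + rad1^2 - rad2^2) / (2 * d * rad1))))
  a2 <- rad2^2 * acos(pmin(1, pmax(-1, (d^2 + rad2^2 - rad1^2) / (2 * d * rad2))))
  a3 <- 0.5 * sqrt(max(0, (-d + rad1 + rad2) * (d + rad1 - rad2) *
                          (d - rad1 + rad2) * (d + rad1 + rad2)))
  (a1 + a2 - a3) / (pi * rmin^2)
}

# Stop unless condition holds; message supports sprintf-style arguments.
assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
  invisible(TRUE)
}
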