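# LC3 puncta detection and scoring: median despeckling, scale-normalized
# Laplacian-of-Gaussian blob detection, suppression of blobs inside nuclei
# or bright-cell halos, and the circle-area readout A = pi * (c * sigma)^2.

#' Median filter for speckle-noise removal
#'
#' Pixelwise median over a window x window neighborhood; edge pixels use
#' the truncated neighborhood that lies inside the image.
#'
#' @param raster Numeric matrix.
#' @param window Odd window size >= 1.
#' @return Filtered matrix of the same shape.
#' @export
despeckle <- function(raster, window = 3L) {
  assert_that(window >= 1 && window %% 2 == 1, "window must be odd and >= 1")
  if (window == 1L) return(raster)
  k <- (window - 1L) %/% 2L
  nr <- nrow(raster); nc <- ncol(raster)
  shifts <- expand.grid(dr = -k:k, dc = -k:k)
  stack <- array(NA_real_, dim = c(nr, nc, nrow(shifts)))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    src_r <- max(1, 1 - dr):min(nr, nr - dr)
    src_c <- max(1, 1 - dc):min(nc, nc - dc)
    stack[src_r, src_c, s] <- raster[src_r + dr, src_c + dc]
  }
  out <- apply(stack, c(1, 2), median, na.rm = TRUE)
  matrix(out, nr, nc)
}

# Scale-normalized negated LoG kernel for scale sigma: responds positively
# to bright blobs. Kernel radius 4*sigma; zero-mean so flat regions give 0.
log_kernel <- function(sigma) {
  ext <- max(2L, ceiling(4 * sigma))
  x <- -ext:ext
  d2 <- outer(x^2, x^2, `+`)
  g <- exp(-d2 / (2 * sigma^2))
  k <- -(d2 / sigma^2 - 2) * g          # -sigma^2 * Laplacian of Gaussian
  k <- k / (2 * pi * sigma^2)
  k - mean(k)
}

#' Detect bright blobs by scale-normalized Laplacian of Gaussian
#'
#' Filters the raster with negated scale-normalized LoG kernels at
#' `n_scales` linearly spaced sigmas in `[sigma_min, sigma_max]`, then
#' reports local maxima of the (row, col, scale) response volume whose
#' response exceeds `threshold_rel * max(raster)`. Overlapping detections
#' (disk overlap fraction > `overlap_max`, disks of radius sqrt(2)*sigma)
#' are pruned keeping the stronger response; ties break deterministically
#' by (response, row, col, sigma).
#'
#' @param raster Numeric matrix (despeckled green or red channel).
#' @param sigma_min,sigma_max Scale range in px.
#' @param n_scales Number of scales.
#' @param threshold_rel Detection threshold as a fraction of the raster
#'   maximum (scale-normalized response units), so 8- and 16-bit inputs
#'   behave alike.
#' @param overlap_max Maximum allowed disk overlap fraction.
#' @return data.frame with `row`, `col`, `sigma`, `response`, sorted by
#'   decreasing response.
#' @export
detect_blobs_log <- function(raster, sigma_min = 1, sigma_max = 5,
                             n_scales = 10L, threshold_rel = 0.1,
                             overlap_max = 0.5) {
  assert_that(sigma_min > 0 && sigma_min <= sigma_max,
              "sigma_min must satisfy 0 < sigma_min <= sigma_max")
  assert_that(n_scales >= 1, "n_scales must be >= 1")
  assert_that(threshold_rel > 0, "threshold must be > 0")
  nr <- nrow(raster); nc <- ncol(raster)
  sigmas <- if (n_scales == 1L) sigma_min else
    seq(sigma_min, sigma_max, length.out = n_scales)
  resp <- array(0, dim = c(nr, nc, length(sigmas)))
  for (s in seq_along(sigmas))
    resp[, , s] <- as.matrix(EBImage::filter2(raster, log_kernel(sigmas[s]),
                                              boundary = "replicate"))
  threshold <- threshold_rel * max(raster)
  if (max(resp) <= threshold)
    return(data.frame(row = integer(0), col = integer(0), sigma = numeric(0),
                      response = numeric(0)))
  # local maxima over the 3x3x3 neighborhood (>= neighbors, > threshold)
  neigh_max <- array(-Inf, dim = dim(resp))
  for (dr in -1:1) for (dc in -1:1) for (ds in -1:1) {
    if (dr == 0 && dc == 0 && ds == 0) next
    r_dst <- max(1, 1 - dr):min(nr, nr - dr)
    c_dst <- max(1, 1 - dc):min(nc, nc - dc)
    s_dst <- max(1, 1 - ds):min(length(sigmas), length(sigmas) - ds)
    neigh_max[r_dst, c_dst, s_dst] <-
      pmax(neigh_max[r_dst, c_dst, s_dst],
           resp[r_dst + dr, c_dst + dc, s_dst + ds])
  }
  cand <- which(resp > threshold & resp >= neigh_max, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(row = integer(0), col = integer(0), sigma = numeric(0),
                      response = numeric(0)))
  blobs <- data.frame(row = cand[, 1], col = cand[, 2],
                      sigma = sigmas[cand[, 3]],
                      response = resp[cand])
  # deterministic order, then greedy overlap pruning (stronger kept)
  blobs <- blobs[order(-blobs$response, blobs$row, blobs$col, blobs$sigma), ]
  rownames(blobs) <- NULL
  keep <- rep(TRUE, nrow(blobs))
  rad <- sqrt(2) * blobs$sigma
  for (i in seq_len(nrow(blobs))) {
    if (!keep[i]) next
    if (i == nrow(blobs)) break
    j <- (i + 1):nrow(blobs)
    j <- j[keep[j]]
    # cheap distance prefilter before the exact lens-area computation
    close <- j[(blobs$row[j] - blobs$row[i])^2 + (blobs$col[j] - blobs$col[i])^2 <
                 (rad[i] + rad[j])^2]
    for (jj in close) {
      ov <- circle_overlap_fraction(blobs$row[i], blobs$col[i], rad[i],
                                    blobs$row[jj], blobs$col[jj], rad[jj])
      if (ov > overlap_max) keep[jj] <- FALSE
    }
  }
  blobs <- blobs[keep, , drop = FALSE]
  rownames(blobs) <- NULL
  blobs
}

#' Remove blobs inside nuclei or excluded bright-cell regions
#'
#' A blob is removed when its center pixel (rounded to the grid) lies in a
#' nucleus label or in the bright-cell exclusion halo; all others pass
#' through untouched.
#'
#' @param blobs data.frame from [detect_blobs_log()].
#' @param ln Optional `labeled_nuclei` (its `labels` suppress blobs; its
#'   `exclusion_mask`, when present, suppresses halo blobs).
#' @return Filtered blobs data.frame.
#' @export
suppress_masked_blobs <- function(blobs, ln = NULL) {
  if (is.null(ln) || !nrow(blobs)) return(blobs)
  r <- pmin(nrow(ln$labels), pmax(1L, round(blobs$row)))
  c <- pmin(ncol(ln$labels), pmax(1L, round(blobs$col)))
  ij <- cbind(r, c)
  bad <- ln$labels[ij] > 0
  if (!is.null(ln$exclusion_mask)) bad <- bad | ln$exclusion_mask[ij]
  out <- blobs[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score puncta: radius, circle area, per-channel disk intensities
#'
#' Each punctum's radius is `radius_coeff * sigma` and its area the area of
#' that circle, pi * radius^2. Disk mean intensities are computed over the
#' discrete disk clipped to the image.
#'
#' @param blobs Blobs data.frame (`row`, `col`, `sigma`, `response`).
#' @param image A `multichannel_image` supplying green/red rasters.
#' @param radius_coeff Proportionality constant c in radius = c * sigma.
#'   Default sqrt(2): a LoG kernel of scale sigma responds maximally to a
#'   Gaussian blob whose bright core has radius sqrt(2) * sigma.
#' @return data.frame of puncta: blobs columns plus `radius`, `area`,
#'   `mean_green`, `mean_red`, `label` (initially "unclassified").
#' @export
score_puncta <- function(blobs, image, radius_coeff = sqrt(2)) {
  assert_that(radius_coeff > 0, "radius_coeff must be > 0")
  n <- nrow(blobs)
  radius <- radius_coeff * blobs$sigma
  mg <- numeric(n); mr <- numeric(n)
  for (i in seq_len(n)) {
    mg[i] <- disk_mean(image$green, blobs$row[i], blobs$col[i], radius[i])
    mr[i] <- disk_mean(image$red, blobs$row[i], blobs$col[i], radius[i])
  }
  out <- blobs
  out$radius <- radius
  out$area <- pi * radius^2
  out$mean_green <- mg
  out$mean_red <- mr
  out$label <- rep("unclassified", n)
  out
}

#' Summarize puncta of one image or condition
#'
#' @param puncta Scored puncta data.frame (possibly empty).
#' @param cell_count One row of [count_cells()] output (or any list with
#'   `total_effective`).
#' @param id Identifier echoed into the summary.
#' @return One-row data.frame: `id`, `effective_cell_count`, `puncta_count`,
#'   `total_puncta_area`, `puncta_area_per_cell`, `n_autophagosome`,
#'   `n_autolysosome`.
#' @export
summarize_sample <- function(puncta, cell_count, id = "sample") {
  eff <- cell_count$total_effective
  assert_that(length(eff) == 1 && eff > 0, "effective cell count must be > 0")
  total_area <- if (nrow(puncta)) sum(puncta$area) else 0
  data.frame(id = id, effective_cell_count = eff,
             puncta_count = nrow(puncta), total_puncta_area = total_area,
             puncta_area_per_cell = total_area / eff,
             n_autophagosome = sum(puncta$label == "autophagosome"),
             n_autolysosome = sum(puncta$label == "autolysosome"))
}
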