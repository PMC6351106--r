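# Nuclei detection from the DAPI (blue) channel: Gaussian smoothing, Otsu
# threshold, watershed splitting of touching nuclei, area filtering,
# fractional counting of border-clipped nuclei, bright-cell exclusion.

#' Otsu threshold of a raster over a 256-bin histogram
#'
#' Exhaustive search over the bin boundaries of a 256-bin histogram of the
#' raster (binned over its own min-max range), maximizing the between-class
#' variance w1*w2*(mu1 - mu2)^2. Returns the threshold on the raster's
#' intensity scale; pixels strictly above it are foreground.
#'
#' @param x Numeric matrix or vector with at least two distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold value (upper edge of the optimal background bin).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  rng <- range(v)
  assert_that(diff(rng) > 0, "degenerate histogram, Otsu undefined")
  # bin index 1..levels; bin i covers (rng1 + (i-1)*w, rng1 + i*w]
  w <- diff(rng) / levels
  idx <- pmin(levels, pmax(1L, ceiling((v - rng[1]) / w)))
  idx[v == rng[1]] <- 1L
  h <- tabulate(idx, nbins = levels)
  # per-bin intensity sums (not bin midpoints): for integer-valued input the
  # binned search is then exactly the classic exhaustive Otsu on gray levels
  hsum <- as.vector(rowsum(v, idx, reorder = TRUE))
  hs <- numeric(levels)
  hs[sort(unique(idx))] <- hsum
  n <- length(v)
  cw <- cumsum(h)                     # pixels in bins 1..t
  cm <- cumsum(hs)                    # intensity mass in bins 1..t
  w1 <- cw / n
  w2 <- 1 - w1
  mu1 <- cm / cw
  mu2 <- (cm[levels] - cm) / (n - cw)
  sb <- w1 * w2 * (mu1 - mu2)^2
  sb[!is.finite(sb)] <- -Inf
  sb <- sb[-levels]                   # threshold must leave both classes nonempty
  t_bin <- which.max(sb)              # first maximum: deterministic tie-break
  rng[1] + t_bin * w
}

#' Binarize the nuclei channel (Gaussian smoothing + Otsu)
#'
#' @param blue Blue-channel raster (nonnegative matrix with >= 2 distinct
#'   values).
#' @param smoothing_sigma Gaussian smoothing width in px; 0 disables
#'   smoothing.
#' @return Logical matrix: TRUE on the nuclei mask.
#' @export
make_nuclei_mask <- function(blue, smoothing_sigma = 2) {
  assert_that(length(blue) > 0, "empty raster")
  sm <- if (smoothing_sigma > 0)
    as.matrix(EBImage::gblur(blue, sigma = smoothing_sigma)) else blue
  thr <- otsu_threshold(sm)
  sm > thr
}

# Build the per-label record table for a label raster.
label_records <- function(labels, image = NULL) {
  n_lab <- max(labels)
  if (n_lab == 0)
    return(data.frame(label = integer(0), area = integer(0),
                      touches_border = logical(0), border_fraction = numeric(0),
                      mean_blue = numeric(0), mean_green = numeric(0),
                      mean_red = numeric(0), excluded_bright = logical(0)))
  lv <- as.integer(labels)
  area <- tabulate(lv, nbins = n_lab)
  nr <- nrow(labels); nc <- ncol(labels)
  border_px <- c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc])
  touches <- seq_len(n_lab) %in% border_px[border_px > 0]
  ch_mean <- function(ch) {
    if (is.null(ch)) return(rep(NA_real_, n_lab))
    as.vector(rowsum(as.vector(ch)[lv > 0], lv[lv > 0])) / area
  }
  data.frame(label = seq_len(n_lab), area = area, touches_border = touches,
             border_fraction = 1,
             mean_blue = ch_mean(image$blue), mean_green = ch_mean(image$green),
             mean_red = ch_mean(image$red), excluded_bright = FALSE)
}

#' Split touching nuclei by watershed on the distance transform
#'
#' Labels each connected foreground region by watershed over the negated
#' Euclidean distance transform. Shallow local maxima closer in depth than
#' `tolerance` are merged, which prevents over-segmentation of single
#' nuclei; the labeling is deterministic for fixed inputs.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param image Optional `multichannel_image` for per-label mean intensities.
#' @param tolerance Minimum distance-map depth separating two objects, px.
#' @return A `labeled_nuclei` object: list with `labels` (integer matrix,
#'   0 = background) and `records` (per-label data.frame: label, area,
#'   touches_border, border_fraction, mean intensities, excluded_bright).
#' @export
split_touching_nuclei <- function(mask, image = NULL, tolerance = 1) {
  mask <- mask > 0
  if (!any(mask)) {
    labels <- matrix(0L, nrow(mask), ncol(mask))
    return(structure(list(labels = labels, records = label_records(labels)),
                     class = "labeled_nuclei"))
  }
  d <- EBImage::distmap(mask)
  labels <- as.matrix(EBImage::watershed(d, tolerance = tolerance, ext = 1))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, records = label_records(labels, image)),
            class = "labeled_nuclei")
}

#' @export
print.labeled_nuclei <- function(x, ...) {
  cat(sprintf("<labeled_nuclei> %d labels, %d px foreground\n",
              nrow(x$records), sum(x$labels > 0)))
  invisible(x)
}

#' Remove labels smaller than a minimum area
#'
#' Surviving labels are recompacted to 1..K preserving their order.
#'
#' @param ln A `labeled_nuclei` object.
#' @param min_area Minimum area in px^2 (labels with area < min_area drop).
#' @return Filtered `labeled_nuclei`.
#' @export
filter_small_regions <- function(ln, min_area = 200) {
  assert_that(min_area >= 0, "min_area must be >= 0")
  keep <- ln$records$label[ln$records$area >= min_area]
  remap <- integer(max(ln$labels, 1L))
  remap[keep] <- seq_along(keep)
  labels <- ln$labels
  labels[labels > 0] <- remap[labels[labels > 0]]
  rec <- ln$records[ln$records$label %in% keep, , drop = FALSE]
  rec$label <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  structure(list(labels = labels, records = rec), class = "labeled_nuclei")
}

#' Count cells with fractional credit for border-clipped nuclei
#'
#' Interior nuclei count 1 each. Nuclei touching the image border count as
#' `min(1, area / mean_interior_area)`, where the mean interior area is
#' measured over all interior nuclei of the whole dataset (not per image).
#' Bright-excluded labels are not counted.
#'
#' @param ln_list List of `labeled_nuclei`, one per image of the dataset.
#' @return data.frame with one row per image: `n_interior`,
#'   `n_border_effective`, `total_effective`, `mean_interior_area`.
#' @export
count_cells <- function(ln_list) {
  if (inherits(ln_list, "labeled_nuclei")) ln_list <- list(ln_list)
  recs <- lapply(ln_list, `[[`, "records")
  interior_areas <- unlist(lapply(recs, function(r)
    r$area[!r$touches_border & !r$excluded_bright]))
  assert_that(length(interior_areas) > 0,
              "cannot estimate average nuclei size: dataset has no interior nuclei")
  mean_area <- mean(interior_areas)
  out <- lapply(recs, function(r) {
    r <- r[!r$excluded_bright, , drop = FALSE]
    n_int <- sum(!r$touches_border)
    bfrac <- pmin(1, r$area[r$touches_border] / mean_area)
    data.frame(n_interior = n_int, n_border_effective = sum(bfrac),
               total_effective = n_int + sum(bfrac),
               mean_interior_area = mean_area)
  })
  res <- do.call(rbind, out)
  rownames(res) <- names(ln_list)
  res
}

#' Flag abnormally bright cells for exclusion
#'
#' Marks as excluded every nucleus whose mean intensity on the chosen
#' channel exceeds the Tukey upper fence Q3 + fence_k * IQR of the image's
#' per-nucleus mean intensities. With fewer than 4 nuclei no cell is
#' flagged (the fence is meaningless). The exclusion mask is the flagged
#' labels dilated by a disc of `halo_radius` px, so puncta in a surrounding
#' area are also suppressed downstream.
#'
#' @param ln A `labeled_nuclei` with per-label mean intensities populated.
#' @param channel Channel whose per-nucleus mean drives the outlier test;
#'   `"green"` (default: bright diffuse reporter signal is what obscures
#'   puncta) or `"blue"`.
#' @param fence_k Tukey fence multiplier (default 1.5).
#' @param halo_radius Dilation radius of the exclusion halo, px.
#' @param min_ratio Additional guard: a nucleus is only flagged when its
#'   mean intensity also exceeds `min_ratio` times the median nucleus mean.
#'   This keeps the fence from tripping on images whose nuclei are all of
#'   near-equal brightness, where the IQR is dominated by pixel noise.
#' @return `labeled_nuclei` with `excluded_bright` set and an added
#'   `exclusion_mask` (logical matrix) covering flagged nuclei + halo.
#' @export
flag_bright_cells <- function(ln, channel = c("green", "blue"), fence_k = 1.5,
                              halo_radius = 25, min_ratio = 1.5) {
  channel <- match.arg(channel)
  vals <- switch(channel, green = ln$records$mean_green,
                 blue = ln$records$mean_blue)
  ln$exclusion_mask <- matrix(FALSE, nrow(ln$labels), ncol(ln$labels))
  if (nrow(ln$records) < 4 || anyNA(vals)) return(ln)
  q <- quantile(vals, c(0.25, 0.75), names = FALSE)
  fence <- max(q[2] + fence_k * (q[2] - q[1]), min_ratio * median(vals))
  flagged <- which(vals > fence)
  ln$records$excluded_bright <- seq_len(nrow(ln$records)) %in% flagged
  if (length(flagged)) {
    m <- matrix(0, nrow(ln$labels), ncol(ln$labels))
    m[ln$labels %in% flagged] <- 1
    if (halo_radius > 0) {
      brush <- EBImage::makeBrush(2L * as.integer(halo_radius) + 1L, "disc")
      m <- as.matrix(EBImage::dilate(m, brush))
    }
    ln$exclusion_mask <- m > 0
  }
  ln
}

#' Segment nuclei of one image end to end
#'
#' Convenience wrapper: mask, watershed split, area filter, bright-cell
#' flagging, in the order the pipeline applies them.
#'
#' @param image A `multichannel_image`.
#' @param params Parameter list; see [default_params()].
#' @return `labeled_nuclei` with exclusion mask.
#' @export
segment_nuclei <- function(image, params = default_params()) {
  mask <- make_nuclei_mask(image$blue, params$smoothing_sigma)
  ln <- split_touching_nuclei(mask, image, tolerance = params$watershed_tolerance)
  ln <- filter_small_regions(ln, params$min_area)
  flag_bright_cells(ln, channel = params$bright_channel,
                    fence_k = params$bright_fence_k,
                    halo_radius = params$halo_radius,
                    min_ratio = params$bright_min_ratio)
}
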