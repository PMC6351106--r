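# Independent reference implementations used as oracles. Deliberately
# naive: explicit loops, no shared code with the package internals.

# Connected-component labeling of a logical matrix by breadth-first
# flood fill (8-connectivity). Returns an integer matrix.
flood_fill_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start_r in seq_len(nr)) for (start_c in seq_len(nc)) {
    if (!mask[start_r, start_c] || lab[start_r, start_c] > 0) next
    cur <- cur + 1L
    queue <- list(c(start_r, start_c))
    lab[start_r, start_c] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Exhaustive Otsu search over the 256-bin partition of a pixel vector:
# for every candidate split, between-class variance is computed from the
# raw pixel values by explicit grouping. Returns the optimal bin index t
# (class 1 = bins 1..t).
brute_otsu_bin <- function(v, levels = 256L) {
  rng <- range(v)
  w <- diff(rng) / levels
  idx <- pmin(levels, pmax(1L, ceiling((v - rng[1]) / w)))
  idx[v == rng[1]] <- 1L
  best <- -Inf; best_t <- NA_integer_
  for (t in seq_len(levels - 1L)) {
    g1 <- v[idx <= t]; g2 <- v[idx > t]
    if (!length(g1) || !length(g2)) next
    w1 <- length(g1) / length(v)
    sb <- w1 * (1 - w1) * (mean(g1) - mean(g2))^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  best_t
}

# Naive median filter with truncated neighborhoods at the edges.
naive_median_filter <- function(x, window) {
  k <- (window - 1) %/% 2
  nr <- nrow(x); nc <- ncol(x)
  out <- x
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rs <- max(1, r - k):min(nr, r + k)
    cs <- max(1, c - k):min(nc, c + k)
    out[r, c] <- median(as.vector(x[rs, cs]))
  }
  out
}

# Match detected puncta to ground truth by nearest center within max_dist
# px; returns precision, recall and the matched index pairs.
match_puncta <- function(detected, truth, max_dist = 3) {
  if (!nrow(detected) || !nrow(truth))
    return(list(precision = 0, recall = 0, pairs = NULL))
  D <- sqrt(outer(detected$row, truth$row, "-")^2 +
            outer(detected$col, truth$col, "-")^2)
  list(precision = mean(apply(D, 1, min) <= max_dist),
       recall = mean(apply(D, 2, min) <= max_dist),
       det_idx = which(apply(D, 2, min) <= max_dist),
       nearest_det = apply(D, 2, which.min))
}

# Minimal labeled_nuclei stand-in for counting tests that only need the
# per-label record table.
fake_nuclei_records <- function(areas, border, bright = rep(FALSE, length(areas))) {
  structure(list(
    labels = matrix(0L, 1, 1),
    records = data.frame(label = seq_along(areas), area = areas,
                         touches_border = border, border_fraction = 1,
                         mean_blue = 0, mean_green = 0, mean_red = 0,
                         excluded_bright = bright)),
    class = "labeled_nuclei")
}
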