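# Pixelwise Pearson colocalization between two fluorescence channels.

#' Pearson correlation between two channels over an ROI
#'
#' r = sum((a - mean(a)) (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2)) over the ROI pixels.
#'
#' @param a,b Numeric matrices of identical shape.
#' @param roi Logical matrix selecting the region of interest; default all
#'   pixels.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_coefficient <- function(a, b, roi = NULL) {
  assert_that(all(dim(a) == dim(b)), "channel shapes differ")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
  va <- a[roi]; vb <- b[roi]
  assert_that(length(va) >= 2, "ROI must contain at least 2 pixels")
  assert_that(sd(va) > 0 || sd(vb) > 0,
              "correlation undefined: both channels constant on ROI")
  assert_that(sd(va) > 0 && sd(vb) > 0,
              "correlation undefined: a channel is constant on ROI")
  cor(va, vb)
}

#' Colocalization over a dataset of image pairs
#'
#' Computes the Pearson coefficient per pair over the requested ROI and the
#' per-condition mean and SD. Pairs whose ROI is degenerate are skipped with
#' a recorded reason rather than failing the run.
#'
#' @param pairs List of lists, each with matrices `a`, `b`, optional logical
#'   `roi`, optional `condition` (default "all").
#' @return List with `per_roi` (data.frame: condition, pair, r, n_pixels),
#'   `summary` (condition, mean_r, sd_r, n), and `skipped` (pair, reason).
#' @export
colocalize_dataset <- function(pairs) {
  assert_that(length(pairs) >= 1, "at least one image pair required")
  rows <- list(); skipped <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    cond <- if (is.null(p$condition)) "all" else p$condition
    roi <- if (is.null(p$roi)) matrix(TRUE, nrow(p$a), ncol(p$a)) else p$roi
    r <- tryCatch(pearson_coefficient(p$a, p$b, roi), error = function(e) e)
    if (inherits(r, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(pair = i, reason = conditionMessage(r))
    } else {
      rows[[length(rows) + 1]] <-
        data.frame(condition = cond, pair = i, r = r, n_pixels = sum(roi))
    }
  }
  per_roi <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(0), pair = integer(0), r = numeric(0),
               n_pixels = integer(0))
  summary <- if (nrow(per_roi)) {
    agg <- split(per_roi$r, per_roi$condition)
    do.call(rbind, lapply(names(agg), function(cn)
      data.frame(condition = cn, mean_r = mean(agg[[cn]]),
                 sd_r = if (length(agg[[cn]]) > 1) sd(agg[[cn]]) else 0,
                 n = length(agg[[cn]]))))
  } else {
    data.frame(condition = character(0), mean_r = numeric(0),
               sd_r = numeric(0), n = integer(0))
  }
  list(per_roi = per_roi, summary = summary,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(pair = integer(0), reason = character(0)))
}
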