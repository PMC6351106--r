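# Tandem mCherry-GFP-LC3 classification. Detection runs on the red channel
# (mCherry persists in autophagosomes and autolysosomes alike); each red
# punctum is then scored green-positive or not. Green+red puncta are
# autophagosomes; red-only puncta are autolysosomes, GFP having been
# quenched at lysosomal pH.

#' Classify tandem-reporter puncta into autophagosomes and autolysosomes
#'
#' Estimates the green background b as the median green intensity over
#' pixels not covered by any punctum disk (and outside any exclusion mask),
#' then labels a punctum autophagosome iff its disk mean green exceeds
#' `green_positivity_factor * b`, else autolysosome.
#'
#' @param puncta Scored puncta (from [score_puncta()] on red-channel blobs;
#'   must carry `mean_green` and `radius`).
#' @param green Green-channel raster.
#' @param green_positivity_factor Multiple of background a punctum's mean
#'   green must exceed to count as green-positive (default 2).
#' @param background One of `"median_outside_puncta"` (default) or a fixed
#'   numeric background value.
#' @param exclusion_mask Optional logical matrix of pixels to ignore when
#'   estimating the background.
#' @return List: `puncta` with `label` filled in, `n_autophagosome`,
#'   `n_autolysosome`, `background`.
#' @export
classify_tandem_puncta <- function(puncta, green,
                                   green_positivity_factor = 2,
                                   background = "median_outside_puncta",
                                   exclusion_mask = NULL) {
  assert_that(green_positivity_factor > 0,
              "green_positivity_factor must be > 0")
  if (is.numeric(background)) {
    b <- background
  } else {
    covered <- matrix(FALSE, nrow(green), ncol(green))
    for (i in seq_len(nrow(puncta))) {
      px <- disk_pixels(puncta$row[i], puncta$col[i], puncta$radius[i],
                        nrow(green), ncol(green))
      if (nrow(px)) covered[px] <- TRUE
    }
    if (!is.null(exclusion_mask)) covered <- covered | exclusion_mask
    assert_that(any(!covered),
                "background undefined: no pixels outside puncta available")
    b <- median(green[!covered])
  }
  lab <- ifelse(puncta$mean_green > green_positivity_factor * b,
                "autophagosome", "autolysosome")
  puncta$label <- if (nrow(puncta)) lab else character(0)
  list(puncta = puncta,
       n_autophagosome = sum(lab == "autophagosome"),
       n_autolysosome = sum(lab == "autolysosome"),
       background = b)
}
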