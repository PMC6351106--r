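# Small synthetic specs shared across tests; sizes chosen so the whole
# suite stays fast while every stage still has realistic structure.

tiny_spec <- function(...) {
  args <- list(image_shape = c(192L, 192L), n_nuclei = 4L,
               nucleus_radius_mean = 14, nucleus_radius_sd = 1.5,
               n_border_nuclei = 1L, puncta_per_cell_mean = 5,
               seed = 123L)
  mod <- list(...)
  args[names(mod)] <- mod
  do.call(synthetic_spec, args)
}

# A clean bimodal test raster: background plus discs at given centers.
disc_raster <- function(nr, nc, centers, radius, bg = 10, fg = 200) {
  x <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    for (r in seq_len(nr)) {
      span <- radius^2 - (r - centers[i, 1])^2
      if (span >= 0) {
        cs <- ceiling(centers[i, 2] - sqrt(span)):floor(centers[i, 2] + sqrt(span))
        cs <- cs[cs >= 1 & cs <= nc]
        x[r, cs] <- fg
      }
    }
  }
  x
}
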