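# Seeded synthetic fluorescence-microscopy generator with exact ground truth.
#
# The generator emulates the imaging conditions the quantification pipeline
# assumes: DAPI-stained nuclei in the blue channel (including nuclei clipped
# by the image border and abnormally bright cells), diffraction-limited
# Gaussian LC3 puncta in the green/red channels, and pixel noise (gaussian,
# poisson, speckle). All intensities are on a [0, 1] scale (16-bit on disk).

#' Specification of one synthetic image
#'
#' Defines the study conditions a generated image emulates. Identical spec +
#' seed reproduces bit-identical rasters and ground truth.
#'
#' @param image_shape Integer (rows, cols) in pixels.
#' @param n_nuclei Total nuclei, including border-clipped ones.
#' @param nucleus_radius_mean,nucleus_radius_sd Nucleus radius distribution, px.
#' @param n_border_nuclei Number of nuclei deliberately clipped by an edge.
#' @param puncta_per_cell_mean Poisson mean of puncta generated per cell.
#' @param punctum_sigma_range (sigma_min, sigma_max) px; each punctum's true
#'   Gaussian width is drawn uniformly from this range.
#' @param punctum_amplitude Peak intensity of one punctum above background.
#' @param min_punctum_separation Minimum center-to-center distance between
#'   puncta, px.
#' @param autolysosome_fraction Probability a punctum is red-only
#'   (autolysosome); the remainder are green+red (autophagosomes).
#' @param n_bright_cells Number of cells rendered with a saturating diffuse
#'   green plateau (puncta indistinguishable there).
#' @param bright_amplitude Plateau intensity of a bright cell.
#' @param background_level Constant background intensity per channel.
#' @param noise_model One of `"none"`, `"gaussian"`, `"poisson"`, `"speckle"`.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param noise_photons Photon scale for Poisson noise (counts at intensity 1).
#' @param speckle_density Fraction of pixels replaced by max-value salt
#'   impulses under the speckle model.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated `synthetic_spec` object (a list).
#' @export
synthetic_spec <- function(image_shape = c(512L, 512L),
                           n_nuclei = 15L,
                           nucleus_radius_mean = 18,
                           nucleus_radius_sd = 2,
                           n_border_nuclei = 2L,
                           puncta_per_cell_mean = 8,
                           punctum_sigma_range = c(1.5, 3),
                           punctum_amplitude = 0.5,
                           min_punctum_separation = 8,
                           autolysosome_fraction = 0,
                           n_bright_cells = 0L,
                           bright_amplitude = 0.9,
                           background_level = 0.05,
                           noise_model = c("gaussian", "poisson", "speckle", "none"),
                           noise_sd = 0.01,
                           noise_photons = 5000,
                           speckle_density = 0.001,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  spec <- list(image_shape = as.integer(image_shape), n_nuclei = as.integer(n_nuclei),
               nucleus_radius_mean = nucleus_radius_mean,
               nucleus_radius_sd = nucleus_radius_sd,
               n_border_nuclei = as.integer(n_border_nuclei),
               puncta_per_cell_mean = puncta_per_cell_mean,
               punctum_sigma_range = punctum_sigma_range,
               punctum_amplitude = punctum_amplitude,
               min_punctum_separation = min_punctum_separation,
               autolysosome_fraction = autolysosome_fraction,
               n_bright_cells = as.integer(n_bright_cells),
               bright_amplitude = bright_amplitude,
               background_level = background_level,
               noise_model = noise_model, noise_sd = noise_sd,
               noise_photons = noise_photons, speckle_density = speckle_density,
               seed = as.integer(seed))
  assert_that(length(spec$image_shape) == 2L && all(spec$image_shape >= 1L),
              "image_shape must be two positive integers")
  assert_that(spec$n_nuclei >= 0L && spec$n_border_nuclei >= 0L &&
              spec$n_bright_cells >= 0L, "counts must be >= 0")
  assert_that(spec$n_border_nuclei <= spec$n_nuclei,
              "n_border_nuclei cannot exceed n_nuclei")
  assert_that(spec$n_bright_cells <= spec$n_nuclei,
              "n_bright_cells cannot exceed n_nuclei")
  assert_that(spec$punctum_sigma_range[1] > 0 &&
              spec$punctum_sigma_range[1] <= spec$punctum_sigma_range[2],
              "punctum_sigma_range must satisfy 0 < sigma_min <= sigma_max")
  assert_that(spec$autolysosome_fraction >= 0 && spec$autolysosome_fraction <= 1,
              "autolysosome_fraction must lie in [0, 1]")
  assert_that(spec$puncta_per_cell_mean >= 0, "puncta_per_cell_mean must be >= 0")
  class(spec) <- "synthetic_spec"
  spec
}

# Apply the spec's noise model to a clean raster (deterministic given the
# current RNG state). Intensities are clamped to [0, 1].
apply_noise <- function(raster, spec) {
  out <- switch(spec$noise_model,
    none = raster,
    gaussian = raster + matrix(rnorm(length(raster), 0, spec$noise_sd),
                               nrow(raster)),
    poisson = matrix(rpois(length(raster), pmax(0, raster) * spec$noise_photons),
                     nrow(raster)) / spec$noise_photons,
    speckle = {
      n_salt <- round(spec$speckle_density * length(raster))
      r <- raster
      if (n_salt > 0) r[sample.int(length(r), n_salt)] <- 1
      r
    })
  matrix(pmin(1, pmax(0, out)), nrow(raster), ncol(raster))
}

# Render a cosine-tapered disc additively into `raster` (max-composited so
# overlapping nuclei do not exceed the plateau amplitude). edge_width px of
# smooth falloff keeps the intensity histogram cleanly bimodal for Otsu.
render_tapered_disc <- function(raster, row, col, radius, amplitude,
                                edge_width = 2) {
  nr <- nrow(raster); nc <- ncol(raster)
  r0 <- max(1L, floor(row - radius - edge_width))
  r1 <- min(nr, ceiling(row + radius + edge_width))
  c0 <- max(1L, floor(col - radius - edge_width))
  c1 <- min(nc, ceiling(col + radius + edge_width))
  if (r0 > r1 || c0 > c1) return(raster)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - row)^2, (cc - col)^2, `+`))
  prof <- ifelse(d <= radius - edge_width, 1,
          ifelse(d >= radius + edge_width, 0,
                 0.5 * (1 + cos(pi * (d - radius + edge_width) / (2 * edge_width)))))
  raster[rr, cc] <- pmax(raster[rr, cc], amplitude * prof)
  raster
}

# Render an isotropic 2D Gaussian spot additively.
render_gaussian_spot <- function(raster, row, col, sigma, amplitude) {
  nr <- nrow(raster); nc <- ncol(raster)
  ext <- ceiling(4 * sigma)
  r0 <- max(1L, floor(row - ext)); r1 <- min(nr, ceiling(row + ext))
  c0 <- max(1L, floor(col - ext)); c1 <- min(nc, ceiling(col + ext))
  if (r0 > r1 || c0 > c1) return(raster)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - row)^2, (cc - col)^2, `+`)
  raster[rr, cc] <- raster[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  raster
}

#' Generate the DAPI (blue) nuclei channel
#'
#' Places `n_nuclei` cosine-tapered discs: `n_border_nuclei` of them have
#' centers close enough to an image edge that the disc is clipped, the rest
#' lie fully interior. Placement uses rejection sampling with a minimum
#' center separation; exceeding the retry budget is an error naming the
#' constraint. Bright-cell flags are assigned to the first `n_bright_cells`
#' interior nuclei (the flags drive the green plateau in
#' [generate_puncta_channels()]).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `raster` (blue channel) and `nuclei`, a data.frame with
#'   columns `row`, `col`, `radius`, `is_border`, `is_bright`,
#'   `clip_fraction` (visible disc area / full disc area, 1 for interior).
#' @export
generate_nuclei_channel <- function(spec) {
  set.seed(spec$seed)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  raster <- matrix(0, nr, nc)
  nuclei <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0),
                       is_border = logical(0), is_bright = logical(0),
                       clip_fraction = numeric(0))
  if (spec$n_nuclei > 0) {
    min_sep <- 2.2 * spec$nucleus_radius_mean
    budget <- 2000L
    for (k in seq_len(spec$n_nuclei)) {
      border <- k <= spec$n_border_nuclei
      placed <- FALSE
      for (attempt in seq_len(budget)) {
        rad <- max(4, rnorm(1, spec$nucleus_radius_mean, spec$nucleus_radius_sd))
        if (border) {
          # center within [0.2r, 0.8r] of one edge so the disc is clipped
          # but its majority remains visible
          edge <- sample.int(4L, 1L)
          off <- runif(1, -0.6 * rad, 0.6 * rad)
          pos <- switch(edge,
            c(1 + off, runif(1, rad + 4, nc - rad - 4)),
            c(nr - off, runif(1, rad + 4, nc - rad - 4)),
            c(runif(1, rad + 4, nr - rad - 4), 1 + off),
            c(runif(1, rad + 4, nr - rad - 4), nc - off))
        } else {
          margin <- rad + 6
          if (nr - margin <= margin || nc - margin <= margin) next
          pos <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        }
        if (nrow(nuclei) == 0 ||
            all(sqrt((nuclei$row - pos[1])^2 + (nuclei$col - pos[2])^2) >= min_sep)) {
          vis <- sum((outer((1:nr) - pos[1], rep(1, nc)) ^ 2 +
                      outer(rep(1, nr), (1:nc) - pos[2]) ^ 2) <= rad^2)
          nuclei <- rbind(nuclei, data.frame(
            row = pos[1], col = pos[2], radius = rad, is_border = border,
            is_bright = FALSE, clip_fraction = min(1, vis / (pi * rad^2))))
          raster <- render_tapered_disc(raster, pos[1], pos[2], rad, 0.8)
          placed <- TRUE
          break
        }
      }
      assert_that(placed,
        "placement error: could not place nucleus %d within %d retries (image %dx%d, min separation %.1f px)",
        k, budget, nr, nc, min_sep)
    }
    interior <- which(!nuclei$is_border)
    if (spec$n_bright_cells > 0) {
      assert_that(length(interior) >= spec$n_bright_cells,
                  "placement error: fewer interior nuclei than n_bright_cells")
      nuclei$is_bright[interior[seq_len(spec$n_bright_cells)]] <- TRUE
    }
  }
  raster <- apply_noise(raster + spec$background_level, spec)
  list(raster = raster, nuclei = nuclei)
}

#' Generate the tandem-reporter puncta channels (green and red)
#'
#' For each nucleus a Poisson(`puncta_per_cell_mean`) number of puncta is
#' placed in the surrounding cytoplasm, outside every nucleus disc. Each
#' punctum is an isotropic Gaussian of width drawn from
#' `punctum_sigma_range`; its class is Bernoulli(`autolysosome_fraction`):
#' autophagosomes render in both green and red, autolysosomes in red only.
#' Bright-flagged cells additionally receive a diffuse green plateau over
#' the nucleus and a surrounding halo.
#'
#' @param spec A [synthetic_spec()].
#' @param nuclei Ground-truth nuclei table from [generate_nuclei_channel()]
#'   run on the same spec.
#' @return List with `green`, `red` rasters and `puncta`, a data.frame with
#'   `row`, `col`, `sigma_true`, `class` ("autophagosome"/"autolysosome"),
#'   `owner_cell` (nucleus index).
#' @export
generate_puncta_channels <- function(spec, nuclei) {
  set.seed(spec$seed + 1L)
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  green <- matrix(0, nr, nc); red <- matrix(0, nr, nc)
  puncta <- data.frame(row = numeric(0), col = numeric(0),
                       sigma_true = numeric(0), class = character(0),
                       owner_cell = integer(0))
  budget <- 400L
  smax <- spec$punctum_sigma_range[2]
  inside_any_nucleus <- function(r, c, margin) {
    if (nrow(nuclei) == 0) return(FALSE)
    any(sqrt((nuclei$row - r)^2 + (nuclei$col - c)^2) <= nuclei$radius + margin)
  }
  for (k in seq_len(nrow(nuclei))) {
    n_p <- rpois(1, spec$puncta_per_cell_mean)
    if (nuclei$is_bright[k]) n_p <- 0L  # puncta are unreadable there anyway
    for (j in seq_len(n_p)) {
      for (attempt in seq_len(budget)) {
        ang <- runif(1, 0, 2 * pi)
        dist <- runif(1, nuclei$radius[k] + 3 * smax, nuclei$radius[k] + 30)
        r <- nuclei$row[k] + dist * sin(ang)
        c <- nuclei$col[k] + dist * cos(ang)
        m <- 3 * smax
        ok <- r > m && r <= nr - m && c > m && c <= nc - m &&
          !inside_any_nucleus(r, c, 2 * smax) &&
          (nrow(puncta) == 0 ||
           all(sqrt((puncta$row - r)^2 + (puncta$col - c)^2) >=
               spec$min_punctum_separation))
        if (ok) {
          sig <- runif(1, spec$punctum_sigma_range[1], spec$punctum_sigma_range[2])
          cls <- if (runif(1) < spec$autolysosome_fraction) "autolysosome"
                 else "autophagosome"
          puncta <- rbind(puncta, data.frame(row = r, col = c, sigma_true = sig,
                                             class = cls, owner_cell = k))
          red <- render_gaussian_spot(red, r, c, sig, spec$punctum_amplitude)
          if (cls == "autophagosome")
            green <- render_gaussian_spot(green, r, c, sig, spec$punctum_amplitude)
          break
        }
        if (attempt == budget) break  # skip punctum: crowded image, not fatal
      }
    }
  }
  # bright-cell plateaus: high diffuse green over nucleus + halo
  for (k in which(nuclei$is_bright)) {
    green <- render_tapered_disc(green, nuclei$row[k], nuclei$col[k],
                                 nuclei$radius[k] + 12, spec$bright_amplitude,
                                 edge_width = 6)
  }
  green <- apply_noise(green + spec$background_level, spec)
  red <- apply_noise(red + spec$background_level, spec)
  list(green = green, red = red, puncta = puncta)
}

#' Generate one complete synthetic multi-channel image with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param name Image identifier.
#' @return List with `image` (a `multichannel_image`) and `truth`: list of
#'   `nuclei`, `puncta`, `effective_cell_count_true`, and `seed`. The true
#'   effective count applies the counting rule the pipeline implements to
#'   the true geometry: interior nuclei count 1, border nuclei count
#'   `min(1, visible area / expected full nucleus area)`, the expected full
#'   area being `pi * (radius_mean^2 + radius_sd^2)`.
#' @export
generate_synthetic_image <- function(spec, name = "synthetic") {
  nuc <- generate_nuclei_channel(spec)
  pun <- generate_puncta_channels(spec, nuc$nuclei)
  mean_full_area <- pi * (spec$nucleus_radius_mean^2 + spec$nucleus_radius_sd^2)
  visible <- nuc$nuclei$clip_fraction * pi * nuc$nuclei$radius^2
  eff <- sum(ifelse(nuc$nuclei$is_border,
                    pmin(1, visible / mean_full_area), 1))
  list(image = multichannel_image(nuc$raster, pun$green, pun$red, name = name),
       truth = list(nuclei = nuc$nuclei, puncta = pun$puncta,
                    effective_cell_count_true = eff, seed = spec$seed))
}

#' Generate a pair of rasters with a prescribed pixelwise Pearson correlation
#'
#' Builds two smooth random fields A and E, orthogonalizes E against A, and
#' mixes `B = rho * A + sqrt(1 - rho^2) * E` on standardized signals, so the
#' measured pixelwise correlation equals `rho_target` to float precision.
#' Outputs are affinely rescaled to [0, 1] (Pearson is invariant to this).
#'
#' @param shape (rows, cols).
#' @param rho_target Target correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @param smooth_sigma Gaussian smoothing applied to the white-noise fields,
#'   px; gives the rasters microscopy-like spatial structure.
#' @return List with matrices `a` and `b`.
#' @export
generate_colocalization_pair <- function(shape, rho_target, seed = 1L,
                                         smooth_sigma = 2) {
  assert_that(abs(rho_target) <= 1, "|rho_target| must be <= 1")
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  smooth_field <- function() {
    f <- matrix(rnorm(nr * nc), nr, nc)
    if (smooth_sigma > 0) f <- as.matrix(EBImage::gblur(f, sigma = smooth_sigma))
    as.vector(scale(as.vector(f)))  # mean 0, sd 1
  }
  a <- smooth_field()
  e <- smooth_field()
  e <- e - sum(a * e) / sum(a * a) * a       # exact orthogonalization
  e <- e / sd(e)
  b <- rho_target * a + sqrt(1 - rho_target^2) * e
  to01 <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) matrix(0.5, nr, nc)
    else matrix((v - rng[1]) / diff(rng), nr, nc)
  }
  list(a = to01(a), b = to01(b))
}

#' Generate a dataset of synthetic images on disk
#'
#' Writes, for every condition and image index, 16-bit grayscale TIFFs
#' `<condition>_<i>_b.tif`, `_g.tif`, `_r.tif`, a per-nucleus and per-punctum
#' ground-truth CSV keyed by image name, and a JSON sidecar echoing each
#' condition's spec. Per-image seeds are `spec$seed + 101 * (i - 1)` so the
#' dataset is reproducible and images are independent.
#'
#' @param specs Named list of [synthetic_spec()] objects, one per condition.
#' @param n_images Images per condition.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data.frame: name, condition,
#'   blue/green/red paths), `nuclei`, `puncta`, and `images` (the in-memory
#'   images keyed by name).
#' @export
generate_dataset <- function(specs, n_images, out_dir) {
  assert_that(length(specs) >= 1, "at least one condition required")
  assert_that(!is.null(names(specs)) && all(nzchar(names(specs))),
              "specs must be a named list (condition names)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- NULL; nuclei_all <- NULL; puncta_all <- NULL
  images <- list()
  for (cond in names(specs)) {
    for (i in seq_len(n_images)) {
      sp <- specs[[cond]]
      sp$seed <- as.integer(sp$seed + 101L * (i - 1L))
      nm <- sprintf("%s_%02d", cond, i)
      gen <- generate_synthetic_image(sp, name = nm)
      paths <- file.path(out_dir, paste0(nm, c("_b.tif", "_g.tif", "_r.tif")))
      write_channel_tiff(gen$image$blue, paths[1])
      write_channel_tiff(gen$image$green, paths[2])
      write_channel_tiff(gen$image$red, paths[3])
      manifest <- rbind(manifest, data.frame(
        name = nm, condition = cond, blue = paths[1], green = paths[2],
        red = paths[3], effective_cell_count_true = gen$truth$effective_cell_count_true))
      if (nrow(gen$truth$nuclei))
        nuclei_all <- rbind(nuclei_all, cbind(name = nm, gen$truth$nuclei))
      if (nrow(gen$truth$puncta))
        puncta_all <- rbind(puncta_all, cbind(name = nm, gen$truth$puncta))
      images[[nm]] <- gen$image
    }
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(nuclei_all))
    write.csv(nuclei_all, file.path(out_dir, "truth_nuclei.csv"), row.names = FALSE)
  if (!is.null(puncta_all))
    write.csv(puncta_all, file.path(out_dir, "truth_puncta.csv"), row.names = FALSE)
  jsonlite::write_json(specs, file.path(out_dir, "specs.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(manifest = manifest, nuclei = nuclei_all, puncta = puncta_all,
                 images = images))
}
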