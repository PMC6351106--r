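test_that("spec validation rejects inconsistent parameters", {
  expect_error(synthetic_spec(n_nuclei = -1), "counts")
  expect_error(synthetic_spec(punctum_sigma_range = c(3, 1)), "sigma_min")
  expect_error(synthetic_spec(autolysosome_fraction = 1.2), "autolysosome_fraction")
  expect_error(synthetic_spec(n_nuclei = 2, n_border_nuclei = 3), "n_border_nuclei")
})

test_that("empty spec yields a blank background and empty ground truth", {
  sp <- tiny_spec(n_nuclei = 0L, n_border_nuclei = 0L, noise_model = "none")
  nuc <- generate_nuclei_channel(sp)
  expect_equal(nrow(nuc$nuclei), 0)
  expect_true(all(nuc$raster == sp$background_level))
  pun <- generate_puncta_channels(sp, nuc$nuclei)
  expect_equal(nrow(pun$puncta), 0)
})

test_that("rendered nuclei match the requested count (flood-fill oracle)", {
  sp <- tiny_spec(n_nuclei = 5L, n_border_nuclei = 0L, noise_model = "none",
                  image_shape = c(256L, 256L), seed = 21L)
  nuc <- generate_nuclei_channel(sp)
  lab <- flood_fill_label(nuc$raster > sp$background_level + 0.2)
  expect_equal(max(lab), 5)
})

test_that("identical spec and seed reproduce rasters and truth exactly", {
  sp <- tiny_spec(n_bright_cells = 1L, autolysosome_fraction = 0.3)
  a <- generate_synthetic_image(sp)
  b <- generate_synthetic_image(sp)
  expect_identical(a$image$blue, b$image$blue)
  expect_identical(a$image$green, b$image$green)
  expect_identical(a$image$red, b$image$red)
  expect_identical(a$truth, b$truth)
})

test_that("border nuclei are clipped and reduce the true effective count", {
  sp <- tiny_spec(n_nuclei = 5L, n_border_nuclei = 2L, seed = 33L)
  gen <- generate_synthetic_image(sp)
  nuc <- gen$truth$nuclei
  expect_equal(sum(nuc$is_border), 2)
  expect_true(all(nuc$clip_fraction[nuc$is_border] < 1))
  expect_lt(gen$truth$effective_cell_count_true, 5)
  mean_full <- pi * (sp$nucleus_radius_mean^2 + sp$nucleus_radius_sd^2)
  vis <- nuc$clip_fraction[nuc$is_border] * pi * nuc$radius[nuc$is_border]^2
  expect_equal(gen$truth$effective_cell_count_true,
               3 + sum(pmin(1, vis / mean_full)))
})

test_that("placement failure names the constraint", {
  sp <- tiny_spec(image_shape = c(64L, 64L), n_nuclei = 30L,
                  n_border_nuclei = 0L)
  expect_error(generate_nuclei_channel(sp), "placement error")
})

test_that("tandem classes follow autolysosome_fraction", {
  # fraction 0: every punctum present in both channels
  sp0 <- tiny_spec(autolysosome_fraction = 0, noise_model = "none")
  g0 <- generate_synthetic_image(sp0)
  expect_true(all(g0$truth$puncta$class == "autophagosome"))
  for (i in seq_len(nrow(g0$truth$puncta))) {
    p <- g0$truth$puncta[i, ]
    expect_gt(g0$image$green[round(p$row), round(p$col)],
              sp0$background_level + 0.2)
    expect_gt(g0$image$red[round(p$row), round(p$col)],
              sp0$background_level + 0.2)
  }
  # fraction 1: green contains background only
  sp1 <- tiny_spec(autolysosome_fraction = 1, noise_model = "none",
                   n_bright_cells = 0L)
  g1 <- generate_synthetic_image(sp1)
  expect_true(all(g1$truth$puncta$class == "autolysosome"))
  expect_equal(max(g1$image$green), sp1$background_level)
})

test_that("empirical class fraction lies in the exact binomial 99% interval", {
  sp <- synthetic_spec(image_shape = c(768L, 768L), n_nuclei = 24L,
                       n_border_nuclei = 0L, puncta_per_cell_mean = 22,
                       autolysosome_fraction = 0.3, seed = 55L)
  gen <- generate_synthetic_image(sp)
  n <- nrow(gen$truth$puncta)
  expect_gte(n, 400)
  k <- sum(gen$truth$puncta$class == "autolysosome")
  ci <- binom.test(k, n, p = 0.3, conf.level = 0.99)
  expect_gt(ci$p.value, 0.01)  # observed fraction consistent with 0.3
})

test_that("increasing noise variance never decreases raster variance", {
  vars <- sapply(c(0, 0.01, 0.03, 0.06), function(s) {
    sp <- tiny_spec(noise_model = if (s == 0) "none" else "gaussian",
                    noise_sd = s, seed = 9L)
    var(as.vector(generate_nuclei_channel(sp)$raster))
  })
  expect_true(all(diff(vars) >= 0))
})

test_that("every ground-truth punctum is visibly rendered in the red channel", {
  sp <- tiny_spec(noise_model = "none", seed = 77L)
  gen <- generate_synthetic_image(sp)
  for (i in seq_len(nrow(gen$truth$puncta))) {
    p <- gen$truth$puncta[i, ]
    expect_gt(gen$image$red[round(p$row), round(p$col)],
              sp$background_level + 0.25 * sp$punctum_amplitude)
  }
})

test_that("speckle noise adds isolated max-value impulses", {
  sp <- tiny_spec(noise_model = "speckle", speckle_density = 0.002, seed = 13L)
  nuc <- generate_nuclei_channel(sp)
  expect_gte(sum(nuc$raster == 1), 0.5 * round(0.002 * length(nuc$raster)))
})

test_that("dataset generation writes files, truth tables, and is reproducible", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  specs <- list(ctrl = tiny_spec(seed = 1L),
                treat = tiny_spec(puncta_per_cell_mean = 10, seed = 2L))
  ds1 <- generate_dataset(specs, n_images = 3, out_dir = d1)
  expect_equal(nrow(ds1$manifest), 6)
  expect_length(list.files(d1, pattern = "\\.tif$"), 18)
  ds2 <- generate_dataset(specs, n_images = 3, out_dir = d2)
  expect_identical(readLines(file.path(d1, "truth_puncta.csv")),
                   readLines(file.path(d2, "truth_puncta.csv")))
  expect_identical(readLines(file.path(d1, "truth_nuclei.csv")),
                   readLines(file.path(d2, "truth_nuclei.csv")))
  # channels written round-trip through 16-bit TIFF
  img <- read_channel(ds1$manifest$blue[1])
  expect_equal(dim(img), c(192, 192))
  expect_equal(max(abs(img - ds1$images[[ds1$manifest$name[1]]]$blue)), 0,
               tolerance = 1 / 65535)
})

test_that("doubling the puncta load doubles the true per-cell load", {
  specs <- list(a = tiny_spec(puncta_per_cell_mean = 5, seed = 3L,
                              image_shape = c(320L, 320L), n_nuclei = 8L,
                              n_border_nuclei = 0L),
                b = tiny_spec(puncta_per_cell_mean = 10, seed = 4L,
                              image_shape = c(320L, 320L), n_nuclei = 8L,
                              n_border_nuclei = 0L))
  d <- withr::local_tempdir()
  ds <- generate_dataset(specs, n_images = 4, out_dir = d)
  n_a <- sum(ds$puncta$name %in% ds$manifest$name[ds$manifest$condition == "a"])
  n_b <- sum(ds$puncta$name %in% ds$manifest$name[ds$manifest$condition == "b"])
  # ratio of two Poisson totals: check 2 lies inside the ratio's 99% CI
  pt <- poisson.test(c(n_b, n_a), r = 2)
  expect_gt(pt$p.value, 0.01)
})

test_that("colocalization pairs hit the target correlation", {
  cp <- generate_colocalization_pair(c(128L, 128L), 1, seed = 8L)
  expect_equal(pearson_coefficient(cp$a, cp$b), 1, tolerance = 1e-12)
  cn <- generate_colocalization_pair(c(128L, 128L), -1, seed = 8L)
  expect_equal(pearson_coefficient(cn$a, cn$b), -1, tolerance = 1e-12)
  ch <- generate_colocalization_pair(c(512L, 512L), 0.5, seed = 8L)
  expect_equal(pearson_coefficient(ch$a, ch$b), 0.5, tolerance = 0.02)
  expect_error(generate_colocalization_pair(c(64L, 64L), 1.4), "rho_target")
})
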