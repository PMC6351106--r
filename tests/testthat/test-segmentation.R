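test_that("Otsu threshold separates a clean two-level image", {
  x <- disc_raster(64, 64, cbind(32, 32), 12, bg = 10, fg = 200) / 255
  thr <- otsu_threshold(x)
  expect_gt(thr, 10 / 255)
  expect_lt(thr, 200 / 255)
  expect_identical(x > thr, x == 200 / 255)
})

test_that("Otsu equals the exhaustive between-class-variance search", {
  set.seed(401)
  for (i in 1:20) {
    v <- c(round(rnorm(400, 80, 20)), round(rnorm(250, 175, 25)))
    v <- as.integer(pmin(255, pmax(0, v)))
    x <- matrix(v / 255, ncol = 25)
    thr <- otsu_threshold(x)
    t_oracle <- brute_otsu_bin(v / 255)
    # same class partition as the oracle's optimal split
    rng <- range(v / 255); w <- diff(rng) / 256
    idx <- pmin(256, pmax(1, ceiling((v / 255 - rng[1]) / w)))
    idx[v / 255 == rng[1]] <- 1
    expect_identical(as.vector(x) > thr, idx > t_oracle)
  }
})

test_that("Otsu errors on a constant raster", {
  expect_error(otsu_threshold(matrix(5, 10, 10)), "degenerate histogram")
})

test_that("smoothing does not change the mask of a well-separated image", {
  x <- disc_raster(96, 96, rbind(c(30, 30), c(66, 66)), 14) / 255
  m0 <- make_nuclei_mask(x, smoothing_sigma = 0)
  m1 <- make_nuclei_mask(x, smoothing_sigma = 1)
  expect_gt(mean(m0 == m1), 0.995)  # identical up to a 1-px rim
  expect_equal(max(flood_fill_label(m1)), 2)
})

test_that("watershed keeps a single disc whole", {
  mask <- disc_raster(80, 80, cbind(40, 40), 18, bg = 0, fg = 1) > 0
  ln <- split_touching_nuclei(mask)
  expect_equal(nrow(ln$records), 1)
  expect_equal(ln$records$area, sum(mask))
})

test_that("watershed splits two overlapping discs into two comparable labels", {
  mask <- disc_raster(100, 130, rbind(c(50, 50), c(50, 80)), 20,
                      bg = 0, fg = 1) > 0
  single <- sum(disc_raster(100, 130, cbind(50, 50), 20, bg = 0, fg = 1) > 0)
  ln <- split_touching_nuclei(mask)
  expect_equal(nrow(ln$records), 2)
  expect_true(all(abs(ln$records$area - single) / single <= 0.15))
  expect_equal(sum(ln$records$area), sum(mask))
})

test_that("watershed on separated discs equals connected-component labeling", {
  mask <- disc_raster(120, 120, rbind(c(30, 30), c(85, 85), c(30, 90)), 15,
                      bg = 0, fg = 1) > 0
  ln <- split_touching_nuclei(mask)
  ref <- flood_fill_label(mask)
  expect_equal(nrow(ln$records), max(ref))
  # identical partitions up to label permutation
  tab <- table(ln$labels[mask], ref[mask])
  expect_equal(sum(tab > 0), max(ref))
})

test_that("area filtering removes small labels and conserves the rest", {
  labels <- matrix(0L, 40, 60)
  labels[2:21, 2:21] <- 1L   # 400 px
  labels[2:26, 30:43] <- 2L  # 350 px
  labels[35:38, 50:52] <- 3L # 12 px
  ln <- structure(list(labels = labels, records = punctaflux:::label_records(labels)),
                  class = "labeled_nuclei")
  expect_identical(filter_small_regions(ln, 0)$records$area, ln$records$area)
  f <- filter_small_regions(ln, 50)
  expect_equal(nrow(f$records), 2)
  expect_equal(f$records$label, 1:2)
  expect_equal(f$records$area, c(400L, 350L))
  # conservation: surviving + removed areas = original foreground
  expect_equal(sum(f$records$area) + 12, sum(labels > 0))
  expect_equal(sum(f$labels > 0), sum(f$records$area))
})

test_that("fractional border counting follows the mean-interior-area rule", {
  ln <- fake_nuclei_records(areas = c(100, 100, 100, 50),
                            border = c(FALSE, FALSE, FALSE, TRUE))
  cc <- count_cells(list(ln))
  expect_equal(cc$total_effective, 3.5)
  expect_equal(cc$n_interior, 3)
  # border nucleus larger than the mean contributes 1 (capped)
  ln2 <- fake_nuclei_records(areas = c(100, 100, 100, 130),
                             border = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(count_cells(list(ln2))$total_effective, 4)
  # only-border dataset is an error
  ln3 <- fake_nuclei_records(areas = c(80, 90), border = c(TRUE, TRUE))
  expect_error(count_cells(list(ln3)), "cannot estimate average nuclei size")
})

test_that("mean interior area is estimated dataset-wide, not per image", {
  a <- fake_nuclei_records(areas = c(100, 100), border = c(FALSE, FALSE))
  b <- fake_nuclei_records(areas = c(200, 75), border = c(FALSE, TRUE))
  cc <- count_cells(list(a = a, b = b))
  # mean interior area = (100 + 100 + 200) / 3
  expect_equal(cc["b", "n_border_effective"], 75 / (400 / 3))
})

test_that("adding one interior nucleus adds exactly 1 to the effective count", {
  base <- fake_nuclei_records(areas = c(90, 110, 60), border = c(FALSE, FALSE, TRUE))
  more <- fake_nuclei_records(areas = c(90, 110, 60, 100),
                              border = c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(count_cells(list(more))$total_effective,
               count_cells(list(base))$total_effective + 1)
})

test_that("bright-cell fence flags the hand-computed outlier and no more", {
  labels <- matrix(0L, 20, 110)
  for (k in 1:10) labels[6:10, (k * 10 - 7):(k * 10 - 4)] <- as.integer(k)
  img_vals <- matrix(0, 20, 110)
  for (k in 1:10) img_vals[labels == k] <- if (k == 4) 10000 else 100
  image <- list(blue = img_vals, green = img_vals, red = img_vals)
  ln <- structure(list(labels = labels,
                       records = punctaflux:::label_records(labels, image)),
                  class = "labeled_nuclei")
  # by hand on {100 x 9, 10000}: Q3 = 100, IQR = 0, fence = 100 -> only the
  # 10000 label exceeds it (and the median guard: 10000 > 1.5 * 100)
  fl <- flag_bright_cells(ln, channel = "green")
  expect_identical(which(fl$records$excluded_bright), 4L)
  expect_true(any(fl$exclusion_mask))
  # halo: exclusion extends beyond the label itself
  expect_gt(sum(fl$exclusion_mask), sum(labels == 4))
})

test_that("no bright flags with equal intensities or fewer than 4 nuclei", {
  labels <- matrix(0L, 20, 110)
  for (k in 1:10) labels[6:10, (k * 10 - 7):(k * 10 - 4)] <- as.integer(k)
  flat <- matrix(0, 20, 110); flat[labels > 0] <- 50
  image <- list(blue = flat, green = flat, red = flat)
  ln <- structure(list(labels = labels,
                       records = punctaflux:::label_records(labels, image)),
                  class = "labeled_nuclei")
  expect_false(any(flag_bright_cells(ln)$records$excluded_bright))
  labels3 <- matrix(0L, 20, 40)
  for (k in 1:3) labels3[6:10, (k * 10 - 7):(k * 10 - 4)] <- as.integer(k)
  vals3 <- matrix(0, 20, 40); vals3[labels3 == 2] <- 1e5; vals3[labels3 != 2 & labels3 > 0] <- 1
  image3 <- list(blue = vals3, green = vals3, red = vals3)
  ln3 <- structure(list(labels = labels3,
                        records = punctaflux:::label_records(labels3, image3)),
                   class = "labeled_nuclei")
  expect_false(any(flag_bright_cells(ln3)$records$excluded_bright))
})

test_that("generator bright cells are recovered with no false flags", {
  sp <- synthetic_spec(image_shape = c(384L, 384L), n_nuclei = 10L,
                       n_border_nuclei = 0L, n_bright_cells = 2L,
                       puncta_per_cell_mean = 5, seed = 7L)
  gen <- generate_synthetic_image(sp)
  ln <- segment_nuclei(gen$image)
  expect_equal(sum(ln$records$excluded_bright), 2)
  expect_equal(nrow(ln$records), 10)
})

test_that("label partition invariant holds through the segmentation chain", {
  sp <- tiny_spec(seed = 19L)
  gen <- generate_synthetic_image(sp)
  mask <- make_nuclei_mask(gen$image$blue)
  ln <- split_touching_nuclei(mask, gen$image)
  expect_equal(sum(ln$records$area), sum(mask))
  f <- filter_small_regions(ln, 200)
  expect_equal(sum(f$records$area), sum(f$labels > 0))
})

test_that("noise-free synthetic nuclei are recovered at true count", {
  sp <- tiny_spec(n_nuclei = 5L, n_border_nuclei = 0L, noise_model = "none",
                  image_shape = c(256L, 256L), seed = 21L)
  gen <- generate_synthetic_image(sp)
  ln <- segment_nuclei(gen$image)
  expect_equal(sum(!ln$records$touches_border), 5)
})
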