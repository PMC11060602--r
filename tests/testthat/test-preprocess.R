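test_that("max projection is the per-pixel maximum and permutation-invariant", {
  a <- image2d(matrix(c(1, 0, 0, 0), 2, 2), 40)
  b <- image2d(matrix(c(0, 0, 2, 0), 2, 2), 40)
  expect_equal(unclass(max_project(list(a))), unclass(a))
  expect_equal(unclass(max_project(list(a, b))), matrix(c(1, 0, 2, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(unclass(max_project(list(b, a))),
               unclass(max_project(list(a, b))))
  expect_error(max_project(list(a, image2d(matrix(0, 3, 3), 40))), "shape")
})

test_that("background subtraction clips at zero and records provenance", {
  m <- matrix(50, 20, 40)
  m[, 10:12] <- 150
  img <- image2d(m, 40)
  out <- subtract_background(img, roi = c(20, 0, 10, 10))
  expect_equal(unique(as.vector(unclass(out)[, 10:12])), 100)
  expect_equal(unique(as.vector(unclass(out)[, 1:5])), 0)
  expect_equal(attr(out, "provenance")$background$mean, 50)

  # constant image: everything subtracts to zero (with a signal warning)
  flat <- image2d(matrix(50, 10, 10), 40)
  expect_warning(out2 <- subtract_background(flat, c(0, 0, 5, 5)),
                 "ROI likely contains signal")
  expect_true(all(unclass(out2) == 0))

  # monotonicity: an ROI covering signal subtracts more
  out3 <- suppressWarnings(subtract_background(img, roi = c(9, 0, 3, 20)))
  expect_gt(attr(out3, "provenance")$background$mean,
            attr(out, "provenance")$background$mean)
  expect_error(subtract_background(img, c(35, 0, 10, 10)), "outside")
})

test_that("isodata threshold splits a symmetric two-level image at the midpoint", {
  img <- image2d(matrix(rep(c(0, 100), each = 50), 10, 10), 40)
  expect_equal(isodata_threshold(img), 50, tolerance = 1e-6)
  expect_error(isodata_threshold(image2d(matrix(7, 5, 5), 40)), "degenerate")
})

test_that("isodata threshold agrees with the exhaustive fixed-point oracle", {
  for (s in 1:100) {
    v <- withr::with_seed(s, {
      # bimodal-ish random 8-bit images
      n_lo <- sample(20:200, 1)
      round(c(rnorm(n_lo, 60, 25), rnorm(256 - n_lo, 170, 30)))
    })
    v <- pmin(pmax(v, 0), 255)
    if (min(v) == max(v)) next
    img <- image2d(matrix(v, 16, 16), 40)
    t_impl <- isodata_threshold(img)
    fixed <- isodata_oracle(v)
    expect_gt(length(fixed), 0)
    bw <- (max(v) - min(v)) / 256
    # the nearest scan candidate to the returned threshold is a fixed point
    expect_lt(min(abs(fixed - t_impl)), bw + 1e-9)
  }
})

test_that("binarize follows the strict-threshold convention and is monotone", {
  img <- image2d(matrix(1:16, 4, 4), 40)
  expect_equal(sum(binarize(img, 16)), 0)
  expect_equal(sum(binarize(img, 0)), 16)
  counts <- vapply(c(2, 5, 9, 13), function(t) sum(binarize(img, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("particle analysis matches geometry on known shapes", {
  m <- matrix(FALSE, 10, 12)
  m[2:4, 2:4] <- TRUE     # 3x3 square
  m[7:9, 8:10] <- TRUE    # second 3x3 square
  ps <- analyze_particles(as_mask(m), min_area_px = 1)
  expect_equal(nrow(ps$particles), 2)
  expect_equal(ps$particles$area_px, c(9, 9))
  expect_equal(ps$particles$n_outline, c(8, 8))  # centre pixel is interior
  expect_equal(ps$particles$area_nm2, c(9, 9) * 40^2)

  # diagonal touch merges under 8-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  psd <- analyze_particles(as_mask(d), min_area_px = 1)
  expect_equal(nrow(psd$particles), 1)

  # area filter drops small components; count non-increasing in min_area
  ns <- vapply(c(1, 5, 10), function(a) {
    nrow(analyze_particles(as_mask(m), min_area_px = a)$particles)
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("labeling equals the flood-fill oracle on random masks", {
  for (s in 1:50) {
    nr <- withr::with_seed(s, sample(8:20, 1))
    nc <- withr::with_seed(s + 500, sample(8:20, 1))
    mask <- random_mask(nr, nc, 0.45, seed = s)
    ps <- analyze_particles(mask, min_area_px = 1)
    oracle <- floodfill_oracle(unclass(mask))
    expect_true(same_partition(ps$labels, oracle),
                info = sprintf("seed %d", s))
  }
})

test_that("bare outline pixels are foreground touching 4-connected background", {
  mask <- random_mask(15, 15, 0.5, seed = 99)
  ps <- analyze_particles(mask, min_area_px = 1)
  m <- unclass(mask)
  for (k in seq_len(nrow(ps$particles))) {
    for (idx in ps$particles$outline_idx[[k]]) {
      i <- (idx - 1) %% 15 + 1; j <- (idx - 1) %/% 15 + 1
      expect_true(m[i, j])
      nb_bg <- (i == 1 || !m[i - 1, j]) || (i == 15 || !m[i + 1, j]) ||
        (j == 1 || !m[i, j - 1]) || (j == 15 || !m[i, j + 1])
      expect_true(nb_bg)
    }
    # outline pixels belong to the particle
    expect_true(all(ps$particles$outline_idx[[k]] %in%
                      ps$particles$pixel_idx[[k]]))
  }
})

test_that("particle labels are 1..K in raster order and pairwise disjoint", {
  mask <- random_mask(20, 20, 0.4, seed = 3)
  ps <- analyze_particles(mask, min_area_px = 1)
  labs <- ps$particles$label
  expect_equal(labs, seq_along(labs))
  # raster order: first pixel (row-major) of particle k precedes that of k+1
  first_raster <- vapply(ps$particles$pixel_idx, function(idx) {
    i <- (idx - 1) %% 20 + 1; j <- (idx - 1) %/% 20 + 1
    min((i - 1) * 20 + j)
  }, numeric(1))
  expect_true(all(diff(first_raster) > 0))
  all_idx <- unlist(ps$particles$pixel_idx)
  expect_equal(length(all_idx), length(unique(all_idx)))
  expect_equal(sort(all_idx), which(ps$labels > 0))
})

test_that("the pipeline is idempotent on binary input and reproducible", {
  img <- clean_fixture(n_sarcomeres = 4, shape = c(24, 300))
  z <- img$channels$zdisc
  r1 <- preprocess_channel(z, roi = c(30, 0, 20, 20))
  r2 <- preprocess_channel(z, roi = c(30, 0, 20, 20))
  expect_identical(unclass(r1$mask), unclass(r2$mask))
  expect_equal(r1$log$threshold, r2$log$threshold)
  # particle count equals Z-discs in the field on a clean channel
  expect_equal(nrow(r1$particles$particles),
               length(img$ground_truth$centers_nm))
  # binarizing the mask-as-image reproduces the mask
  mimg <- image2d(unclass(r1$mask) * 1, 40)
  expect_equal(unclass(binarize(mimg, 0.5)), unclass(r1$mask),
               ignore_attr = TRUE)
  # zero-background input: skipping subtraction changes nothing
  t_direct <- isodata_threshold(z)
  mask_direct <- binarize(z, t_direct)
  expect_equal(unclass(mask_direct), unclass(r1$mask))
})
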