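test_that("profile sampling follows the stated conventions", {
  img <- image2d(matrix(7, 20, 20), 40)
  p <- line_path(c(0, 10), c(10, 10), sample_step_px = 0.25)
  prof <- extract_profile(img, p)
  expect_equal(nrow(prof), 41)                      # 10 px / 0.25 + 1
  expect_true(all(prof$value == 7))
  expect_equal(diff(prof$position_nm)[1], 0.25 * 40)

  # bilinear sample at a pixel centre equals the pixel value
  m <- matrix(runif(100), 10, 10)
  img2 <- image2d(m, 40)
  prof2 <- extract_profile(img2, line_path(c(2.5, 4.5), c(7.5, 4.5),
                                           sample_step_px = 1))
  expect_equal(prof2$value, m[5, 3:8])

  expect_error(extract_profile(img, line_path(c(-1, 5), c(10, 5))), "outside")
})

test_that("crossings land at sample midpoints with the documented convention", {
  prof <- tibble::tibble(position_nm = seq(0, 400, by = 100),
                         value = c(0, 0, 1, 1, 0))
  ev <- detect_crossings(prof)
  expect_equal(ev$position_nm, c(150, 350))
  expect_equal(ev$type, c("enter", "exit"))
  expect_true(all(ev$real))
  b <- bands_from_crossings(ev, channel = "z")
  expect_equal(b$center_nm, 250)
  expect_equal(b$width_nm, 200)
  expect_true(b$complete)

  # all-ones profile: one band flagged incomplete
  ones <- tibble::tibble(position_nm = seq(0, 400, by = 100), value = rep(1, 5))
  b1 <- bands_from_crossings(detect_crossings(ones))
  expect_equal(nrow(b1), 1)
  expect_false(b1$complete)

  # all-zero profile: nothing
  zeros <- tibble::tibble(position_nm = seq(0, 400, by = 100), value = rep(0, 5))
  expect_equal(nrow(detect_crossings(zeros)), 0)
  expect_equal(nrow(bands_from_crossings(detect_crossings(zeros))), 0)
})

test_that("crossing positions converge under sample-step refinement", {
  img <- clean_fixture(n_sarcomeres = 4, shape = c(16, 300))
  pre <- preprocess_channel(img$channels$zdisc, roi = c(30, 0, 20, 16))
  get_centers <- function(step) {
    p <- line_path(c(0, 8), c(300, 8), sample_step_px = step)
    b <- scan_bands(pre$clean_mask, p)
    b$center_nm[b$complete]
  }
  coarse <- get_centers(0.5)
  fine <- get_centers(0.05)
  expect_equal(length(coarse), length(fine))
  expect_lt(max(abs(coarse - fine)), 0.5 * 40)
})

test_that("band metrics are invariant to reversing the path direction", {
  img <- clean_fixture(n_sarcomeres = 4, shape = c(16, 300))
  pre <- preprocess_channel(img$channels$zdisc, roi = c(30, 0, 20, 16))
  fwd <- scan_bands(pre$clean_mask, line_path(c(0, 8), c(300, 8)))
  rev <- scan_bands(pre$clean_mask, line_path(c(300, 8), c(0, 8)))
  total <- 300 * 40
  expect_equal(sort(total - rev$center_nm), sort(fwd$center_nm),
               tolerance = 1e-8)
  expect_equal(sort(rev$width_nm), sort(fwd$width_nm))
})

test_that("auto paths follow the striation normal and are separated", {
  img <- clean_fixture(n_sarcomeres = 6, shape = c(64, 400))
  paths <- auto_paths(img$channels$zdisc, n_scans = 5,
                      min_separation_px = 2, seed = 1)
  expect_length(paths, 5)
  for (p in paths) {
    dir <- (p$end - p$start) / p$length_px
    ang <- atan2(dir[2], dir[1]) * 180 / pi
    expect_lt(min(abs(ang %% 180), 180 - abs(ang %% 180)), 2)
  }
  # pairwise perpendicular separation respected (horizontal paths: rows)
  rows <- sort(vapply(paths, function(p) p$start[2], numeric(1)))
  expect_true(all(diff(rows) >= 2))
  # deterministic per seed
  p2 <- auto_paths(img$channels$zdisc, n_scans = 5, min_separation_px = 2,
                   seed = 1)
  expect_identical(paths, p2)

  expect_error(auto_paths(image2d(matrix(rnorm(64 * 64, 100, 1), 64), 40),
                          n_scans = 3, seed = 1),
               "no striation")
})

test_that("recovered scan orientation rotates with the lattice", {
  lat30 <- make_lattice(8, length_jitter_sd_nm = 0, orientation_deg = 30,
                        epitopes = NULL, origin_nm = 700, seed = 1)
  img <- render_ground_truth(lat30, c(300, 300), 40)$channels$zdisc
  paths <- auto_paths(img, n_scans = 3, seed = 1)
  dir <- (paths[[1]]$end - paths[[1]]$start) / paths[[1]]$length_px
  ang <- atan2(dir[2], dir[1]) * 180 / pi
  expect_lt(abs(ang %% 180 - 30), 2)
})

test_that("particle-aware bands bridge interior dropouts", {
  m <- matrix(FALSE, 9, 30)
  m[, 10:14] <- TRUE
  m[5, 12] <- FALSE            # interior hole at the scan row
  ps <- analyze_particles(as_mask(m), min_area_px = 1)
  b <- scan_bands(ps, line_path(c(0, 4.5), c(30, 4.5)))
  expect_equal(nrow(b), 1)     # one particle, one band
  expect_equal(b$width_nm, 5 * 40, tolerance = 40)
})
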