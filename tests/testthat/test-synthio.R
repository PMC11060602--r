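test_that("zero-jitter lattices are exactly periodic and deterministic", {
  lat <- make_lattice(5, length_mean_nm = 2400, length_jitter_sd_nm = 0,
                      origin_nm = 0, seed = 1)
  expect_equal(lat$centers_nm, c(0, 2400, 4800, 7200, 9600))

  a <- make_lattice(10, length_jitter_sd_nm = 60, seed = 1)
  b <- make_lattice(10, length_jitter_sd_nm = 60, seed = 1)
  c <- make_lattice(10, length_jitter_sd_nm = 60, seed = 2)
  expect_identical(a$centers_nm, b$centers_nm)
  expect_false(identical(a$centers_nm, c$centers_nm))
  expect_true(all(diff(a$centers_nm) > 0))
})

test_that("jittered spacings follow the stated sampling distribution", {
  lat <- make_lattice(1e4 + 1, length_mean_nm = 2400,
                      length_jitter_sd_nm = 60, seed = 7)
  sp <- diff(lat$centers_nm)
  se <- 60 / sqrt(length(sp))
  expect_lt(abs(mean(sp) - 2400), 3 * se)
  expect_lt(abs(sd(sp) - 60) / 60, 0.05)
})

test_that("invalid lattice parameters name the offending field", {
  expect_error(make_lattice(0), "n_sarcomeres")
  expect_error(make_lattice(3, length_mean_nm = -5), "length_mean_nm")
  expect_error(make_lattice(3, zdisc_width_nm = -1), "zdisc_width_nm")
  epi <- default_epitopes(); epi$side[1] <- "left"
  expect_error(make_lattice(3, epitopes = epi), "side")
})

test_that("rendering anti-aliases band edges and conserves analytic mass", {
  lat <- make_lattice(3, length_jitter_sd_nm = 0, zdisc_width_nm = 60,
                      origin_nm = 1000, epitopes = NULL, seed = 1)
  img <- render_ground_truth(lat, c(8, 200), 40)$channels$zdisc
  # mass bookkeeping: bands of 60 nm x amplitude 1, constant over rows
  n_inside <- sum(lat$centers_nm > 30 & lat$centers_nm < 200 * 40 - 30)
  expected_mass <- n_inside * 60 / 40 * 8
  expect_lt(abs(sum(img) - expected_mass) / expected_mass, 0.005)
  # a 60 nm band centred at 1000 covers px 24 (10/40), px 25 fully... check
  # fractional edges sum to width/pixel per band per row
  col_mass <- colSums(unclass(img)) / 8
  expect_true(all(col_mass <= 1 + 1e-12))
})

test_that("zero-width bands render as indicators on the containing pixel", {
  lat <- make_lattice(2, length_jitter_sd_nm = 0, zdisc_width_nm = 0,
                      origin_nm = 1000, epitopes = NULL, seed = 1)
  img <- render_ground_truth(lat, c(4, 150), 40)$channels$zdisc
  hit_cols <- which(colSums(unclass(img)) > 0)
  expect_equal(hit_cols, floor(lat$centers_nm / 40) + 1)
  expect_true(all(unclass(img)[, hit_cols] == 1))
})

test_that("flanking epitope bands straddling one Z-disc are 570 nm apart", {
  lat <- make_lattice(2, length_jitter_sd_nm = 0, origin_nm = 3000, seed = 1)
  bands <- sarcoscan:::lattice_bands(lat, "N2A")
  centers <- sort(bands$center_nm)
  # pairs straddling each Z-disc centre
  for (zc in lat$centers_nm) {
    below <- max(centers[centers < zc])
    above <- min(centers[centers > zc])
    expect_equal(above - below, 570)
  }
})

test_that("a lattice entirely outside the grid is an error", {
  lat <- make_lattice(2, length_jitter_sd_nm = 0, origin_nm = 1e6, seed = 1)
  expect_error(render_ground_truth(lat, c(8, 100), 40), "outside field")
})

test_that("optical blur is flux-conserving with the stated impulse FWHM", {
  optics <- optical_model(psf_fwhm_nm = 240, linkage_error_nm = 0,
                          pixel_size_nm = 40)
  m <- matrix(0, 41, 41); m[21, 21] <- 1
  img <- image2d(m, 40)
  out <- apply_optics(img, optics)
  expect_lt(abs(sum(out) - 1), 0.001)          # flux conserved to 0.1%
  fwhm_px <- fit_fwhm_px(unclass(out)[21, ])   # independent Gaussian fit
  expect_lt(abs(fwhm_px - 6), 0.2)             # 240 nm / 40 nm = 6 px

  # identity at zero blur
  expect_equal(unclass(apply_optics(img, optical_model(0, 0, pixel_size_nm = 40))),
               unclass(img))
})

test_that("effective blur SD grows with both PSF width and linkage error", {
  grid <- expand.grid(fwhm = c(0, 120, 280), link = c(0, 2, 17.5))
  sig <- mapply(function(f, l) sigma_total(optical_model(f, l)),
                grid$fwhm, grid$link)
  expect_true(all(diff(sig[order(grid$fwhm, grid$link)]) >= 0) ||
                all(tapply(sig, grid$link, function(s) all(diff(s) >= 0))))
  # explicit monotone checks
  expect_lt(sigma_total(optical_model(120, 2)), sigma_total(optical_model(280, 2)))
  expect_lt(sigma_total(optical_model(120, 2)), sigma_total(optical_model(120, 17.5)))
})

test_that("noise model matches its stated moments and determinism", {
  optics <- optical_model(photons_per_unit = 10, background_level = 5,
                          read_noise_sd = 0, pixel_size_nm = 40)
  img <- image2d(matrix(100, 1000, 1000), 40)
  noisy <- add_noise(img, optics, seed = 11)
  # mean = 100 + background/photons, SE = sqrt(1005)/10 / 1000
  expected <- 100 + 5 / 10
  se <- sqrt(10 * 100 + 5) / 10 / sqrt(length(img))
  expect_lt(abs(mean(noisy) - expected), 3 * se)
  expect_identical(unclass(add_noise(img, optics, seed = 11)), unclass(noisy))
  expect_false(identical(unclass(add_noise(img, optics, seed = 12)),
                         unclass(noisy)))
  # noiseless limit
  quiet <- add_noise(image2d(matrix(50, 20, 20), 40),
                     optical_model(photons_per_unit = 1e9, background_level = 0,
                                   read_noise_sd = 0, pixel_size_nm = 40),
                     seed = 1)
  expect_lt(max(abs(unclass(quiet) - 50)), 0.1)
  expect_error(add_noise(img, optical_model(photons_per_unit = 0,
                                            pixel_size_nm = 40), 1),
               "photons_per_unit")
})

test_that("modality presets differ only in PSF and linkage error", {
  p1 <- optics_preset("confocal_igg")
  p2 <- optics_preset("sim_igg")
  p3 <- optics_preset("sim_nanobody")
  same <- c("photons_per_unit", "background_level", "read_noise_sd",
            "pixel_size_nm")
  for (f in same) {
    expect_equal(p1[[f]], p2[[f]])
    expect_equal(p2[[f]], p3[[f]])
  }
  expect_false(p1$psf_fwhm_nm == p2$psf_fwhm_nm)
  expect_false(p2$linkage_error_nm == p3$linkage_error_nm)
  expect_error(optics_preset("widefield"), "confocal_igg")
})

test_that("simulation is deterministic per seed and attaches ground truth", {
  a <- simulate_image(list(n_sarcomeres = 3, origin_nm = 700),
                      "sim_nanobody", c(16, 220), seed = 5)
  b <- simulate_image(list(n_sarcomeres = 3, origin_nm = 700),
                      "sim_nanobody", c(16, 220), seed = 5)
  expect_identical(lapply(a$channels, unclass), lapply(b$channels, unclass))
  expect_s3_class(a$ground_truth, "sarcomere_lattice")
})

test_that("fixtures round-trip through 16-bit TIFF and JSON sidecars", {
  outdir <- withr::local_tempdir()
  cfg <- list(lattice = list(n_sarcomeres = 3, origin_nm = 700),
              optics = "sim_nanobody", shape = c(16, 220),
              n_images = 3, base_seed = 2)
  man <- write_fixtures(cfg, outdir)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$tiff)))
  expect_true(all(file.exists(man$sidecar)))
  expect_true(file.exists(file.path(outdir, "manifest.json")))

  # re-run: identical sidecars
  outdir2 <- withr::local_tempdir()
  man2 <- write_fixtures(cfg, outdir2)
  expect_identical(readLines(man$sidecar[1]), readLines(man2$sidecar[1]))

  # quantization error bounded by one 16-bit step of the dynamic range
  orig <- simulate_image(cfg$lattice, "sim_nanobody", c(16, 220), seed = 2)
  back <- read_fixture(man$tiff[1])
  for (ch in names(orig$channels)) {
    scale <- max(orig$channels[[ch]])
    err <- max(abs(unclass(back$channels[[ch]]) - unclass(orig$channels[[ch]])))
    expect_lte(err, scale / 65535)
  }
  expect_equal(back$ground_truth$centers_nm, orig$ground_truth$centers_nm)
})
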