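# Shared simulated fixtures, built in code at test time.

# A clean (noise-free, blur-free) zero-jitter image with all channels.
clean_fixture <- function(n_sarcomeres = 9, shape = c(64, 620),
                          pixel_size_nm = 40, origin_nm = 700) {
  lat <- make_lattice(n_sarcomeres, length_jitter_sd_nm = 0,
                      origin_nm = origin_nm, seed = 1)
  optics <- optical_model(psf_fwhm_nm = 0, linkage_error_nm = 0,
                          pixel_size_nm = pixel_size_nm)
  simulate_image(lat, optics, shape, seed = 1, noise = FALSE)
}

# Horizontal paths at evenly spaced rows (for axis-aligned lattices, with
# positions directly comparable to lattice coordinates).
horizontal_paths <- function(shape, n = 5, step = 0.25) {
  rows <- seq(shape[1] * 0.15, shape[1] * 0.85, length.out = n)
  lapply(rows, function(r) line_path(c(0, r), c(shape[2], r), step))
}

# Random binary masks with tunable density for particle oracle tests.
random_mask <- function(nr, nc, p, seed) {
  withr::with_seed(seed, {
    m <- matrix(runif(nr * nc) < p, nr, nc)
  })
  structure(m, pixel_size_nm = 40, channel = "test",
            threshold = 0.5,
            connectivity = "8-connected foreground / 4-connected background",
            class = c("binary_mask", "matrix", "array"))
}

# Wrap a logical matrix as a binary_mask.
as_mask <- function(m, pixel_size_nm = 40, channel = "test") {
  structure(m, pixel_size_nm = pixel_size_nm, channel = channel,
            threshold = 0.5,
            connectivity = "8-connected foreground / 4-connected background",
            class = c("binary_mask", "matrix", "array"))
}
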