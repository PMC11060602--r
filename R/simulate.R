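#' Simulate a multi-channel fluorescence image of a sarcomere lattice
#'
#' Composes the full forward model: realize a lattice ([make_lattice()]),
#' render its noise-free channels ([render_ground_truth()]), blur each
#' channel with the effective PSF + linkage-error Gaussian
#' ([apply_optics()]) and add shot and read noise ([add_noise()]). The
#' ground-truth lattice is attached to the result. Deterministic per
#' `seed`: the lattice uses `seed` and channel `k` uses noise seed
#' `seed + k`.
#'
#' @param lattice_params Either a `sarcomere_lattice` or a list of
#'   arguments for [make_lattice()] (without `seed`).
#' @param optics An [optical_model()] or preset name for [optics_preset()].
#' @param shape Image shape `c(nrow, ncol)` in pixels.
#' @param seed Integer seed.
#' @param noise Set `FALSE` to return the blurred, noise-free image.
#' @return A [multichannel_image()] with `ground_truth` attached.
#' @examples
#' img <- simulate_image(list(n_sarcomeres = 3, origin_nm = 1200),
#'                       optics_preset("sim_nanobody"),
#'                       shape = c(16, 220), seed = 1)
#' @export
simulate_image <- function(lattice_params, optics, shape, seed = 1L,
                           noise = TRUE) {
  if (is.character(optics)) optics <- optics_preset(optics)
  lattice <- if (inherits(lattice_params, "sarcomere_lattice")) {
    lattice_params
  } else {
    do.call(make_lattice, utils::modifyList(as.list(lattice_params),
                                            list(seed = seed)))
  }
  clean <- render_ground_truth(lattice, shape, optics$pixel_size_nm)
  chans <- purrr::imap(clean$channels, function(ch, lab) {
    blurred <- apply_optics(ch, optics)
    if (noise) {
      idx <- match(lab, names(clean$channels))
      add_noise(blurred, optics, seed = seed + idx)
    } else {
      blurred
    }
  })
  multichannel_image(unname(chans), ground_truth = lattice)
}

lattice_to_list <- function(lat) {
  list(
    n_sarcomeres = lat$n_sarcomeres,
    length_mean_nm = lat$length_mean_nm,
    length_jitter_sd_nm = lat$length_jitter_sd_nm,
    zdisc_width_nm = lat$zdisc_width_nm,
    epitopes = if (is.null(lat$epitopes)) NULL else as.data.frame(lat$epitopes),
    orientation_deg = lat$orientation_deg,
    origin_nm = lat$origin_nm,
    min_length_nm = lat$min_length_nm,
    seed = lat$seed,
    centers_nm = lat$centers_nm
  )
}

lattice_from_list <- function(x) {
  lat <- make_lattice(
    n_sarcomeres = x$n_sarcomeres,
    length_mean_nm = x$length_mean_nm,
    length_jitter_sd_nm = x$length_jitter_sd_nm,
    zdisc_width_nm = x$zdisc_width_nm,
    epitopes = if (is.null(x$epitopes)) NULL else tibble::as_tibble(x$epitopes),
    orientation_deg = x$orientation_deg,
    origin_nm = x$origin_nm,
    min_length_nm = x$min_length_nm,
    seed = x$seed
  )
  # trust the recorded realization over a re-draw (RNG streams can differ
  # across R versions)
  lat$centers_nm <- as.numeric(x$centers_nm)
  lat$lengths_nm <- diff(lat$centers_nm)
  lat
}

#' Write simulated fixture images to disk
#'
#' Simulates `n_images` fields under one configuration and writes, per
#' image, a multi-page 16-bit grayscale TIFF (one page per channel, each
#' channel linearly rescaled to the 16-bit range with the scale recorded in
#' the sidecar), a JSON sidecar holding the full lattice and optics
#' parameters plus the realized Z-disc centres, and a single
#' `manifest.json` listing files, seeds and parameters.
#'
#' @param config A list with elements `lattice` (arguments for
#'   [make_lattice()]), `optics` (an [optical_model()] or preset name),
#'   `shape`, `n_images` and `base_seed` (image `i` uses seed
#'   `base_seed + 100 * (i - 1)`).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a tibble manifest: `image`, `tiff`, `sidecar`, `seed`.
#' @export
write_fixtures <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create outdir '%s'", outdir))
  optics <- config$optics
  if (is.character(optics)) optics <- optics_preset(optics)
  n <- config$n_images %||% 1L
  base_seed <- config$base_seed %||% 1L

  rows <- purrr::map(seq_len(n), function(i) {
    seed <- base_seed + 100L * (i - 1L)
    img <- simulate_image(config$lattice, optics, config$shape, seed = seed)
    name <- sprintf("image_%03d", i)
    tiff_path <- file.path(outdir, paste0(name, ".tif"))
    side_path <- file.path(outdir, paste0(name, ".json"))

    scales <- vapply(img$channels, function(ch) max(max(ch), 1e-12), numeric(1))
    pages <- purrr::map2(img$channels, scales, function(ch, s) unclass(ch) / s)
    ok <- tryCatch(
      tiff::writeTIFF(unname(pages), tiff_path, bits.per.sample = 16L),
      error = function(e) abort(sprintf("failed writing '%s': %s",
                                        tiff_path, conditionMessage(e))))
    sidecar <- list(
      image = name,
      seed = seed,
      pixel_size_nm = optics$pixel_size_nm,
      channels = names(img$channels),
      intensity_scale = as.list(scales),
      optics = unclass(optics),
      lattice = lattice_to_list(img$ground_truth)
    )
    jsonlite::write_json(sidecar, side_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    tibble::tibble(image = name, tiff = tiff_path, sidecar = side_path,
                   seed = seed)
  })
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(
    list(n_images = n, base_seed = base_seed,
         files = manifest[, c("image", "tiff", "sidecar", "seed")]),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a simulated fixture back as a multi-channel image
#'
#' Inverts [write_fixtures()] for one image: reads the multi-page TIFF,
#' undoes the recorded 16-bit rescale, and restores channel labels, pixel
#' size and the ground-truth lattice from the sidecar.
#'
#' @param tiff_path Path to the fixture TIFF; the sidecar is expected next
#'   to it with the same stem and `.json` extension.
#' @return A [multichannel_image()].
#' @export
read_fixture <- function(tiff_path) {
  side_path <- sub("\\.tif{1,2}$", ".json", tiff_path)
  if (!file.exists(tiff_path)) abort(sprintf("no such file: '%s'", tiff_path))
  if (!file.exists(side_path)) abort(sprintf("missing sidecar: '%s'", side_path))
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  chans <- purrr::imap(pages, function(m, i) {
    lab <- side$channels[[i]]
    image2d(m * side$intensity_scale[[lab]], side$pixel_size_nm, lab)
  })
  multichannel_image(chans, ground_truth = lattice_from_list(side$lattice))
}
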