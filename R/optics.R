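#' Optical forward-model parameters
#'
#' Describes how a fluorophore-density map becomes a recorded image: an
#' isotropic Gaussian PSF of given lateral FWHM, an antibody linkage error
#' (the RMS displacement between epitope and fluorophore introduced by the
#' antibody stack) folded into the blur in quadrature, Poisson shot noise at
#' a given photon scale, a constant background added before the shot noise,
#' and Gaussian read noise. The effective blur SD is
#' `sigma_tot = sqrt((psf_fwhm_nm / 2.3548)^2 + linkage_error_nm^2)` with
#' `2.3548 = 2 * sqrt(2 * log(2))` converting FWHM to SD; it is
#' non-decreasing in both the PSF width and the linkage error.
#'
#' @param psf_fwhm_nm Lateral PSF full width at half maximum (nm, >= 0).
#' @param linkage_error_nm RMS fluorophore displacement from the epitope
#'   (nm, >= 0); large for full IgG primary/secondary stacks, small for
#'   single-domain nanobodies.
#' @param photons_per_unit Expected photons per unit of fluorophore density
#'   (> 0); controls the shot-noise level.
#' @param background_level Constant background, in photons, added before
#'   the Poisson draw.
#' @param read_noise_sd SD of additive Gaussian read noise, in intensity
#'   units (>= 0).
#' @param pixel_size_nm Sampling interval (nm/px, > 0).
#' @return An `optical_model` list.
#' @seealso [optics_preset()] for the built-in modality presets.
#' @export
optical_model <- function(psf_fwhm_nm = 280,
                          linkage_error_nm = 17.5,
                          photons_per_unit = 200,
                          background_level = 20,
                          read_noise_sd = 0.01,
                          pixel_size_nm = 40) {
  bad <- function(field, msg) abort(sprintf("invalid `%s`: %s", field, msg))
  if (!is.numeric(psf_fwhm_nm) || psf_fwhm_nm < 0) bad("psf_fwhm_nm", "must be >= 0")
  if (!is.numeric(linkage_error_nm) || linkage_error_nm < 0) {
    bad("linkage_error_nm", "must be >= 0")
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    bad("pixel_size_nm", "must be > 0")
  }
  if (!is.numeric(read_noise_sd) || read_noise_sd < 0) {
    bad("read_noise_sd", "must be >= 0")
  }
  if (!is.numeric(background_level) || background_level < 0) {
    bad("background_level", "must be >= 0")
  }
  structure(list(
    psf_fwhm_nm = psf_fwhm_nm,
    linkage_error_nm = linkage_error_nm,
    photons_per_unit = photons_per_unit,
    background_level = background_level,
    read_noise_sd = read_noise_sd,
    pixel_size_nm = pixel_size_nm
  ), class = "optical_model")
}

# FWHM <-> SD conversion constant, 2*sqrt(2*ln 2)
FWHM_TO_SD <- 2 * sqrt(2 * log(2))

#' @rdname optical_model
#' @param optics An `optical_model`.
#' @return `sigma_total()`: the effective blur SD in nm.
#' @export
sigma_total <- function(optics) {
  sqrt((optics$psf_fwhm_nm / FWHM_TO_SD)^2 + optics$linkage_error_nm^2)
}

#' Built-in imaging-modality presets
#'
#' Three modality presets spanning the resolution range of interest:
#' `"confocal_igg"` (confocal PSF, full IgG antibody stack),
#' `"sim_igg"` (structured-illumination resolution, IgG stack) and
#' `"sim_nanobody"` (structured illumination with nanobody secondaries,
#' minimizing linkage error). The presets differ only in `psf_fwhm_nm` and
#' `linkage_error_nm`; PSF defaults are 280 nm (confocal) and 120 nm (SIM),
#' linkage defaults 17.5 nm (IgG) and 2 nm (nanobody). All values are
#' stand-in, configurable defaults, not calibrated instrument constants.
#'
#' @param name One of `"confocal_igg"`, `"sim_igg"`, `"sim_nanobody"`.
#' @param ... Overrides passed on to [optical_model()].
#' @return An [optical_model()].
#' @examples
#' optics_preset("sim_nanobody")
#' @export
optics_preset <- function(name, ...) {
  presets <- list(
    confocal_igg = list(psf_fwhm_nm = 280, linkage_error_nm = 17.5),
    sim_igg      = list(psf_fwhm_nm = 120, linkage_error_nm = 17.5),
    sim_nanobody = list(psf_fwhm_nm = 120, linkage_error_nm = 2)
  )
  if (!name %in% names(presets)) {
    abort(sprintf("unknown preset '%s'; valid presets: %s",
                  name, paste(names(presets), collapse = ", ")))
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(optical_model, args)
}

#' @export
print.optical_model <- function(x, ...) {
  cat(sprintf(
    "<optical_model> PSF FWHM %.3g nm, linkage %.3g nm (sigma_tot %.3g nm), %.3g nm/px\n",
    x$psf_fwhm_nm, x$linkage_error_nm, sigma_total(x), x$pixel_size_nm))
  cat(sprintf("  photons/unit %.3g, background %.3g, read noise SD %.3g\n",
              x$photons_per_unit, x$background_level, x$read_noise_sd))
  invisible(x)
}

# Map integer positions (possibly < 1 or > n) into 1..n by mirror
# reflection at the boundaries; reflection conserves total flux under a
# symmetric normalized kernel.
mirror_index <- function(p, n) {
  q <- ((p - 1L) %% (2L * n) + 2L * n) %% (2L * n) # 0 .. 2n-1
  ifelse(q < n, q + 1L, 2L * n - q)
}

# 1-D convolution of each row of `m` with symmetric kernel `k`
# (odd length), reflective padding. Returns a matrix of the same shape.
conv_rows_reflect <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nc <- ncol(m)
  if (r == 0L) return(m * k)
  idx <- mirror_index((1L - r):(nc + r), nc)
  padded <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[, j:(j + nc - 1L), drop = FALSE]
  }
  out
}

gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(4 * sigma_px))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

#' Apply the optical blur to an image
#'
#' Convolves the image with an isotropic Gaussian whose SD is the effective
#' blur `sigma_tot` (PSF plus linkage error in quadrature; see
#' [optical_model()]) expressed in pixels. The convolution is separable,
#' uses reflective padding at the boundary, and conserves total intensity.
#' A zero-width blur returns the input unchanged.
#'
#' @param img An [image2d()].
#' @param optics An [optical_model()]; its `pixel_size_nm` is ignored in
#'   favour of the image's own pixel size.
#' @return A blurred [image2d()].
#' @export
apply_optics <- function(img, optics) {
  if (!is_image2d(img)) abort("`img` must be an image2d.")
  sig_nm <- sigma_total(optics)
  if (sig_nm == 0) return(img)
  sig_px <- sig_nm / pixel_size(img)
  k <- gaussian_kernel(sig_px)
  out <- conv_rows_reflect(unclass(img), k)          # blur along x
  out <- t(conv_rows_reflect(t(out), k))             # blur along y
  reimage(img, out)
}
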