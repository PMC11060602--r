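#' Add photon shot noise and camera read noise
#'
#' The recorded intensity is modelled as
#' `Poisson(photons_per_unit * img + background_level) / photons_per_unit
#'  + Normal(0, read_noise_sd)`, clipped at zero: a constant background (in
#' photons) is added before the Poisson draw, the photon count is rescaled
#' back to density units, and Gaussian read noise is added last. The result
#' is a pure function of `(img, optics, seed)`.
#'
#' @param img A non-negative [image2d()].
#' @param optics An [optical_model()]; uses `photons_per_unit`,
#'   `background_level` and `read_noise_sd`.
#' @param seed Integer seed.
#' @return A noisy [image2d()].
#' @export
add_noise <- function(img, optics, seed = 1L) {
  if (!is_image2d(img)) abort("`img` must be an image2d.")
  if (any(img < 0)) abort("`img` must be non-negative.")
  ppu <- optics$photons_per_unit
  if (!is.numeric(ppu) || ppu <= 0) {
    abort("invalid `photons_per_unit`: must be > 0")
  }
  out <- withr::with_seed(seed, {
    lambda <- ppu * as.vector(unclass(img)) + optics$background_level
    counts <- rpois(length(lambda), lambda) / ppu
    counts + rnorm(length(lambda), 0, optics$read_noise_sd)
  })
  reimage(img, matrix(pmax(out, 0), nrow(img), ncol(img)))
}
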