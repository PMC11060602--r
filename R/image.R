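#' Two-dimensional intensity image with physical pixel size
#'
#' The substrate of the pipeline: a numeric matrix of non-negative
#' intensities plus the physical size of one pixel in nanometres and a
#' channel label. Rows are image rows (y), columns are image columns (x);
#' the continuous pixel coordinate system is zero-based and half-open, so
#' pixel `(i, j)` (0-based) covers `x in [j, j+1)`, `y in [i, i+1)` and has
#' its centre at `(j + 0.5, i + 0.5)`.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_nm Physical edge length of one pixel, in nm (> 0).
#' @param channel Channel label, e.g. `"zdisc"` or `"N2A"`.
#' @return An `image2d` object (a matrix with attributes).
#' @examples
#' img <- image2d(matrix(0, 8, 8), pixel_size_nm = 40)
#' pixel_size(img)
#' @export
image2d <- function(pixels, pixel_size_nm, channel = "unnamed") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.")
  }
  if (any(!is.finite(pixels))) abort("`pixels` must be finite everywhere.")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) abort("image must be at least 1x1.")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("`pixel_size_nm` must be a single positive number.")
  }
  structure(pixels,
            pixel_size_nm = as.numeric(pixel_size_nm),
            channel = as.character(channel),
            class = c("image2d", "matrix", "array"))
}

#' @rdname image2d
#' @param x An `image2d`.
#' @export
pixel_size <- function(x) attr(x, "pixel_size_nm")

#' @rdname image2d
#' @export
channel_label <- function(x) attr(x, "channel")

is_image2d <- function(x) inherits(x, "image2d")

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %d x %d px, %.3g nm/px, channel '%s'\n",
              nrow(x), ncol(x), pixel_size(x), channel_label(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x), max(x)))
  invisible(x)
}

# Rebuild an image2d with new pixel values, keeping metadata.
reimage <- function(template, pixels) {
  image2d(pixels, pixel_size(template), channel_label(template))
}

#' Multi-channel image
#'
#' An ordered set of [image2d()] channels sharing shape and pixel size,
#' optionally carrying the ground-truth lattice that generated them (for
#' simulated data).
#'
#' @param channels List of [image2d()] objects with unique channel labels,
#'   congruent shapes and equal pixel sizes.
#' @param ground_truth Optional [make_lattice()] result.
#' @return A `multichannel_image`.
#' @export
multichannel_image <- function(channels, ground_truth = NULL) {
  if (!is.list(channels) || length(channels) < 1) {
    abort("`channels` must be a non-empty list of image2d objects.")
  }
  if (!all(vapply(channels, is_image2d, logical(1)))) {
    abort("every channel must be an image2d.")
  }
  labs <- vapply(channels, channel_label, character(1))
  if (anyDuplicated(labs)) abort("channel labels must be unique.")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all channels must share the same shape.")
  }
  px <- vapply(channels, pixel_size, numeric(1))
  if (any(px != px[1])) abort("all channels must share pixel_size_nm.")
  names(channels) <- labs
  structure(list(channels = channels, ground_truth = ground_truth),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  ch <- x$channels[[1]]
  cat(sprintf("<multichannel_image> %d channel(s) [%s], %d x %d px, %.3g nm/px%s\n",
              length(x$channels),
              paste(names(x$channels), collapse = ", "),
              nrow(ch), ncol(ch), pixel_size(ch),
              if (is.null(x$ground_truth)) "" else ", with ground truth"))
  invisible(x)
}

#' Maximum-intensity projection of an image stack
#'
#' Collapses a z-stack to a single 2D image by taking the per-pixel maximum
#' across slices, the standard reconstruction for band-like structures
#' imaged through a section.
#'
#' @param stack A list of [image2d()] slices with congruent shapes, or a 3D
#'   numeric array (slices along the third dimension) with `pixel_size_nm`
#'   supplied.
#' @param pixel_size_nm Pixel size when `stack` is a bare array.
#' @param channel Channel label when `stack` is a bare array.
#' @return An [image2d()].
#' @examples
#' a <- image2d(matrix(1:4, 2, 2), 40)
#' b <- image2d(matrix(4:1, 2, 2), 40)
#' max_project(list(a, b))
#' @export
max_project <- function(stack, pixel_size_nm = NULL, channel = "unnamed") {
  if (is.array(stack) && length(dim(stack)) == 3) {
    if (is.null(pixel_size_nm)) abort("`pixel_size_nm` required for bare arrays.")
    out <- apply(stack, c(1, 2), max)
    return(image2d(out, pixel_size_nm, channel))
  }
  if (!is.list(stack) || length(stack) < 1) {
    abort("`stack` must be a non-empty list of image2d slices.")
  }
  dims <- vapply(stack, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("stack slices differ in shape.")
  }
  out <- Reduce(pmax, lapply(stack, unclass))
  image2d(out, pixel_size(stack[[1]]), channel_label(stack[[1]]))
}
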