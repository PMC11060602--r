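#' Default titin epitope layout
#'
#' Epitope bands flanking each Z-disc, given as offsets (nm) of the band
#' centre from the nearest Z-disc centre. The defaults place the titin N2A
#' epitope 285 nm from the Z-disc centre on both sides (so the two N2A bands
#' straddling one Z-disc are 570 nm apart) and the PEVK epitope 115 nm from
#' the Z-disc centre on both sides (so N2A and PEVK on the same side are
#' 170 nm apart). Offsets are configurable per channel.
#'
#' @param n2a_offset_nm Distance N2A centre to Z-disc centre (nm).
#' @param pevk_offset_nm Distance PEVK centre to Z-disc centre (nm).
#' @param band_width_nm Intrinsic epitope band width (nm).
#' @return A tibble with columns `channel`, `offset_nm`, `band_width_nm`,
#'   `side` (one of `"both"`, `"plus"`, `"minus"`).
#' @export
default_epitopes <- function(n2a_offset_nm = 285, pevk_offset_nm = 115,
                             band_width_nm = 30) {
  tibble::tibble(
    channel = c("N2A", "PEVK"),
    offset_nm = c(n2a_offset_nm, pevk_offset_nm),
    band_width_nm = band_width_nm,
    side = "both"
  )
}

validate_epitopes <- function(epitopes) {
  if (is.null(epitopes)) return(invisible(NULL))
  need <- c("channel", "offset_nm", "band_width_nm", "side")
  if (!is.data.frame(epitopes) || !all(need %in% names(epitopes))) {
    abort(paste0("`epitopes` must be a data frame with columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (any(epitopes$offset_nm < 0)) abort("epitope `offset_nm` must be >= 0.")
  if (any(epitopes$band_width_nm < 0)) abort("epitope `band_width_nm` must be >= 0.")
  if (!all(epitopes$side %in% c("both", "plus", "minus"))) {
    abort("epitope `side` must be one of 'both', 'plus', 'minus'.")
  }
  if (anyDuplicated(epitopes$channel)) abort("epitope channels must be unique.")
  invisible(NULL)
}

#' Realize a ground-truth sarcomere lattice
#'
#' Draws a one-dimensional lattice of Z-disc centre positions along the
#' fibre axis. Centres are `c_i = origin + sum_{j<=i} L_j` with per-sarcomere
#' lengths `L_j ~ Normal(length_mean_nm, length_jitter_sd_nm)` truncated
#' below at `max(min_length_nm, 4 * zdisc_width_nm)` so consecutive bands
#' can never overlap or invert. With zero jitter the spacing is exactly
#' `length_mean_nm`. The realization is a pure function of the parameters
#' and `seed`.
#'
#' Defaults reflect resting mouse skeletal muscle: sarcomere length around
#' 2.3-2.47 um (default mean 2400 nm) and a Z-disc lateral width of
#' 30-140 nm depending on muscle and species (default 60 nm).
#'
#' @param n_sarcomeres Number of Z-disc bands (>= 1); the lattice spans
#'   `n_sarcomeres - 1` full inter-disc spacings.
#' @param length_mean_nm Mean sarcomere length L (nm, > 0).
#' @param length_jitter_sd_nm SD of per-sarcomere length deviations (nm, >= 0).
#' @param zdisc_width_nm True Z-disc band width (nm, >= 0).
#' @param epitopes Epitope layout as in [default_epitopes()], or `NULL` for
#'   a Z-disc-only lattice.
#' @param orientation_deg Direction of the stripe normal (the fibre axis) in
#'   the image plane, degrees from the +x axis.
#' @param origin_nm Position of the first Z-disc centre (nm).
#' @param min_length_nm Hard lower truncation for sampled lengths (nm).
#' @param seed Integer seed.
#' @return A `sarcomere_lattice` list with the parameters plus
#'   `centers_nm`, the realized strictly increasing Z-disc centre positions.
#' @examples
#' lat <- make_lattice(n_sarcomeres = 4, length_jitter_sd_nm = 0, seed = 1)
#' lat$centers_nm
#' @export
make_lattice <- function(n_sarcomeres,
                         length_mean_nm = 2400,
                         length_jitter_sd_nm = 0,
                         zdisc_width_nm = 60,
                         epitopes = default_epitopes(),
                         orientation_deg = 0,
                         origin_nm = 0,
                         min_length_nm = 400,
                         seed = 1L) {
  stopifnot_param <- function(ok, field, msg) {
    if (!ok) abort(sprintf("invalid `%s`: %s", field, msg))
  }
  stopifnot_param(is.numeric(n_sarcomeres) && n_sarcomeres >= 1,
                  "n_sarcomeres", "must be >= 1")
  stopifnot_param(is.numeric(length_mean_nm) && length_mean_nm > 0,
                  "length_mean_nm", "must be > 0")
  stopifnot_param(is.numeric(length_jitter_sd_nm) && length_jitter_sd_nm >= 0,
                  "length_jitter_sd_nm", "must be >= 0")
  stopifnot_param(is.numeric(zdisc_width_nm) && zdisc_width_nm >= 0,
                  "zdisc_width_nm", "must be >= 0")
  validate_epitopes(epitopes)

  n <- as.integer(n_sarcomeres) - 1L  # number of spacings between centres
  lmin <- max(min_length_nm, 4 * zdisc_width_nm)
  stopifnot_param(length_mean_nm > lmin, "length_mean_nm",
                  sprintf("must exceed the truncation bound %.4g nm", lmin))

  lengths <- if (n == 0L) numeric(0) else withr::with_seed(seed, {
    if (length_jitter_sd_nm == 0) {
      rep(length_mean_nm, n)
    } else {
      draw <- rnorm(n, length_mean_nm, length_jitter_sd_nm)
      # redraw truncated tail until all lengths clear the bound
      while (any(draw <= lmin)) {
        bad <- draw <= lmin
        draw[bad] <- rnorm(sum(bad), length_mean_nm, length_jitter_sd_nm)
      }
      draw
    }
  })

  centers <- origin_nm + c(0, cumsum(lengths))
  structure(list(
    n_sarcomeres = as.integer(n_sarcomeres),
    length_mean_nm = length_mean_nm,
    length_jitter_sd_nm = length_jitter_sd_nm,
    zdisc_width_nm = zdisc_width_nm,
    epitopes = epitopes,
    orientation_deg = orientation_deg,
    origin_nm = origin_nm,
    min_length_nm = min_length_nm,
    seed = as.integer(seed),
    lengths_nm = lengths,
    centers_nm = centers
  ), class = "sarcomere_lattice")
}

#' @export
print.sarcomere_lattice <- function(x, ...) {
  cat(sprintf(
    "<sarcomere_lattice> %d Z-discs, L = %.4g nm (jitter SD %.3g), w_Z = %.3g nm\n",
    x$n_sarcomeres, x$length_mean_nm, x$length_jitter_sd_nm, x$zdisc_width_nm))
  cat(sprintf("  Z-disc centers: %.4g .. %.5g nm, orientation %.3g deg\n",
              min(x$centers_nm), max(x$centers_nm), x$orientation_deg))
  if (!is.null(x$epitopes)) {
    cat(sprintf("  epitopes: %s\n", paste(x$epitopes$channel, collapse = ", ")))
  }
  invisible(x)
}

# All ground-truth band intervals for one channel of a lattice:
# tibble(center_nm, width_nm) along the fibre axis.
lattice_bands <- function(lattice, channel) {
  if (channel == "zdisc") {
    return(tibble::tibble(center_nm = lattice$centers_nm,
                          width_nm = lattice$zdisc_width_nm))
  }
  epi <- lattice$epitopes
  if (is.null(epi) || !channel %in% epi$channel) {
    abort(sprintf("channel '%s' not defined in lattice epitopes.", channel))
  }
  row <- epi[epi$channel == channel, ]
  offs <- switch(row$side,
                 both = c(-row$offset_nm, row$offset_nm),
                 plus = row$offset_nm,
                 minus = -row$offset_nm)
  centers <- sort(as.vector(outer(lattice$centers_nm, offs, `+`)))
  tibble::tibble(center_nm = centers, width_nm = row$band_width_nm)
}

lattice_channels <- function(lattice) {
  c("zdisc", if (!is.null(lattice$epitopes)) lattice$epitopes$channel)
}
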