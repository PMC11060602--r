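# Exact 1-D coverage of disjoint top-hat bands over pixel intervals
# [edges[j], edges[j+1]). Bands are tibble(center_nm, width_nm); amplitude 1
# inside a band, so the pixel value is the covered fraction of the pixel
# footprint. Zero-width bands render as an indicator on the pixel whose
# footprint contains the centre.
coverage_1d <- function(edges_lo, edges_hi, bands) {
  p <- edges_hi - edges_lo
  cov <- numeric(length(edges_lo))
  for (b in seq_len(nrow(bands))) {
    w <- bands$width_nm[b]
    c0 <- bands$center_nm[b]
    if (w > 0) {
      lo <- c0 - w / 2
      hi <- c0 + w / 2
      cov <- cov + pmax(0, pmin(edges_hi, hi) - pmax(edges_lo, lo)) / p
    } else {
      cov <- cov + as.numeric(edges_lo <= c0 & c0 < edges_hi)
    }
  }
  cov
}

# Union-of-bands membership test for supersampled rendering; assumes the
# bands of one channel are pairwise disjoint (true for all realistic
# geometries: the lattice truncation keeps them well separated).
in_bands <- function(u, bands) {
  ord <- order(bands$center_nm)
  lo <- bands$center_nm[ord] - bands$width_nm[ord] / 2
  hi <- bands$center_nm[ord] + bands$width_nm[ord] / 2
  edges <- as.vector(rbind(lo, hi))
  findInterval(u, edges) %% 2L == 1L
}

#' Render a lattice into noise-free fluorophore-density channels
#'
#' Produces one noise-free channel per labelled structure: the Z-disc
#' channel is a top-hat of width `zdisc_width_nm` centred on every realized
#' Z-disc centre, constant along the stripe direction and rotated by the
#' lattice's `orientation_deg`; each epitope channel renders top-hats at the
#' configured offsets on either side of each Z-disc. Pixel values are the
#' mean density over the pixel footprint, so sub-pixel band edges are
#' anti-aliased (fractional coverage). For axis-aligned lattices the
#' coverage is computed analytically; for oblique orientations the pixel
#' footprint is supersampled.
#'
#' @param lattice A [make_lattice()] result.
#' @param shape Integer `c(nrow, ncol)` of the target grid, in pixels.
#' @param pixel_size_nm Pixel size of the target grid (nm/px).
#' @param channels Which channels to render; default all channels the
#'   lattice defines.
#' @param supersample Sub-pixel sampling factor per axis for oblique
#'   orientations.
#' @return A [multichannel_image()] carrying the lattice as ground truth.
#' @examples
#' lat <- make_lattice(3, length_jitter_sd_nm = 0, origin_nm = 1000, seed = 1)
#' img <- render_ground_truth(lat, shape = c(16, 200), pixel_size_nm = 40)
#' @export
render_ground_truth <- function(lattice, shape, pixel_size_nm,
                                channels = lattice_channels(lattice),
                                supersample = 5L) {
  stopifnot(length(shape) == 2, all(shape >= 1), pixel_size_nm > 0)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  theta <- lattice$orientation_deg * pi / 180
  ct <- cos(theta); st <- sin(theta)
  axis_aligned <- lattice$orientation_deg %% 90 == 0

  render_one <- function(channel) {
    bands <- lattice_bands(lattice, channel)
    if (axis_aligned) {
      quarter <- (lattice$orientation_deg %/% 90) %% 4
      n_u <- if (quarter %% 2 == 0) nc else nr
      # u runs along +x (0), +y (90), -x (180), -y (270); mirror the band
      # centres instead of the axis for the negative directions
      bands_eff <- bands
      if (quarter >= 2) bands_eff$center_nm <- -bands$center_nm
      lo <- (seq_len(n_u) - 1) * pixel_size_nm
      cov <- coverage_1d(lo, lo + pixel_size_nm, bands_eff)
      px <- if (quarter %% 2 == 0) {
        matrix(cov, nr, nc, byrow = TRUE)
      } else {
        matrix(cov, nr, nc)
      }
    } else {
      ss <- as.integer(supersample)
      off <- (seq_len(ss) - 0.5) / ss
      px <- matrix(0, nr, nc)
      xg <- rep(seq_len(nc) - 1, each = nr)
      yg <- rep(seq_len(nr) - 1, times = nc)
      for (ox in off) {
        for (oy in off) {
          u <- ((xg + ox) * ct + (yg + oy) * st) * pixel_size_nm
          px <- px + matrix(in_bands(u, bands), nr, nc)
        }
      }
      px <- px / ss^2
    }
    image2d(px, pixel_size_nm, channel)
  }

  chans <- lapply(channels, render_one)
  if (all(vapply(chans, function(x) max(x) == 0, logical(1)))) {
    abort("lattice outside field: no band intersects the image grid.")
  }
  multichannel_image(chans, ground_truth = lattice)
}
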