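#' Subtract the mean of a background region of interest
#'
#' The first pre-processing step: the mean gray value over a background
#' rectangle (outside the fluorescent label) is subtracted globally from
#' the channel and negative values are clipped to zero. The subtracted
#' value is recorded in the result's `provenance` attribute.
#'
#' @param img An [image2d()].
#' @param roi Either `"auto"` (the 64x64 tile, or the largest tile that
#'   fits, with minimal mean intensity) or a rectangle `c(x, y, w, h)` in
#'   0-based pixel coordinates.
#' @return The subtracted [image2d()]; `attr(, "provenance")$background`
#'   holds the subtracted mean and the ROI used.
#' @examples
#' img <- image2d(matrix(50, 16, 16) + diag(16) * 100, 40)
#' out <- subtract_background(img, roi = c(0, 8, 8, 8))
#' attr(out, "provenance")$background
#' @export
subtract_background <- function(img, roi = "auto") {
  if (!is_image2d(img)) abort("`img` must be an image2d.")
  if (identical(roi, "auto")) roi <- auto_background_roi(img)
  if (length(roi) != 4 || any(roi[3:4] < 1)) {
    abort("`roi` must be c(x, y, w, h) with w, h >= 1.")
  }
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (x < 0 || y < 0 || x + w > ncol(img) || y + h > nrow(img)) {
    abort("roi extends outside the image.")
  }
  block <- unclass(img)[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
  bg <- mean(block)
  if (bg >= max(img)) warn("ROI likely contains signal: its mean is >= the image maximum.")
  out <- reimage(img, pmax(unclass(img) - bg, 0))
  attr(out, "provenance") <- list(background = list(mean = bg, roi = roi))
  out
}

# The tile (64x64, or the largest square that fits) with minimal mean,
# scanned on a half-tile grid.
auto_background_roi <- function(img, tile = 64L) {
  t_h <- min(tile, nrow(img)); t_w <- min(tile, ncol(img))
  step_y <- max(1L, t_h %/% 2L); step_x <- max(1L, t_w %/% 2L)
  ys <- unique(c(seq(0L, nrow(img) - t_h, by = step_y), nrow(img) - t_h))
  xs <- unique(c(seq(0L, ncol(img) - t_w, by = step_x), ncol(img) - t_w))
  best <- NULL; best_mean <- Inf
  m <- unclass(img)
  for (y in ys) for (x in xs) {
    mu <- mean(m[(y + 1):(y + t_h), (x + 1):(x + t_w)])
    if (mu < best_mean) { best_mean <- mu; best <- c(x, y, t_w, t_h) }
  }
  best
}

#' IsoData (iterative intermeans) threshold
#'
#' The classical Ridler-Calvard automatic threshold on a binned histogram:
#' starting from the global mean, iterate
#' `t <- (mean(values <= t) + mean(values > t)) / 2`
#' until the change is below one bin width, and return the fixed point in
#' intensity units. The iteration is monotone and bounded on a finite
#' histogram, so it always terminates.
#'
#' @param img An [image2d()] or numeric vector/matrix with at least two
#'   distinct values.
#' @param n_bins Number of histogram bins over `[min, max]` (default 256,
#'   matching 8-bit convention).
#' @return The threshold, a single number in intensity units.
#' @examples
#' img <- image2d(matrix(c(0, 100), 10, 10), 40)
#' isodata_threshold(img) # 50
#' @export
isodata_threshold <- function(img, n_bins = 256L) {
  v <- as.vector(unclass(img))
  lo <- min(v); hi <- max(v)
  if (lo == hi) abort("degenerate image: all pixels share one value.")
  n_bins <- as.integer(n_bins)
  bw <- (hi - lo) / n_bins
  # bin counts and per-bin mass at bin centres
  bin <- pmin(floor((v - lo) / bw), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  centers <- lo + (seq_len(n_bins) - 0.5) * bw
  csum_n <- cumsum(counts)
  csum_m <- cumsum(counts * centers)
  n_tot <- csum_n[n_bins]; m_tot <- csum_m[n_bins]

  split_of <- function(t) min(max(findInterval(t, centers), 1L), n_bins - 1L)
  intermeans_at <- function(k) {
    # class split after bin k: bins with centre <= t vs above
    n_lo <- csum_n[k]; m_lo <- csum_m[k]
    if (n_lo == 0 || n_lo == n_tot) return(centers[k])
    (m_lo / n_lo + (m_tot - m_lo) / (n_tot - n_lo)) / 2
  }

  # iterate t -> intermeans(t); the change drops below one bin quickly, and
  # the iteration is continued to the discrete fixed point of the split
  # index (a rare 2-cycle resolves to the split whose intermeans moves
  # least)
  k <- split_of(mean(v))
  prev <- -1L
  for (i in 1:1000) {
    t_new <- intermeans_at(k)
    k_new <- split_of(t_new)
    if (k_new == k) return(t_new)
    if (k_new == prev) { # 2-cycle between adjacent splits
      cand <- c(k, k_new)
      moves <- abs(vapply(cand, intermeans_at, numeric(1)) - centers[cand])
      return(intermeans_at(cand[which.min(moves)]))
    }
    prev <- k
    k <- k_new
  }
  intermeans_at(k)
}

#' Binarize an image at a threshold
#'
#' Pixels strictly above the threshold become foreground. The mask records
#' its connectivity convention (8-connected foreground over 4-connected
#' background) and the originating threshold.
#'
#' @param img An [image2d()].
#' @param t Threshold (finite number).
#' @return A `binary_mask`: a logical matrix with `pixel_size_nm`,
#'   `threshold` and `connectivity` attributes.
#' @export
binarize <- function(img, t) {
  if (!is.finite(t)) abort("`t` must be finite.")
  structure(unclass(img) > t,
            pixel_size_nm = pixel_size(img),
            channel = channel_label(img),
            threshold = t,
            connectivity = "8-connected foreground / 4-connected background",
            class = c("binary_mask", "matrix", "array"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (%.1f%%), t = %.4g\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x), attr(x, "threshold")))
  invisible(x)
}

# Two-pass run-based connected-component labeling, 8-connectivity,
# union-find over provisional run labels. Fast in R because it works on
# row runs, not pixels.
label_components <- function(mask, connectivity = 8L) {
  wide <- if (connectivity == 8L) 1L else 0L
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  prev_runs <- NULL # matrix cols: start, end, label
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    if (!any(row)) { prev_runs <- NULL; next }
    rl <- rle(as.vector(row))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    runs <- cbind(start = starts[fg], end = ends[fg], label = 0L)
    for (k in seq_len(nrow(runs))) {
      lab <- 0L
      if (!is.null(prev_runs)) {
        # 8-connectivity widens the overlap window by 1; 4 does not
        touch <- which(prev_runs[, "end"] >= runs[k, "start"] - wide &
                       prev_runs[, "start"] <= runs[k, "end"] + wide)
        for (tt in touch) {
          root <- find_root(prev_runs[tt, "label"])
          if (lab == 0L) {
            lab <- root
          } else {
            ra <- find_root(lab)
            if (ra != root) {
              parent[max(ra, root)] <- min(ra, root)
            }
            lab <- min(ra, root)
          }
        }
      }
      if (lab == 0L) {
        parent <- c(parent, length(parent) + 1L)
        lab <- length(parent)
      }
      runs[k, "label"] <- lab
      labels[r, runs[k, "start"]:runs[k, "end"]] <- lab
    }
    prev_runs <- runs
  }
  if (length(parent) == 0L) return(labels)
  roots <- vapply(seq_along(parent), find_root, integer(1))
  # relabel compactly; final renumbering to raster order happens later
  labels[labels > 0L] <- roots[labels[labels > 0L]]
  labels
}

#' Particle analysis of a binary mask
#'
#' Labels foreground connected components under 8-connectivity, discards
#' components with area outside `[min_area_px, max_area_px]`, and extracts
#' each particle's bare outline: the foreground pixels with at least one
#' background 4-neighbour (the image border counts as background). Labels
#' are `1..K` with no gaps, assigned in raster-scan order (row-major) of
#' each particle's first pixel.
#'
#' @param mask A [binarize()] result (or logical matrix with a
#'   `pixel_size_nm` attribute).
#' @param min_area_px Minimum particle area in pixels (default 4, to
#'   suppress shot-noise specks).
#' @param max_area_px Maximum area (default `Inf`).
#' @return A `particle_set`: list with `labels` (integer matrix, 0 =
#'   background), `outline` (logical matrix of bare-outline pixels) and
#'   `particles`, a tibble with `label`, `area_px`, `area_nm2`, bounding
#'   box columns and list-columns `pixel_idx`, `outline_idx` of linear
#'   matrix indices.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE; m[6:8, 6:8] <- TRUE
#' ps <- analyze_particles(binarize(image2d(m * 1, 40), 0.5))
#' ps$particles[, c("label", "area_px", "n_outline")]
#' @export
analyze_particles <- function(mask, min_area_px = 4L, max_area_px = Inf) {
  pxsz <- attr(mask, "pixel_size_nm") %||% 1
  m <- unclass(mask) > 0
  labels <- label_components(m)

  # bare outline: foreground with a background 4-neighbour (border = background)
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(mm, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- mm[rs[ok_r], cs[ok_c]]
    out
  }
  has_bg_nb <- !shift(m, 1, 0) | !shift(m, -1, 0) |
               !shift(m, 0, 1) | !shift(m, 0, -1)
  outline_all <- m & has_bg_nb

  fg <- which(labels > 0L)
  if (length(fg) == 0L) {
    return(empty_particle_set(labels, outline_all, pxsz, mask,
                              min_area_px, max_area_px))
  }
  lab_fg <- labels[fg]
  areas <- tabulate(lab_fg)
  keep_labs <- which(areas >= min_area_px & areas <= max_area_px)
  if (length(keep_labs) == 0L) {
    labels[] <- 0L
    return(empty_particle_set(labels, outline_all & FALSE, pxsz, mask,
                              min_area_px, max_area_px))
  }
  # raster order of first pixel: which() returns column-major order, but
  # raster scan is row-major — order by (row, col) of each label's first pixel
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  first_key <- vapply(keep_labs, function(l) {
    sel <- lab_fg == l
    min(rows[sel] * (nc + 1) + cols[sel])
  }, numeric(1))
  keep_labs <- keep_labs[order(first_key)]

  new_lab <- integer(max(lab_fg))
  new_lab[keep_labs] <- seq_along(keep_labs)
  relabeled <- matrix(0L, nr, nc)
  sel <- new_lab[lab_fg] > 0L
  sel[is.na(sel)] <- FALSE
  relabeled[fg[sel]] <- new_lab[lab_fg[sel]]
  outline <- outline_all & relabeled > 0L

  particles <- purrr::map(seq_along(keep_labs), function(i) {
    idx <- which(relabeled == i)
    o_idx <- idx[outline[idx]]
    rr <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
    tibble::tibble(
      label = i,
      area_px = length(idx),
      area_nm2 = length(idx) * pxsz^2,
      bbox_row_min = min(rr), bbox_row_max = max(rr),
      bbox_col_min = min(cc), bbox_col_max = max(cc),
      n_outline = length(o_idx),
      pixel_idx = list(idx),
      outline_idx = list(o_idx)
    )
  })
  structure(list(labels = relabeled, outline = outline,
                 particles = dplyr::bind_rows(particles),
                 pixel_size_nm = pxsz, channel = attr(mask, "channel"),
                 source_threshold = attr(mask, "threshold"),
                 min_area_px = min_area_px, max_area_px = max_area_px),
            class = "particle_set")
}

empty_particle_set <- function(labels, outline, pxsz, mask, min_a, max_a) {
  structure(list(labels = labels * 0L, outline = outline,
                 particles = tibble::tibble(
                   label = integer(), area_px = integer(), area_nm2 = numeric(),
                   bbox_row_min = integer(), bbox_row_max = integer(),
                   bbox_col_min = integer(), bbox_col_max = integer(),
                   n_outline = integer(), pixel_idx = list(), outline_idx = list()),
                 pixel_size_nm = pxsz, channel = attr(mask, "channel"),
                 source_threshold = attr(mask, "threshold"),
                 min_area_px = min_a, max_area_px = max_a),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particle(s), %.3g nm/px, area filter [%s, %s] px\n",
              nrow(x$particles), x$pixel_size_nm,
              format(x$min_area_px), format(x$max_area_px)))
  invisible(x)
}

# Fill enclosed holes: background is 4-connected, so any background
# component that never touches the image border lies inside a particle and
# is promoted to foreground. Band borders then follow each particle's bare
# (outer) outline, so interior noise dropouts cannot split a band.
fill_holes <- function(m) {
  bg <- label_components(!m, connectivity = 4L)
  border_labs <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labs <- border_labs[border_labs > 0L]
  m | (bg > 0L & !(bg %in% border_labs))
}

# The filtered, hole-filled mask implied by a particle set (used for line
# scanning).
particle_mask <- function(ps) {
  structure(fill_holes(ps$labels > 0L),
            pixel_size_nm = ps$pixel_size_nm,
            channel = ps$channel,
            threshold = ps$source_threshold,
            connectivity = "8-connected foreground / 4-connected background",
            class = c("binary_mask", "matrix", "array"))
}

#' Run the three-step pre-processing pipeline on one channel
#'
#' Background subtraction, IsoData binarization and particle analysis in
#' order, returning every intermediate plus a provenance log of the
#' data-dependent decisions (subtracted background, threshold, area
#' filter, particle count).
#'
#' @param img An [image2d()].
#' @param roi Background ROI as in [subtract_background()].
#' @param n_bins Histogram bins for [isodata_threshold()].
#' @param min_area_px,max_area_px Area filter for [analyze_particles()].
#' @return A `preprocessed_channel` list: `subtracted`, `threshold`,
#'   `mask` (raw binarization), `particles`, `clean_mask` (mask restricted
#'   to retained particles) and `log`.
#' @export
preprocess_channel <- function(img, roi = "auto", n_bins = 256L,
                               min_area_px = 4L, max_area_px = Inf) {
  sub <- subtract_background(img, roi)
  t <- isodata_threshold(sub, n_bins)
  mask <- binarize(sub, t)
  ps <- analyze_particles(mask, min_area_px, max_area_px)
  log <- list(
    channel = channel_label(img),
    background = attr(sub, "provenance")$background,
    threshold = t,
    n_bins = n_bins,
    min_area_px = min_area_px,
    max_area_px = max_area_px,
    n_particles = nrow(ps$particles)
  )
  structure(list(subtracted = sub, threshold = t, mask = mask,
                 particles = ps, clean_mask = particle_mask(ps), log = log),
            class = "preprocessed_channel")
}

#' @export
print.preprocessed_channel <- function(x, ...) {
  cat(sprintf(
    "<preprocessed_channel> '%s': background %.4g subtracted, t = %.4g, %d particle(s)\n",
    x$log$channel, x$log$background$mean, x$threshold, x$log$n_particles))
  invisible(x)
}
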