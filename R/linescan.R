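#' A straight line-scan path in pixel coordinates
#'
#' @param start,end Numeric `c(x, y)` endpoints in continuous, 0-based
#'   pixel coordinates (sub-pixel values allowed).
#' @param sample_step_px Sample spacing along the path, in pixels
#'   (default 0.25: sub-pixel crossing precision comes from fine sampling).
#' @return A `linescan_path`.
#' @export
line_path <- function(start, end, sample_step_px = 0.25) {
  if (length(start) != 2 || length(end) != 2) abort("endpoints must be c(x, y).")
  len <- sqrt(sum((end - start)^2))
  if (len <= 0) abort("path must have positive length.")
  if (sample_step_px <= 0) abort("`sample_step_px` must be > 0.")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 length_px = len, sample_step_px = sample_step_px),
            class = "linescan_path")
}

#' @export
print.linescan_path <- function(x, ...) {
  cat(sprintf("<linescan_path> (%.2f, %.2f) -> (%.2f, %.2f), %.2f px, step %.3g px\n",
              x$start[1], x$start[2], x$end[1], x$end[2],
              x$length_px, x$sample_step_px))
  invisible(x)
}

bilinear_sample <- function(m, x, y) {
  # pixel (i, j) centre at (j - 0.5, i - 0.5) in 0-based continuous coords
  # (1-based matrix indices); clamp to centre grid at borders
  nr <- nrow(m); nc <- ncol(m)
  gx <- pmin(pmax(x - 0.5, 0), nc - 1)
  gy <- pmin(pmax(y - 0.5, 0), nr - 1)
  j0 <- pmin(floor(gx), nc - 2); i0 <- pmin(floor(gy), nr - 2)
  if (nc == 1) j0 <- 0
  if (nr == 1) i0 <- 0
  fx <- gx - j0; fy <- gy - i0
  j1 <- pmin(j0 + 1, nc - 1); i1 <- pmin(i0 + 1, nr - 1)
  v00 <- m[cbind(i0 + 1, j0 + 1)]; v01 <- m[cbind(i0 + 1, j1 + 1)]
  v10 <- m[cbind(i1 + 1, j0 + 1)]; v11 <- m[cbind(i1 + 1, j1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

nearest_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  j <- pmin(pmax(floor(x), 0), nc - 1)
  i <- pmin(pmax(floor(y), 0), nr - 1)
  m[cbind(i + 1, j + 1)]
}

#' Sample an intensity or binary profile along a path
#'
#' Samples at uniform arc-length steps from the path start: bilinear
#' interpolation for intensity images (so a sample at a pixel centre equals
#' the pixel value) and nearest-neighbour lookup for binary masks (no
#' sub-threshold values are invented; sub-pixel precision comes from the
#' fine sample step). Positions are arc length from the path start,
#' converted to nm via the image's pixel size.
#'
#' @param img An [image2d()] or `binary_mask`.
#' @param path A [line_path()], fully inside the image.
#' @return A `scan_profile` tibble: `position_nm`, `value`, with
#'   attributes `source` (`"image"` or `"mask"`), `channel`,
#'   `step_nm` and `path`.
#' @export
extract_profile <- function(img, path) {
  nr <- nrow(img); nc <- ncol(img)
  for (pt in list(path$start, path$end)) {
    if (pt[1] < 0 || pt[1] > nc || pt[2] < 0 || pt[2] > nr) {
      abort(sprintf("path endpoint (%.2f, %.2f) lies outside the %d x %d image.",
                    pt[1], pt[2], nr, nc))
    }
  }
  n <- floor(path$length_px / path$sample_step_px) + 1L
  s <- (seq_len(n) - 1L) * path$sample_step_px
  dir <- (path$end - path$start) / path$length_px
  xs <- path$start[1] + s * dir[1]
  ys <- path$start[2] + s * dir[2]
  pxsz <- attr(img, "pixel_size_nm")
  is_mask <- inherits(img, "binary_mask")
  vals <- if (is_mask) {
    as.numeric(nearest_sample(unclass(img) * 1, xs, ys))
  } else {
    bilinear_sample(unclass(img), xs, ys)
  }
  out <- tibble::tibble(position_nm = s * pxsz, value = vals)
  structure(out,
            source = if (is_mask) "mask" else "image",
            channel = attr(img, "channel"),
            step_nm = path$sample_step_px * pxsz,
            pixel_size_nm = pxsz,
            path = path,
            class = c("scan_profile", class(out)))
}

#' Detect band border crossings on a binary profile
#'
#' On a 0/1 profile, a 0 to 1 transition between consecutive samples
#' yields an `enter` event at the midpoint of the two sample positions and
#' a 1 to 0 transition an `exit` event. A profile that starts (ends) inside
#' a band gets a synthetic leading enter (trailing exit) flagged as not
#' real, so downstream bands truncated by the scan ends can be excluded.
#'
#' @param profile A binary-valued [extract_profile()] result.
#' @return A tibble of events: `position_nm`, `type` (`"enter"`/`"exit"`),
#'   `real` (FALSE for synthetic boundary events).
#' @export
detect_crossings <- function(profile) {
  v <- profile$value
  if (!all(v %in% c(0, 1))) abort("`profile` must be binary-valued (0/1).")
  pos <- profile$position_nm
  n <- length(v)
  if (n < 2 || all(v == 0)) {
    if (n >= 1 && all(v == 1)) {
      return(tibble::tibble(position_nm = c(pos[1], pos[n]),
                            type = c("enter", "exit"),
                            real = c(FALSE, FALSE)))
    }
    return(tibble::tibble(position_nm = numeric(), type = character(),
                          real = logical()))
  }
  d <- diff(v)
  up <- which(d == 1)    # enter between sample i and i+1
  dn <- which(d == -1)
  ev <- tibble::tibble(
    position_nm = c((pos[up] + pos[up + 1]) / 2, (pos[dn] + pos[dn + 1]) / 2),
    type = c(rep("enter", length(up)), rep("exit", length(dn))),
    real = TRUE)
  if (v[1] == 1) {
    ev <- dplyr::bind_rows(
      tibble::tibble(position_nm = pos[1], type = "enter", real = FALSE), ev)
  }
  if (v[n] == 1) {
    ev <- dplyr::bind_rows(
      ev, tibble::tibble(position_nm = pos[n], type = "exit", real = FALSE))
  }
  dplyr::arrange(ev, .data$position_nm, dplyr::desc(.data$type == "enter"))
}

#' Pair crossing events into bands
#'
#' Pairs each `enter` with the following `exit`; a band is `complete` only
#' if both borders are real transitions (not scan-end truncations).
#' Incomplete bands are kept but flagged, so width and centre statistics
#' can exclude them.
#'
#' @param events A [detect_crossings()] tibble.
#' @param channel Channel label to stamp on the bands.
#' @return A `band` tibble: `channel`, `enter_nm`, `exit_nm`, `center_nm`,
#'   `width_nm`, `complete`, ordered by centre.
#' @export
bands_from_crossings <- function(events, channel = NA_character_) {
  if (nrow(events) == 0) return(empty_bands(channel))
  tp <- events$type
  if (length(tp) %% 2 != 0 ||
      !all(tp[seq(1, length(tp), by = 2)] == "enter") ||
      !all(tp[seq(2, length(tp), by = 2)] == "exit")) {
    abort("internal error: crossing events do not alternate enter/exit.")
  }
  en <- events[tp == "enter", ]
  ex <- events[tp == "exit", ]
  out <- tibble::tibble(
    channel = channel,
    enter_nm = en$position_nm,
    exit_nm = ex$position_nm,
    center_nm = (en$position_nm + ex$position_nm) / 2,
    width_nm = ex$position_nm - en$position_nm,
    complete = en$real & ex$real)
  dplyr::arrange(out, .data$center_nm)
}

empty_bands <- function(channel = NA_character_) {
  tibble::tibble(channel = character(), enter_nm = numeric(),
                 exit_nm = numeric(), center_nm = numeric(),
                 width_nm = numeric(), complete = logical())
}

#' Bands along one scan
#'
#' For a `binary_mask`, the composition of [extract_profile()],
#' [detect_crossings()] and [bands_from_crossings()]. For a
#' `particle_set`, bands are particle-aware: the scan samples the particle
#' label map and each particle crossed yields exactly one band, from the
#' first entry into that particle to the last exit — the bare-outline
#' (outer border) reading of a particle's reference points, which keeps
#' interior noise dropouts or attached specks from splitting a band.
#'
#' @param x A `binary_mask` or [analyze_particles()] result.
#' @param path A [line_path()].
#' @return A band tibble as in [bands_from_crossings()].
#' @export
scan_bands <- function(x, path) {
  if (inherits(x, "particle_set")) return(scan_particle_bands(x, path))
  prof <- extract_profile(x, path)
  bands_from_crossings(detect_crossings(prof), channel = attr(prof, "channel"))
}

# Bands from the particle label map along a path: runs of one label are
# read off the profile (nearest-neighbour), and consecutive runs of the
# same particle are bridged when the gap between them is small (noise
# notches open to the border, <= merge_gap_px), while larger gaps keep
# genuinely distinct lobes of a noise-bridged particle apart. Enter/exit
# land at run-boundary midpoints; bands touching a profile end are
# incomplete.
scan_particle_bands <- function(ps, path, merge_gap_px = 1.5) {
  lab_img <- structure(ps$labels,
                       pixel_size_nm = ps$pixel_size_nm,
                       channel = ps$channel,
                       class = c("binary_mask", "matrix", "array"))
  # reuse the mask sampler on the integer label map (nearest-neighbour)
  prof <- extract_profile(lab_img, path)
  lv <- prof$value
  pos <- prof$position_nm
  n <- length(lv)
  r <- rle(lv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  fg <- which(r$values > 0)
  if (length(fg) == 0) return(empty_bands(ps$channel))
  runs <- tibble::tibble(
    label = r$values[fg],
    enter_nm = ifelse(starts[fg] == 1L, pos[1],
                      (pos[pmax(starts[fg] - 1L, 1L)] + pos[starts[fg]]) / 2),
    exit_nm = ifelse(ends[fg] == n, pos[n],
                     (pos[ends[fg]] + pos[pmin(ends[fg] + 1L, n)]) / 2),
    enter_real = starts[fg] != 1L,
    exit_real = ends[fg] != n)
  gap_nm <- merge_gap_px * ps$pixel_size_nm
  bands <- list()
  cur <- runs[1, ]
  for (k in seq_len(nrow(runs))[-1]) {
    nxt <- runs[k, ]
    if (nxt$label == cur$label && nxt$enter_nm - cur$exit_nm <= gap_nm) {
      cur$exit_nm <- nxt$exit_nm
      cur$exit_real <- nxt$exit_real
    } else {
      bands[[length(bands) + 1]] <- cur
      cur <- nxt
    }
  }
  bands[[length(bands) + 1]] <- cur
  merged <- dplyr::bind_rows(bands)
  out <- tibble::tibble(
    channel = ps$channel %||% NA_character_,
    enter_nm = merged$enter_nm,
    exit_nm = merged$exit_nm,
    center_nm = (merged$enter_nm + merged$exit_nm) / 2,
    width_nm = merged$exit_nm - merged$enter_nm,
    complete = merged$enter_real & merged$exit_real)
  dplyr::arrange(out, .data$center_nm)
}

# Dominant orientation of the striation pattern from the 2D power
# spectrum: angle (deg, in [0, 180)) of the strongest non-DC peak, ties
# broken toward lower spatial frequency.
striation_orientation <- function(img) {
  m <- unclass(img) - mean(img)
  nr <- nrow(m); nc <- ncol(m)
  spec <- Mod(fft(m))^2
  fy <- ifelse(seq_len(nr) - 1 <= nr / 2, seq_len(nr) - 1, seq_len(nr) - 1 - nr) / nr
  fx <- ifelse(seq_len(nc) - 1 <= nc / 2, seq_len(nc) - 1, seq_len(nc) - 1 - nc) / nc
  fyg <- matrix(fy, nr, nc)
  fxg <- matrix(fx, nr, nc, byrow = TRUE)
  fr <- sqrt(fxg^2 + fyg^2)
  cand <- fr > 1e-9
  if (!any(cand)) abort("no striation detected: image has no non-DC power.")
  pk <- spec[cand]
  # under pure noise the periodogram bins are ~exponential with rate
  # 1/lambda, lambda = median/ln 2, and the maximum of n bins concentrates
  # near lambda*ln(n); demand a peak far beyond that extreme-value bound
  lambda <- stats::median(pk) / log(2)
  best <- max(pk)
  if (best < lambda * (log(length(pk)) + 10)) {
    abort("no striation detected: no spectral peak above the noise floor.")
  }
  hits <- which(cand & spec >= best * (1 - 1e-12), arr.ind = TRUE)
  # tie-break toward the lower spatial frequency
  hit_fr <- fr[hits]
  h <- hits[which.min(hit_fr), , drop = TRUE]
  ang <- atan2(fyg[h[1], h[2]], fxg[h[1], h[2]]) * 180 / pi
  ang %% 180
}

#' Automatically place parallel line-scan paths across the striations
#'
#' Estimates the stripe-normal direction from the dominant peak of the 2D
#' power spectrum, then places `n_scans` parallel paths along that normal,
#' spanning the field, pairwise separated by at least `min_separation_px`
#' perpendicular to the scan direction. Deterministic for a fixed seed
#' (the seed only jitters the perpendicular offsets within their slots).
#'
#' @param img An [image2d()] or `binary_mask` containing detectable stripes.
#' @param n_scans Number of paths.
#' @param min_separation_px Minimum pairwise perpendicular separation.
#' @param seed Integer seed.
#' @param sample_step_px Sample step for the returned paths.
#' @param margin_px Inset from the image border along the scan direction.
#' @return A list of [line_path()] objects.
#' @export
auto_paths <- function(img, n_scans = 5L, min_separation_px = 2,
                       seed = 1L, sample_step_px = 0.25, margin_px = 1) {
  ang <- striation_orientation(img)
  theta <- ang * pi / 180
  dir <- c(cos(theta), sin(theta))        # scan direction = stripe normal
  perp <- c(-dir[2], dir[1])
  nr <- nrow(img); nc <- ncol(img)
  centre <- c(nc / 2, nr / 2)

  # usable perpendicular extent: 80% of the rectangle's projection onto perp
  half_perp <- (abs(perp[1]) * nc + abs(perp[2]) * nr) / 2
  usable <- 0.8 * 2 * half_perp
  if ((n_scans - 1) * min_separation_px > usable) {
    abort("cannot place that many non-overlapping scans in this field.")
  }
  slot <- usable / n_scans
  jitter_amp <- max(0, (slot - min_separation_px) / 2)
  offs <- withr::with_seed(seed, {
    base <- (seq_len(n_scans) - (n_scans + 1) / 2) * slot
    base + stats::runif(n_scans, -jitter_amp, jitter_amp) * 0.5
  })

  # clip a centre + t*dir line to the image rectangle (with margin)
  clip_line <- function(p0) {
    t_lo <- -Inf; t_hi <- Inf
    for (k in 1:2) {
      lim <- if (k == 1) c(margin_px, nc - margin_px) else c(margin_px, nr - margin_px)
      if (abs(dir[k]) < 1e-12) {
        if (p0[k] < lim[1] || p0[k] > lim[2]) return(NULL)
      } else {
        tt <- sort((lim - p0[k]) / dir[k])
        t_lo <- max(t_lo, tt[1]); t_hi <- min(t_hi, tt[2])
      }
    }
    if (t_hi <= t_lo) return(NULL)
    line_path(p0 + t_lo * dir, p0 + t_hi * dir, sample_step_px)
  }
  paths <- purrr::compact(purrr::map(offs, function(o) clip_line(centre + o * perp)))
  if (length(paths) < n_scans) {
    abort("cannot place that many non-overlapping scans in this field.")
  }
  paths
}
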