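#' Sarcomere lengths from ordered Z-disc bands
#'
#' The distance between neighbouring Z-discs, measured centre-to-centre on
#' the Z-disc marker bands of one scan. Incomplete (scan-truncated) bands
#' are excluded before differencing.
#'
#' @param zbands A band tibble ([bands_from_crossings()]).
#' @return Numeric vector of consecutive centre-to-centre distances (nm);
#'   empty when fewer than two complete bands are available.
#' @examples
#' b <- tibble::tibble(center_nm = c(250, 2550, 4850), complete = TRUE)
#' sarcomere_lengths(b) # 2300 2300
#' @export
sarcomere_lengths <- function(zbands) {
  centers <- sort(zbands$center_nm[zbands$complete %||% TRUE])
  if (length(centers) < 2) return(numeric(0))
  diff(centers)
}

#' Z-disc widths from bands
#'
#' Band widths (nm) of the complete Z-disc bands; incomplete bands are
#' excluded.
#'
#' @param zbands A band tibble.
#' @return Numeric vector of widths (nm).
#' @export
zdisc_widths <- function(zbands) {
  zbands$width_nm[zbands$complete %||% TRUE]
}

#' Inter-epitope distances along one scan
#'
#' Two pairing modes for distances between labelled epitope bands sampled
#' on the same scan path:
#' * `"flanking_pair"` pairs consecutive same-channel bands in `bands_a`
#'   that straddle a Z-disc centre (from `zbands`) — the geometry of the
#'   titin N2A epitope measured across the Z-disc.
#' * `"nearest_cross_channel"` pairs each band in `bands_a` with its
#'   nearest neighbour in `bands_b` within `cutoff_nm` — e.g. N2A to PEVK.
#'   An exact tie between two candidates is broken deterministically
#'   toward the lower position and flagged in `tie`.
#'
#' @param bands_a,bands_b Band tibbles from the same scan path
#'   (`bands_b` only for `nearest_cross_channel`).
#' @param mode `"flanking_pair"` or `"nearest_cross_channel"`.
#' @param zbands Z-disc bands of the same scan (for `flanking_pair`).
#' @param cutoff_nm Maximum pairing distance for `nearest_cross_channel`
#'   (default 1200, half a typical sarcomere length).
#' @param label Pair label stamped on the output.
#' @return A tibble: `pair`, `position_a_nm`, `position_b_nm`,
#'   `distance_nm`, `tie`.
#' @export
epitope_distances <- function(bands_a, bands_b = NULL,
                              mode = c("flanking_pair", "nearest_cross_channel"),
                              zbands = NULL, cutoff_nm = 1200,
                              label = NULL) {
  mode <- match.arg(mode)
  empty <- tibble::tibble(pair = character(), position_a_nm = numeric(),
                          position_b_nm = numeric(), distance_nm = numeric(),
                          tie = logical())
  ca <- sort(bands_a$center_nm[bands_a$complete %||% TRUE])
  if (mode == "flanking_pair") {
    if (is.null(zbands)) abort("`zbands` is required for flanking_pair mode.")
    if (length(ca) < 2) return(empty)
    zc <- zbands$center_nm[zbands$complete %||% TRUE]
    lab <- label %||% paste0(bands_a$channel[1], "-", bands_a$channel[1])
    lo <- ca[-length(ca)]; hi <- ca[-1]
    straddles <- vapply(seq_along(lo), function(i) {
      any(zc > lo[i] & zc < hi[i])
    }, logical(1))
    if (!any(straddles)) return(empty)
    tibble::tibble(pair = lab, position_a_nm = lo[straddles],
                   position_b_nm = hi[straddles],
                   distance_nm = hi[straddles] - lo[straddles], tie = FALSE)
  } else {
    if (is.null(bands_b)) abort("`bands_b` is required for nearest_cross_channel mode.")
    cb <- sort(bands_b$center_nm[bands_b$complete %||% TRUE])
    if (length(ca) == 0 || length(cb) == 0) return(empty)
    lab <- label %||% paste0(bands_a$channel[1], "-", bands_b$channel[1])
    rows <- purrr::map(ca, function(a) {
      d <- abs(cb - a)
      dmin <- min(d)
      if (dmin > cutoff_nm) return(NULL)
      hits <- which(d <= dmin + 1e-9)
      tie <- length(hits) > 1
      b <- cb[hits[1]] # lower position wins the tie
      tibble::tibble(pair = lab, position_a_nm = a, position_b_nm = b,
                     distance_nm = abs(b - a), tie = tie)
    })
    out <- dplyr::bind_rows(purrr::compact(rows))
    if (nrow(out) == 0) empty else out
  }
}

#' Merge band fragments that violate a minimum separation
#'
#' Treats bands whose consecutive centres lie closer than `min_sep_nm` as
#' fragments of one physical band and fuses them (first entry to last
#' exit). For Z-disc bands the default 1000 nm is the same physiological
#' lower bound on sarcomere length that delimits the FFT period search
#' band: two genuine Z-discs can never be closer, so any closer pair is a
#' split band (e.g. a noise notch through a stripe at the scan row).
#'
#' @param bands A band tibble, ordered or not.
#' @param min_sep_nm Minimum credible centre-to-centre separation.
#' @return The merged band tibble, ordered by centre.
#' @export
merge_close_bands <- function(bands, min_sep_nm = 1000) {
  if (nrow(bands) < 2) return(bands)
  b <- dplyr::arrange(bands, .data$center_nm)
  out <- list()
  cur <- b[1, ]
  for (k in 2:nrow(b)) {
    nxt <- b[k, ]
    if (nxt$center_nm - cur$center_nm < min_sep_nm) {
      cur$exit_nm <- max(cur$exit_nm, nxt$exit_nm)
      cur$enter_nm <- min(cur$enter_nm, nxt$enter_nm)
      cur$center_nm <- (cur$enter_nm + cur$exit_nm) / 2
      cur$width_nm <- cur$exit_nm - cur$enter_nm
      cur$complete <- cur$complete && nxt$complete
    } else {
      out[[length(out) + 1]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1]] <- cur
  dplyr::bind_rows(out)
}

#' Dominant spatial period of an intensity profile by FFT
#'
#' The comparator against which the line-scan estimator is judged: the
#' profile is detrended (mean subtracted), Hann-windowed, zero-padded 4x,
#' and the magnitude spectrum's highest peak within the period band is
#' refined by parabolic interpolation on the log magnitude; the estimate
#' is the reciprocal of the refined peak frequency.
#'
#' @param profile An intensity [extract_profile()] result (uniformly
#'   sampled positions).
#' @param period_band_nm Search band for the period, `c(min, max)` in nm
#'   (default 1000-5000, bracketing physiological sarcomere lengths).
#' @param zero_pad Zero-padding factor.
#' @param min_peak_log_margin The squared peak magnitude must exceed the
#'   extreme-value bound for pure noise, `lambda * (log(m) +
#'   min_peak_log_margin)` with `m` in-band bins and `lambda` the
#'   exponential scale fitted from the in-band median power; otherwise the
#'   profile is declared aperiodic.
#' @param refine Apply sub-bin parabolic peak interpolation (default
#'   `TRUE`). With `refine = FALSE` and `zero_pad = 1` the estimate is the
#'   raw spectral peak bin, the behaviour of the plain FFT readout this
#'   estimator is usually compared against.
#' @return The period estimate in nm (a single number).
#' @export
fft_period <- function(profile, period_band_nm = c(1000, 5000),
                       zero_pad = 4L, min_peak_log_margin = 8, refine = TRUE) {
  v <- profile$value
  pos <- profile$position_nm
  n <- length(v)
  dx <- (pos[n] - pos[1]) / (n - 1)
  if (n * dx < 3 * period_band_nm[2]) {
    abort("profile too short: need at least 3 periods of the band maximum.")
  }
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))) # Hann
  x <- (v - mean(v)) * w
  nfft <- zero_pad * n
  mag <- Mod(fft(c(x, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) / (nfft * dx)
  in_band <- freq >= 1 / period_band_nm[2] & freq <= 1 / period_band_nm[1]
  if (!any(in_band)) abort("no dominant period: search band is empty at this sampling.")
  band_idx <- which(in_band)
  pk_rel <- which.max(mag[band_idx])
  pk <- band_idx[pk_rel]
  pw <- mag[band_idx]^2
  lambda <- stats::median(pw) / log(2)
  if (mag[pk]^2 < lambda * (log(length(pw)) + min_peak_log_margin)) {
    abort("no dominant period: peak does not exceed the spectral noise floor.")
  }
  # parabolic interpolation on log magnitude around the peak bin
  if (refine && pk > 1 && pk < length(mag) && mag[pk - 1] > 0 && mag[pk + 1] > 0) {
    a <- log(mag[pk - 1]); b <- log(mag[pk]); c <- log(mag[pk + 1])
    denom <- a - 2 * b + c
    delta <- if (abs(denom) > 1e-12) 0.5 * (a - c) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
  } else {
    delta <- 0
  }
  f_star <- freq[pk] + delta / (nfft * dx)
  1 / f_star
}

#' Measure one simulated or real multi-channel image end-to-end
#'
#' Runs the full pipeline on every channel of a multi-channel image:
#' pre-processing ([preprocess_channel()]), automatic or user-supplied
#' scan paths, band extraction on the particle-filtered masks, and the
#' per-scan measurands (sarcomere lengths from the Z-disc channel, Z-disc
#' widths, inter-epitope distances per the channel roles).
#'
#' @param mci A [multichannel_image()].
#' @param roles Named character vector mapping channel labels to roles:
#'   exactly one `"zdisc"`, any number of `"epitope"` channels. Default:
#'   channel named `"zdisc"` is the Z-disc, all others epitopes.
#' @param paths A list of [line_path()], or `NULL` to place
#'   `n_scans` paths automatically on the Z-disc channel.
#' @param n_scans,seed,min_separation_px Passed to [auto_paths()] when
#'   `paths` is `NULL`.
#' @param roi Background ROI per [subtract_background()].
#' @param min_area_px Particle area filter.
#' @param epitope_pairs A tibble describing which distances to report,
#'   with columns `a`, `b`, `mode` (see [epitope_distances()]); default
#'   pairs every epitope channel with itself (`flanking_pair`) and
#'   consecutive epitope channels with each other
#'   (`nearest_cross_channel`).
#' @param sample_step_px Line-scan sample step.
#' @param min_zband_separation_nm Z-disc bands closer than this are fused
#'   as fragments of one band (see [merge_close_bands()]).
#' @return A `scan_measures` list: `bands` (tibble over all channels and
#'   scans, with `scan` id and absolute positions), `measures` (long
#'   tibble: `scan`, `measure`, `pair`, `value_nm`), `logs` (per-channel
#'   provenance), `paths`.
#' @export
measure_image <- function(mci, roles = NULL, paths = NULL, n_scans = 5L,
                          seed = 1L, min_separation_px = 2, roi = "auto",
                          min_area_px = 4L, epitope_pairs = NULL,
                          sample_step_px = 0.25,
                          min_zband_separation_nm = 1000) {
  labs <- names(mci$channels)
  if (is.null(roles)) {
    if (!"zdisc" %in% labs) {
      abort("no channel labelled 'zdisc'; supply `roles` explicitly.")
    }
    roles <- stats::setNames(ifelse(labs == "zdisc", "zdisc", "epitope"), labs)
  }
  zlab <- names(roles)[roles == "zdisc"]
  if (length(zlab) != 1) abort("exactly one channel must have role 'zdisc'.")
  epi_labs <- names(roles)[roles == "epitope"]

  pre <- purrr::map(mci$channels[c(zlab, epi_labs)], preprocess_channel,
                    roi = roi, min_area_px = min_area_px)
  if (is.null(paths)) {
    paths <- auto_paths(pre[[zlab]]$clean_mask, n_scans = n_scans,
                        min_separation_px = min_separation_px, seed = seed,
                        sample_step_px = sample_step_px)
  }

  pxsz <- pixel_size(mci$channels[[1]])
  all_bands <- purrr::imap(pre, function(ch, lab) {
    purrr::imap(paths, function(p, i) {
      b <- scan_bands(ch$particles, p)
      if (lab == zlab) b <- merge_close_bands(b, min_zband_separation_nm)
      if (nrow(b) == 0) return(dplyr::mutate(b, scan = integer()))
      dir <- (p$end - p$start) / p$length_px
      offset_nm <- sum(p$start * dir) * pxsz
      dplyr::mutate(b, scan = i,
                    center_abs_nm = .data$center_nm + offset_nm)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  per_scan <- purrr::map(seq_along(paths), function(i) {
    sb <- dplyr::filter(all_bands, .data$scan == i)
    zb <- dplyr::filter(sb, .data$channel == zlab)
    rows <- list(
      tibble::tibble(scan = i, measure = "length", pair = NA_character_,
                     value_nm = sarcomere_lengths(zb)),
      tibble::tibble(scan = i, measure = "width", pair = NA_character_,
                     value_nm = zdisc_widths(zb)))
    pairs <- epitope_pairs %||% default_epitope_pairs(epi_labs)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      prow <- purrr::pmap(pairs, function(a, b, mode) {
        ba <- dplyr::filter(sb, .data$channel == a)
        bb <- if (!is.na(b)) dplyr::filter(sb, .data$channel == b) else NULL
        d <- epitope_distances(ba, bb, mode = mode, zbands = zb)
        tibble::tibble(scan = i, measure = "epitope_distance",
                       pair = if (nrow(d)) d$pair else character(),
                       value_nm = d$distance_nm)
      })
      rows <- c(rows, prow)
    }
    dplyr::bind_rows(rows)
  }) |> dplyr::bind_rows()

  structure(list(bands = all_bands, measures = per_scan,
                 logs = purrr::map(pre, "log"), paths = paths,
                 roles = roles),
            class = "scan_measures")
}

default_epitope_pairs <- function(epi_labs) {
  if (length(epi_labs) == 0) return(NULL)
  self <- tibble::tibble(a = epi_labs, b = NA_character_, mode = "flanking_pair")
  cross <- if (length(epi_labs) >= 2) {
    tibble::tibble(a = epi_labs[-length(epi_labs)], b = epi_labs[-1],
                   mode = "nearest_cross_channel")
  }
  dplyr::bind_rows(self, cross)
}

#' @export
print.scan_measures <- function(x, ...) {
  cat(sprintf("<scan_measures> %d scan(s), %d band(s), %d measurement(s)\n",
              length(x$paths), nrow(x$bands), nrow(x$measures)))
  smry <- dplyr::summarise(
    dplyr::group_by(x$measures, .data$measure, .data$pair),
    n = dplyr::n(), mean_nm = mean(.data$value_nm), .groups = "drop")
  print(smry)
  invisible(x)
}
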