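# Independent brute-force oracles, deliberately implemented with different
# algorithms than the package code they check.

# Exhaustive IsoData oracle: quantize values to the operation's 256-bin
# histogram (binning is part of the contract), then scan every candidate
# threshold (bin centre) and return those satisfying the intermeans
# fixed-point condition: (mean below + mean above)/2 lands back within
# half a bin of the candidate. Exhaustive enumeration, no iteration.
isodata_oracle <- function(v, n_bins = 256L) {
  v <- as.vector(v)
  lo <- min(v); hi <- max(v)
  bw <- (hi - lo) / n_bins
  vq <- lo + (pmin(floor((v - lo) / bw), n_bins - 1) + 0.5) * bw
  centers <- lo + (seq_len(n_bins) - 0.5) * bw
  fixed <- c()
  for (k in seq_len(n_bins - 1L)) {
    t <- centers[k]
    below <- vq[vq <= t + 1e-9]; above <- vq[vq > t + 1e-9]
    if (length(below) == 0 || length(above) == 0) next
    t_next <- (mean(below) + mean(above)) / 2
    # fixed point: the intermeans lands back on the same candidate split
    # (candidate k owns the half-open interval [centers[k], centers[k+1]))
    if (t_next >= t - 1e-12 && t_next < centers[k + 1L] - 1e-12) {
      fixed <- c(fixed, t_next)
    }
  }
  fixed
}

# Recursive flood-fill labeling oracle (stack-based DFS, pixel at a time),
# 8-connectivity.
floodfill_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    labels[i, j] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && labels[ii, jj] == 0L) {
          labels[ii, jj] <- cur
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  labels
}

# Same labeling up to a permutation of label values?
same_partition <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  if (!any(fg)) return(TRUE)
  key <- paste(a[fg], b[fg])
  map_ab <- unique(cbind(a[fg], b[fg]))
  !anyDuplicated(map_ab[, 1]) && !anyDuplicated(map_ab[, 2])
}

# 1-D numeric oracle for the measured width of a thresholded, blurred
# top-hat band: analytic Gaussian-blurred top-hats (error-function
# integrals, no discrete convolution) for the given band centres over the
# given field, its own intermeans threshold iterated on the raw values,
# width of the above-threshold set. With `pixel_nm` set, the profile is
# first averaged over pixel footprints so the oracle carries the same
# sampling quantization as a pixelated image; widths are then per-band
# pixel-run extents. Returns the mean width over complete bands.
blurred_tophat_width_oracle <- function(width_nm, sigma_nm,
                                        centers_nm = 1200,
                                        field_nm = 2400,
                                        du = 0.25, pixel_nm = NULL) {
  band_profile <- function(u) {
    v <- 0
    for (c0 in centers_nm) {
      v <- v + if (sigma_nm > 0) {
        pnorm((c0 + width_nm / 2 - u) / sigma_nm) -
          pnorm((c0 - width_nm / 2 - u) / sigma_nm)
      } else {
        as.numeric(abs(u - c0) < width_nm / 2)
      }
    }
    v
  }
  if (is.null(pixel_nm)) {
    u <- seq(du / 2, field_nm, by = du)
    v <- band_profile(u)
    step <- du
  } else {
    n_px <- floor(field_nm / pixel_nm)
    sub <- 20
    uu <- rep((seq_len(n_px) - 1) * pixel_nm, each = sub) +
      (seq_len(sub) - 0.5) / sub * pixel_nm
    v <- colMeans(matrix(band_profile(uu), sub))
    step <- pixel_nm
  }
  t <- mean(v)
  for (i in 1:500) {
    t_new <- (mean(v[v <= t]) + mean(v[v > t])) / 2
    if (abs(t_new - t) < 1e-10) break
    t <- t_new
  }
  fg <- v > t
  r <- rle(fg)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  keep <- r$values & starts > 1 & ends < length(v)
  if (!any(keep)) return(NA_real_)
  mean(r$lengths[keep]) * step
}

# Least-squares Gaussian FWHM of a 1-D response (for PSF checks).
fit_fwhm_px <- function(y) {
  x <- seq_along(y)
  mu0 <- sum(x * y) / sum(y)
  s0 <- sqrt(sum((x - mu0)^2 * y) / sum(y))
  fit <- stats::nls(y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
                    start = list(a = max(y), mu = mu0, s = s0))
  unname(coef(fit)["s"]) * 2 * sqrt(2 * log(2))
}
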