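# Filtered back-projection.

#' FBP filter specification
#'
#' @param window ramp window: \code{"ram-lak"} (pure ramp), \code{"hann"} or
#'   \code{"cosine"}.
#' @param cutoff cutoff frequency as a fraction of Nyquist, in (0, 1].
#' @return a \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(window = c("ram-lak", "hann", "cosine"), cutoff = 1) {
  new("FilterSpec", window = match.arg(window), cutoff = as.numeric(cutoff))
}

#' Frequency response of the ramp filter
#'
#' The filter is constructed directly in the frequency domain: \code{|f|}
#' (cycles per detector sample) times the window, zero above
#' \code{cutoff * Nyquist}.  The DC gain is exactly zero, so filtering a
#' constant detector row yields a zero-mean output.
#'
#' @param filt a \linkS4class{FilterSpec}.
#' @param nfft FFT length.
#' @return numeric vector of length \code{nfft}: the multiplier applied to
#'   the discrete spectrum of each (zero-padded) detector row.
#' @export
rampFrequencyResponse <- function(filt, nfft) {
  k <- seq_len(nfft) - 1
  f <- ifelse(k <= nfft / 2, k, k - nfft) / nfft   # cycles/sample, [-0.5, 0.5)
  fc <- 0.5 * filt@cutoff
  w <- abs(f)
  fn <- f / fc
  win <- switch(filt@window,
    "ram-lak" = rep(1, nfft),
    "hann" = 0.5 * (1 + cos(pi * fn)),
    "cosine" = cos(pi * fn / 2))
  w <- w * win
  w[abs(f) > fc] <- 0
  w
}

#' Ramp-filter a sinogram
#'
#' Convolves every view row with the windowed ramp kernel (implemented by
#' zero-padded FFT).  Linear; a zero sinogram maps to zero, a constant row to
#' a row with zero mean.
#'
#' @param sino a \linkS4class{Sinogram} with at least 2 detector bins.
#' @param filt a \linkS4class{FilterSpec}.
#' @return a \linkS4class{Sinogram} holding the filtered rows.
#' @export
rampFilter <- function(sino, filt = filterSpec()) {
  stopifnot(is(sino, "Sinogram"))
  v <- sino@values
  nd <- ncol(v)
  if (nd < 2) stop("ramp filtering needs >= 2 detector bins")
  nfft <- 2^ceiling(log2(2 * nd))
  w <- rampFrequencyResponse(filt, nfft) / sino@geometry@detectorSpacing
  # pad by linear interpolation between the row's two edge samples: identical
  # to zero padding for compactly supported rows, and exactly DC-free for
  # constant rows (the padded signal is then constant, and the ramp's DC
  # gain is zero)
  pad <- matrix(0, nrow(v), nfft)
  pad[, seq_len(nd)] <- v
  npad <- nfft - nd
  if (npad > 0) {
    wts <- seq_len(npad) / (npad + 1)
    pad[, nd + seq_len(npad)] <- outer(v[, nd], 1 - wts) + outer(v[, 1], wts)
  }
  ft <- stats::mvfft(t(pad)) * w
  out <- t(Re(stats::mvfft(ft, inverse = TRUE))) / nfft
  out <- out[, seq_len(nd), drop = FALSE]
  new("Sinogram", values = out, geometry = sino@geometry,
      noiseLevel = sino@noiseLevel, seed = sino@seed)
}

#' Reconstruct an image by filtered back-projection
#'
#' Parallel beam: ramp-filter each view and back-project along the rays,
#' scaled by the angular step (halved when the trajectory covers the full
#' circle, where every line integral is measured twice).  Fan beam (flat
#' virtual detector through the rotation axis): detector rows are cosine
#' pre-weighted, ramp-filtered and back-projected with inverse-square
#' distance weighting.  Half-range fan data are reconstructed with plain
#' weighting (no short-scan compensation): the resulting limited-angle
#' artefacts are the object of study.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param filt a \linkS4class{FilterSpec}; default pure ramp at full cutoff.
#' @param outSize output image side; defaults to the geometry's
#'   \code{imageSize}.
#' @return numeric \code{outSize x outSize} matrix (the artefact-corrupted
#'   input image of the learned post-processing workflow).
#' @export
fbpReconstruct <- function(sino, filt = filterSpec(), outSize = NULL) {
  stopifnot(is(sino, "Sinogram"))
  geom <- sino@geometry
  if (is.null(outSize)) outSize <- geom@imageSize
  if (outSize < 16) stop("outSize must be >= 16")
  ang <- geometryAngles(geom, "radians")
  off <- detectorOffsets(geom)
  span <- (geom@angleEnd - geom@angleStart) * pi / 180
  dth <- span / geom@nViews
  scale <- if (span >= 1.5 * pi) dth / 2 else dth
  if (geom@beam == "parallel") {
    fs <- rampFilter(sino, filt)
    rec <- cpp_backproject_parallel(fs@values, ang, off, as.integer(outSize))
  } else {
    sad <- geom@sourceAxisDist
    pre <- sino
    pre@values <- sweep(sino@values, 2, sad / sqrt(sad^2 + off^2), "*")
    fs <- rampFilter(pre, filt)
    rec <- cpp_backproject_fan(fs@values, ang, off, as.integer(outSize), sad)
  }
  rec * scale
}
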