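# Feature similarity index: phase congruency (log-Gabor filter bank) and
# gradient magnitude (Scharr operators), combined with the standard
# constants T1 = 0.85 and T2 = 160 on a 0-255 dynamic range and weighted by
# the pointwise maximum phase congruency.

# log-Gabor filter bank in the frequency domain: 4 scales x 4 orientations,
# smallest wavelength 6, scale multiplier 2, sigmaOnf 0.55, angular spread
# sd = (pi/norient)/1.2.  Cached per image size.
.fsimCache <- new.env(parent = emptyenv())

logGaborBank <- function(H, W, nscale = 4, norient = 4, minWave = 6,
                         mult = 2, sigmaOnf = 0.55, dThetaOnSigma = 1.2) {
  key <- paste(H, W, sep = "x")
  if (!is.null(.fsimCache[[key]])) return(.fsimCache[[key]])
  fx <- ifelse(seq_len(W) - 1 <= W / 2, seq_len(W) - 1,
               seq_len(W) - 1 - W) / W
  fy <- ifelse(seq_len(H) - 1 <= H / 2, seq_len(H) - 1,
               seq_len(H) - 1 - H) / H
  FX <- matrix(fx, H, W, byrow = TRUE)
  FY <- matrix(fy, H, W)
  radius <- sqrt(FX^2 + FY^2)
  radius[1, 1] <- 1   # avoid log(0) at DC; filters are zeroed there anyway
  theta <- atan2(-FY, FX)
  sintheta <- sin(theta); costheta <- cos(theta)
  thetaSigma <- (pi / norient) / dThetaOnSigma
  bank <- vector("list", norient)
  for (o in seq_len(norient)) {
    ang <- (o - 1) * pi / norient
    ds <- sintheta * cos(ang) - costheta * sin(ang)
    dc <- costheta * cos(ang) + sintheta * sin(ang)
    dtheta <- abs(atan2(ds, dc))
    spread <- exp(-dtheta^2 / (2 * thetaSigma^2))
    filters <- vector("list", nscale)
    for (s in seq_len(nscale)) {
      f0 <- 1 / (minWave * mult^(s - 1))
      lg <- exp(-(log(radius / f0))^2 / (2 * log(sigmaOnf)^2))
      lg[1, 1] <- 0
      filters[[s]] <- lg * spread
    }
    bank[[o]] <- filters
  }
  .fsimCache[[key]] <- bank
  bank
}

# phase congruency map: local energy over scales per orientation, normalised
# by the summed filter-response amplitudes (no noise-threshold compensation)
phaseCongruency <- function(img) {
  H <- nrow(img); W <- ncol(img)
  bank <- logGaborBank(H, W)
  Fimg <- fft(img)
  eps <- 1e-4
  energy <- matrix(0, H, W)
  ampSum <- matrix(0, H, W)
  for (o in seq_along(bank)) {
    sumRe <- matrix(0, H, W); sumIm <- matrix(0, H, W)
    for (s in seq_along(bank[[o]])) {
      resp <- fft(Fimg * bank[[o]][[s]], inverse = TRUE) / (H * W)
      sumRe <- sumRe + Re(resp)
      sumIm <- sumIm + Im(resp)
      ampSum <- ampSum + Mod(resp)
    }
    energy <- energy + sqrt(sumRe^2 + sumIm^2)
  }
  energy / (ampSum + eps)
}

scharrGradient <- function(img) {
  kx <- matrix(c(3, 10, 3, 0, 0, 0, -3, -10, -3), 3, 3) / 16
  H <- nrow(img); W <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[H, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, W, drop = FALSE])
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (dy in 1:3) for (dx in 1:3) {
    blk <- pad[dy:(dy + H - 1), dx:(dx + W - 1)]
    gx <- gx + kx[dy, dx] * blk
    gy <- gy + kx[dx, dy] * blk
  }
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index
#'
#' Combines a phase-congruency similarity term (log-Gabor filter bank, 4
#' scales x 4 orientations) with a gradient-magnitude similarity term
#' (Scharr operators), using constants T1 = 0.85 and T2 = 160 defined on a
#' 0-255 dynamic range, and averages the product weighted by the pointwise
#' maximum phase congruency.  Equal images score exactly 1; the value always
#' lies in (0, 1].
#'
#' @param x,gt grayscale matrices of equal dimension.  Intensities are mapped
#'   to 0-255 using the ground truth's dynamic range.
#' @return scalar in (0, 1].
#' @export
fsim <- function(x, gt) {
  if (!identical(dim(x), dim(gt))) stop("dimension mismatch")
  rng <- max(gt) - min(gt)
  if (rng <= 0) rng <- 1
  a <- (x - min(gt)) / rng * 255
  b <- (gt - min(gt)) / rng * 255
  pc1 <- phaseCongruency(a)
  pc2 <- phaseCongruency(b)
  g1 <- scharrGradient(a)
  g2 <- scharrGradient(b)
  T1 <- 0.85; T2 <- 160
  sPC <- (2 * pc1 * pc2 + T1) / (pc1^2 + pc2^2 + T1)
  sG <- (2 * g1 * g2 + T2) / (g1^2 + g2^2 + T2)
  pcm <- pmax(pc1, pc2)
  sum(sPC * sG * pcm) / sum(pcm)
}
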