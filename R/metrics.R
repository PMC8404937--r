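# Full-reference image quality metrics.

#' Relative error
#'
#' \code{||x - gt||_2 / ||gt||_2}.  The unsquared norm ratio is the default
#' (the conventional relative error); the squared variant is available by
#' flag.  Scale-invariant: RE(c x, c gt) = RE(x, gt) for c > 0.
#'
#' @param x,gt matrices of equal dimension; \code{gt} must not be all zero.
#' @param squared return the squared ratio instead.
#' @return nonnegative scalar.
#' @export
relativeError <- function(x, gt, squared = FALSE) {
  if (!identical(dim(x), dim(gt))) stop("dimension mismatch")
  den <- sum(gt^2)
  if (den == 0) stop("ground truth is all zero; relative error undefined")
  r <- sum((x - gt)^2) / den
  if (squared) r else sqrt(r)
}

#' Peak signal-to-noise ratio (both conventions)
#'
#' \code{psnrPaper = 20 log10(n * max(gt) / ||x - gt||_2)} with n the pixel
#' count, and the standard \code{psnrStd = 20 log10(max(gt) / RMSE)}.  The
#' two differ by exactly \code{10 log10(n)} for any x != gt.  Identical
#' images return the +Inf sentinel for both.
#'
#' @param x,gt matrices of equal dimension.
#' @return named numeric vector \code{c(paper = ..., standard = ...)}.
#' @export
psnr <- function(x, gt) {
  if (!identical(dim(x), dim(gt))) stop("dimension mismatch")
  n <- length(gt)
  d <- sqrt(sum((x - gt)^2))
  if (d == 0) return(c(paper = Inf, standard = Inf))
  mx <- max(gt)
  c(paper = 20 * log10(n * mx / d),
    standard = 20 * log10(mx / sqrt(mean((x - gt)^2))))
}

# separable 11-tap Gaussian window (sd 1.5), truncated like the reference
# implementations; valid-region filtering realised as band-matrix products.
ssimWindowMatrix <- function(side, radius = 5L, sigma = 1.5) {
  g <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  g <- g / sum(g)
  n <- side - 2L * radius
  if (n < 1) stop("image too small for the 11x11 SSIM window")
  G <- matrix(0, n, side)
  for (i in seq_len(n)) G[i, i:(i + 2L * radius)] <- g
  G
}

#' Structural similarity index
#'
#' Mean local SSIM with an 11x11 Gaussian window (sd 1.5) and stability
#' constants K1 = 0.01, K2 = 0.03, the standard configuration.  Local
#' statistics are Gaussian-weighted and evaluated on the valid interior
#' (window fully inside the image).
#'
#' @param x,gt matrices of equal dimension (side >= 11).
#' @param dataRange dynamic range L; defaults to \code{max(gt) - min(gt)}.
#' @return scalar in (0, 1] for nonnegative images; 1 iff x == gt.
#' @export
ssim <- function(x, gt, dataRange = NULL) {
  if (!identical(dim(x), dim(gt))) stop("dimension mismatch")
  if (is.null(dataRange)) dataRange <- max(gt) - min(gt)
  if (dataRange <= 0) dataRange <- 1
  Gr <- ssimWindowMatrix(nrow(x))
  Gc <- ssimWindowMatrix(ncol(x))
  w <- function(m) Gr %*% m %*% t(Gc)
  mu1 <- w(x); mu2 <- w(gt)
  s11 <- w(x * x) - mu1^2
  s22 <- w(gt * gt) - mu2^2
  s12 <- w(x * gt) - mu1 * mu2
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  mean(((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
       ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)))
}

#' Evaluate a reconstruction method over a paired dataset
#'
#' Computes RE, both PSNR conventions, SSIM and FSIM per image against the
#' ground truths and their arithmetic means.  \code{model = NULL} evaluates
#' the FBP inputs themselves (passthrough baseline); a trained
#' \linkS4class{NetworkSpec} evaluates its restored outputs.
#'
#' @param model \code{NULL} (FBP passthrough) or a \linkS4class{NetworkSpec}.
#' @param dataset a \linkS4class{PairedDataset}.
#' @param label method label; defaults to \code{"FBP"} or the network name.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateMethod <- function(model = NULL, dataset, label = NULL) {
  stopifnot(is(dataset, "PairedDataset"))
  outs <- if (is.null(model)) dataset@y
  else netForward(model, dataset@y)
  if (is.null(label)) label <- if (is.null(model)) "FBP" else model@name
  rows <- lapply(seq_along(outs), function(i) {
    x <- outs[[i]]; gt <- dataset@gt[[i]]
    p <- psnr(x, gt)
    data.frame(re = relativeError(x, gt), psnrPaper = p[["paper"]],
               psnrStd = p[["standard"]], ssim = ssim(x, gt),
               fsim = fsim(x, gt))
  })
  per <- do.call(rbind, rows)
  new("MetricsReport", perImage = per, means = colMeans(per),
      n = length(dataset@gt[[1]]), geometryTag = dataset@geometryTag,
      method = label)
}

#' Tabulate several metric reports as a comparison table
#'
#' One row per method, columns RE, PSNR (both conventions), SSIM, FSIM.
#'
#' @param ... \linkS4class{MetricsReport} objects.
#' @return data.frame.
#' @export
metricsTable <- function(...) {
  reps <- list(...)
  do.call(rbind, lapply(reps, function(r) {
    data.frame(method = r@method, geometry = r@geometryTag,
               RE = r@means[["re"]], PSNR = r@means[["psnrPaper"]],
               PSNR_std = r@means[["psnrStd"]], SSIM = r@means[["ssim"]],
               FSIM = r@means[["fsim"]], row.names = NULL)
  }))
}
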