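# Synthetic ground-truth phantom families.
#
# Two families emulate the two image populations of the study design:
#   - "chest": a soft-tissue body outline with lung-like cavities and a
#     handful of internal features, plus mild Gaussian texture inside the
#     body, so that ground truths are not noise-free (as real reconstructed
#     training slices are not);
#   - "flat-sharp": piecewise-constant flat regions containing small
#     high-contrast sharp objects and no texture at all -- the out-of-domain
#     family with image statistics unlike anything seen in training.
# "shepp-logan" provides the canonical analytic reference phantom.

canonicalSheppLogan <- data.frame(
  x0    = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
  y0    = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
  a     = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
  b     = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
  phi   = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0),
  value = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))

# randomized chest-like ellipse table; rng state supplied by caller
chestEllipses <- function() {
  jit <- function(v, f) v * (1 + runif(1, -f, f))
  e <- data.frame(
    x0 = 0, y0 = runif(1, 0.02, 0.08),
    a = jit(0.46, 0.06), b = jit(0.36, 0.06), phi = runif(1, -4, 4),
    value = 0.25)
  lungs <- data.frame(
    x0 = c(-1, 1) * jit(0.19, 0.08), y0 = rep(runif(1, -0.03, 0.02), 2),
    a = c(jit(0.14, 0.08), jit(0.14, 0.08)),
    b = c(jit(0.19, 0.08), jit(0.19, 0.08)),
    phi = c(jit(8, 0.3), -jit(8, 0.3)), value = -0.18)
  spine <- data.frame(x0 = 0, y0 = jit(0.27, 0.1), a = jit(0.07, 0.2),
                      b = jit(0.055, 0.2), phi = 0, value = 0.3)
  nf <- sample(3:7, 1)   # bright internal features (vessels, lesions)
  feats <- data.frame(
    x0 = runif(nf, -0.3, 0.3), y0 = runif(nf, -0.25, 0.15),
    a = runif(nf, 0.02, 0.07), b = runif(nf, 0.02, 0.07),
    phi = runif(nf, -90, 90),
    value = runif(nf, 0.05, 0.15))
  rbind(e, lungs, spine, feats)
}

flatSharpEllipses <- function() {
  nr <- sample(2:4, 1)   # large flat regions
  regions <- data.frame(
    x0 = runif(nr, -0.35, 0.35), y0 = runif(nr, -0.35, 0.35),
    a = runif(nr, 0.25, 0.45), b = runif(nr, 0.25, 0.45),
    phi = runif(nr, -90, 90), value = runif(nr, 0.1, 0.3))
  ns <- sample(6:12, 1)  # small sharp objects
  sharp <- data.frame(
    x0 = runif(ns, -0.45, 0.45), y0 = runif(ns, -0.45, 0.45),
    a = runif(ns, 0.012, 0.04), b = runif(ns, 0.012, 0.04),
    phi = runif(ns, -90, 90),
    value = sample(c(-1, 1), ns, replace = TRUE) * runif(ns, 0.15, 0.3))
  rbind(regions, sharp)
}

#' Build a phantom specification
#'
#' Without an explicit ellipse table the family template is drawn
#' deterministically from \code{seed}: the chest family randomises a body /
#' lungs / spine layout with internal features, the flat-sharp family draws
#' flat regions with small sharp objects, and \code{"shepp-logan"} returns the
#' canonical ten-ellipse table.
#'
#' @param family \code{"chest"}, \code{"flat-sharp"} or \code{"shepp-logan"}.
#' @param size image side in pixels (>= 16).
#' @param seed integer seed.
#' @param textureSigma sd of the Gaussian texture added inside the body
#'   outline (chest family only; the flat-sharp family is noise-free by
#'   contract).  Default 0.02 for chest, 0 otherwise.
#' @param ellipses optional explicit ellipse data.frame
#'   (\code{x0, y0, a, b, phi, value}, coordinates normalised to \[-1, 1\]).
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' spec <- phantomSpec("shepp-logan", size = 64)
#' img <- generatePhantom(spec)
#' range(img)
#' @export
phantomSpec <- function(family = c("chest", "flat-sharp", "shepp-logan"),
                        size = 128L, seed = 1L, textureSigma = NULL,
                        ellipses = NULL) {
  family <- match.arg(family)
  if (is.null(textureSigma))
    textureSigma <- if (family == "chest") 0.02 else 0
  if (is.null(ellipses)) {
    ellipses <- switch(family,
      "shepp-logan" = canonicalSheppLogan,
      "chest" = withSeed(seed, chestEllipses()),
      "flat-sharp" = withSeed(seed, flatSharpEllipses()))
  }
  new("PhantomSpec", family = family, size = as.integer(size),
      ellipses = ellipses, textureSigma = as.numeric(textureSigma),
      seed = as.integer(seed))
}

# sum of ellipse intensities at normalised coordinates; vectorised over grid
rasterizeEllipses <- function(ellipses, size) {
  img <- matrix(0, size, size)
  if (nrow(ellipses) == 0) return(img)
  cc <- ((seq_len(size) - 1) - (size - 1) / 2) / (size / 2)
  X <- matrix(cc, size, size, byrow = TRUE)   # x varies along columns
  Y <- matrix(cc, size, size)                 # y varies along rows
  for (i in seq_len(nrow(ellipses))) {
    e <- ellipses[i, ]
    th <- e$phi * pi / 180
    xr <- (X - e$x0) * cos(th) + (Y - e$y0) * sin(th)
    yr <- -(X - e$x0) * sin(th) + (Y - e$y0) * cos(th)
    img <- img + e$value * ((xr / e$a)^2 + (yr / e$b)^2 <= 1)
  }
  img
}

#' Rasterise a phantom specification into a ground-truth image
#'
#' Deterministic in (spec, seed): every pixel inside an ellipse accumulates
#' that ellipse's additive intensity; the chest family then receives zero-mean
#' Gaussian texture (sd \code{textureSigma}) inside the body outline.  If the
#' summed intensities leave \[0, 1\] the image is affinely rescaled into range
#' and a message records the rescale (values are never silently clipped).
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return numeric matrix in \[0, 1\].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  img <- rasterizeEllipses(spec@ellipses, spec@size)
  if (spec@textureSigma > 0 && nrow(spec@ellipses) > 0) {
    body <- rasterizeEllipses(spec@ellipses[1, , drop = FALSE], spec@size) != 0
    tex <- withSeed(spec@seed + 211L,
                    matrix(rnorm(spec@size^2, 0, spec@textureSigma),
                           spec@size, spec@size))
    # texture is truncated so it never pushes a pixel outside the image range
    img[body] <- pmin(pmax(img[body] + tex[body], 0), 1)
  }
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 1) {
    message(sprintf(
      "phantom intensities [%0.3f, %0.3f] exceed [0, 1]; rescaling affinely",
      rng[1], rng[2]))
    img <- scaleToUnit(img)
  }
  img
}

#' Centred disk phantom with anti-aliased boundary
#'
#' Analytic reference object for projector and FBP checks: its parallel-beam
#' projection is the chord length 2*sqrt(R^2 - s^2).  Pixels crossing the
#' boundary carry their sub-pixel area fraction (supersampled), so the
#' discretised object matches the analytic one to first order.
#'
#' @param size image side in pixels.
#' @param radius disk radius in pixels.
#' @param supersample supersampling factor for the boundary pixels.
#' @return numeric matrix in \[0, 1\].
#' @export
diskPhantom <- function(size, radius = size * 0.3, supersample = 4L) {
  ss <- as.integer(supersample)
  cc <- ((seq_len(size * ss)) - (size * ss + 1) / 2) / ss
  big <- outer(cc, cc, function(y, x) as.numeric(x^2 + y^2 <= radius^2))
  idx <- rep(seq_len(size), each = ss)
  m <- rowsum(big, idx)
  t(rowsum(t(m), idx)) / ss^2
}

#' Generate a dataset of phantoms with randomised parameters
#'
#' Draws \code{n} phantoms of the template's family, each from its own seed
#' derived from \code{seed} (so train/test splits built from different master
#' seeds use disjoint streams).
#'
#' @param n number of images (>= 1).
#' @param spec template \linkS4class{PhantomSpec}; family, size and
#'   textureSigma are inherited, ellipse layouts are re-drawn per image
#'   (the shepp-logan family jitters the canonical table).
#' @param seed master seed of the dataset.
#' @return list of ground-truth matrices in \[0, 1\].
#' @export
generateDataset <- function(n, spec, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    si <- deriveSeed(seed, i)
    sp <- if (spec@family == "shepp-logan") {
      ell <- withSeed(si, {
        e <- canonicalSheppLogan
        e$x0 <- e$x0 + runif(nrow(e), -0.02, 0.02)
        e$y0 <- e$y0 + runif(nrow(e), -0.02, 0.02)
        e$a <- e$a * runif(nrow(e), 0.95, 1.05)
        e$b <- e$b * runif(nrow(e), 0.95, 1.05)
        e
      })
      phantomSpec(spec@family, spec@size, seed = si,
                  textureSigma = spec@textureSigma, ellipses = ell)
    } else {
      phantomSpec(spec@family, spec@size, seed = si,
                  textureSigma = spec@textureSigma)
    }
    generatePhantom(sp)
  })
}
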