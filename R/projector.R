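# Forward projection and measurement noise.

#' Build a scan geometry from a protocol preset
#'
#' Presets follow the two sparse-view protocols under study:
#' \code{"full-range"} acquires 360 views with 1-degree spacing over
#' \[0, 360) degrees; \code{"half-range"} restricts the trajectory to
#' \[0, 180) with 180 views (limited angle).  \code{"custom"} takes explicit
#' angles/views.  The detector count defaults to \code{ceiling(sqrt(2) * size)}
#' rounded up to even, enough to cover the image diagonal at unit pitch.
#' Fan-beam distances default to twice the image side.
#'
#' In parallel geometry the two presets carry the same information (opposite
#' views are redundant); only the fan beam preserves the full-range versus
#' half-range distinction, which is why the paired-dataset simulations default
#' to \code{"fan-flat"}.
#'
#' @param protocol \code{"full-range"}, \code{"half-range"} or \code{"custom"}.
#' @param imageSize side of the square image the scan is designed for.
#' @param beam \code{"fan-flat"} (default) or \code{"parallel"}.
#' @param nViews,angleStart,angleEnd view count and angular range in degrees
#'   (end exclusive); required for \code{"custom"}, fixed by the presets.
#' @param nDetectors,detectorSpacing detector bin count and pitch.
#' @param sourceAxisDist,axisDetectorDist fan-beam distances in pixel units.
#' @return a \linkS4class{ScanGeometry}.
#' @examples
#' makeGeometry("full-range", 128)
#' @export
makeGeometry <- function(protocol = c("full-range", "half-range", "custom"),
                         imageSize, beam = c("fan-flat", "parallel"),
                         nViews = NULL, angleStart = 0, angleEnd = NULL,
                         nDetectors = NULL, detectorSpacing = 1,
                         sourceAxisDist = NULL, axisDetectorDist = NULL) {
  protocol <- match.arg(protocol)
  beam <- match.arg(beam)
  if (protocol == "full-range") { nViews <- 360L; angleStart <- 0; angleEnd <- 360 }
  else if (protocol == "half-range") { nViews <- 180L; angleStart <- 0; angleEnd <- 180 }
  else if (is.null(nViews)) stop("custom protocol requires nViews")
  if (is.null(angleEnd)) angleEnd <- angleStart + 180
  if (is.null(nDetectors)) {
    nDetectors <- ceiling(sqrt(2) * imageSize)
    if (nDetectors %% 2 == 1) nDetectors <- nDetectors + 1
  }
  if (is.null(sourceAxisDist)) sourceAxisDist <- 2 * imageSize
  if (is.null(axisDetectorDist)) axisDetectorDist <- 2 * imageSize
  new("ScanGeometry", beam = beam, angleStart = as.numeric(angleStart),
      angleEnd = as.numeric(angleEnd), nViews = as.integer(nViews),
      nDetectors = as.integer(nDetectors),
      detectorSpacing = as.numeric(detectorSpacing),
      sourceAxisDist = as.numeric(sourceAxisDist),
      axisDetectorDist = as.numeric(axisDetectorDist),
      protocolTag = protocol, imageSize = as.integer(imageSize))
}

#' View angles of a geometry
#'
#' Equally spaced over \[angleStart, angleEnd), end exclusive.
#'
#' @param geom a \linkS4class{ScanGeometry}.
#' @param units \code{"degrees"} or \code{"radians"}.
#' @return numeric vector of length \code{nViews(geom)}.
#' @export
geometryAngles <- function(geom, units = c("degrees", "radians")) {
  units <- match.arg(units)
  a <- geom@angleStart +
    (seq_len(geom@nViews) - 1) * (geom@angleEnd - geom@angleStart) / geom@nViews
  if (units == "radians") a * pi / 180 else a
}

detectorOffsets <- function(geom) {
  (seq_len(geom@nDetectors) - 1 - (geom@nDetectors - 1) / 2) *
    geom@detectorSpacing
}

#' Forward-project an image into a sinogram
#'
#' Each sinogram entry is the discretised line integral of the image along
#' the corresponding ray, computed by Joseph's method (linear interpolation
#' along the ray's minor axis).  The operation is linear in the image; rays
#' missing the image support contribute zero.
#'
#' @param img square numeric matrix (pixel size 1).
#' @param geom a \linkS4class{ScanGeometry} with matching \code{imageSize}.
#' @param backend optional plug-in projector: a
#'   \code{function(img, geom)} returning an \code{nViews x nDetectors}
#'   matrix of line integrals, substituted for the built-in ray tracer
#'   (e.g. to bind an external projection toolbox to the same contract).
#' @return a clean \linkS4class{Sinogram} (noise level 0).
#' @export
forwardProject <- function(img, geom, backend = NULL) {
  assertSquare(img)
  if (nrow(img) != geom@imageSize)
    stop("image side ", nrow(img), " does not match geometry imageSize ",
         geom@imageSize)
  if (!is.null(backend)) {
    vals <- backend(img, geom)
    if (!is.matrix(vals) || nrow(vals) != geom@nViews ||
        ncol(vals) != geom@nDetectors)
      stop("backend must return an nViews x nDetectors matrix")
  } else {
    ang <- geometryAngles(geom, "radians")
    off <- detectorOffsets(geom)
    vals <- if (geom@beam == "parallel")
      cpp_forward_parallel(img, ang, off)
    else
      cpp_forward_fan(img, ang, off, geom@sourceAxisDist)
  }
  new("Sinogram", values = vals, geometry = geom, noiseLevel = 0,
      seed = NA_integer_)
}

#' Add white Gaussian measurement noise to a sinogram
#'
#' The perturbation is \code{e = level * (||b||_2 / sqrt(m)) * xi} with
#' \code{xi} i.i.d. standard normal over all \code{m} entries of the clean
#' sinogram \code{b}, so that the expected relative L2 perturbation
#' \code{||e||_2 / ||b||_2} equals \code{level}.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param level relative noise level (>= 0); 0 returns the input unchanged.
#' @param seed integer seed making the draw reproducible.
#' @return a noisy \linkS4class{Sinogram} recording level and seed.
#' @export
addNoise <- function(sino, level, seed = 1L) {
  stopifnot(is(sino, "Sinogram"))
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(sino)
  b <- sino@values
  m <- length(b)
  scale <- level * sqrt(sum(b^2)) / sqrt(m)
  noisy <- b + withSeed(seed, matrix(rnorm(m), nrow(b), ncol(b))) * scale
  new("Sinogram", values = noisy, geometry = sino@geometry,
      noiseLevel = level, seed = as.integer(seed))
}
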