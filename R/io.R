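# Image and sinogram I/O: 16-bit TIFF / PNG for images, TSV with a JSON
# sidecar carrying geometry and provenance attributes for sinograms.

#' Write / read an image as 16-bit TIFF or PNG
#'
#' Values are clamped to \[0, 1\] on write (both formats store normalised
#' intensities).  The PNG writer stores 16-bit samples as well.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return \code{readImageTIFF}/\code{readImagePNG} return a numeric matrix.
#' @export
writeImageTIFF <- function(img, path) {
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImageTIFF <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' @rdname writeImageTIFF
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' @rdname writeImageTIFF
#' @export
readImagePNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

geometryToList <- function(geom) {
  list(beam = geom@beam, angleStart = geom@angleStart,
       angleEnd = geom@angleEnd, nViews = geom@nViews,
       nDetectors = geom@nDetectors,
       detectorSpacing = geom@detectorSpacing,
       sourceAxisDist = geom@sourceAxisDist,
       axisDetectorDist = geom@axisDetectorDist,
       protocolTag = geom@protocolTag, imageSize = geom@imageSize)
}

listToGeometry <- function(l) {
  new("ScanGeometry", beam = l$beam, angleStart = l$angleStart,
      angleEnd = l$angleEnd, nViews = as.integer(l$nViews),
      nDetectors = as.integer(l$nDetectors),
      detectorSpacing = l$detectorSpacing,
      sourceAxisDist = l$sourceAxisDist,
      axisDetectorDist = l$axisDetectorDist,
      protocolTag = l$protocolTag, imageSize = as.integer(l$imageSize))
}

#' Write / read a sinogram as TSV plus a JSON sidecar
#'
#' The TSV holds the views-by-detectors array; \code{<path>.json} records the
#' geometry, noise level and seed so the sinogram can be restored losslessly
#' into its full object.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param path path of the TSV file.
#' @return \code{readSinogramTSV} returns the restored
#'   \linkS4class{Sinogram}.
#' @export
writeSinogramTSV <- function(sino, path) {
  stopifnot(is(sino, "Sinogram"))
  utils::write.table(sino@values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  side <- list(geometry = geometryToList(sino@geometry),
               noiseLevel = sino@noiseLevel,
               seed = if (is.na(sino@seed)) NULL else sino@seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSinogramTSV
#' @export
readSinogramTSV <- function(path) {
  vals <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(vals) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("Sinogram", values = vals, geometry = listToGeometry(side$geometry),
      noiseLevel = side$noiseLevel,
      seed = if (is.null(side$seed)) NA_integer_ else as.integer(side$seed))
}
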