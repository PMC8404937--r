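# generics, accessors, show methods

#' @rdname Sinogram-class
#' @param object,x a \linkS4class{Sinogram}
#' @export
setGeneric("sinogramValues", function(x) standardGeneric("sinogramValues"))
#' @rdname Sinogram-class
#' @export
setMethod("sinogramValues", "Sinogram", function(x) x@values)

#' @rdname Sinogram-class
#' @export
setGeneric("scanGeometry", function(x) standardGeneric("scanGeometry"))
#' @rdname Sinogram-class
#' @export
setMethod("scanGeometry", "Sinogram", function(x) x@geometry)

#' @rdname ScanGeometry-class
#' @param x a \linkS4class{ScanGeometry} (or object holding one)
#' @export
setGeneric("nViews", function(x) standardGeneric("nViews"))
#' @rdname ScanGeometry-class
#' @export
setMethod("nViews", "ScanGeometry", function(x) x@nViews)
#' @rdname ScanGeometry-class
#' @export
setMethod("nViews", "Sinogram", function(x) x@geometry@nViews)

#' @rdname ScanGeometry-class
#' @export
setGeneric("nDetectors", function(x) standardGeneric("nDetectors"))
#' @rdname ScanGeometry-class
#' @export
setMethod("nDetectors", "ScanGeometry", function(x) x@nDetectors)
#' @rdname ScanGeometry-class
#' @export
setMethod("nDetectors", "Sinogram", function(x) x@geometry@nDetectors)

#' @rdname PairedDataset-class
#' @param x a \linkS4class{PairedDataset}
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname PairedDataset-class
#' @export
setMethod("nPairs", "PairedDataset", function(x) length(x@y))

#' @rdname PairedDataset-class
#' @export
setGeneric("pairInputs", function(x) standardGeneric("pairInputs"))
#' @rdname PairedDataset-class
#' @export
setMethod("pairInputs", "PairedDataset", function(x) x@y)

#' @rdname PairedDataset-class
#' @export
setGeneric("pairTargets", function(x) standardGeneric("pairTargets"))
#' @rdname PairedDataset-class
#' @export
setMethod("pairTargets", "PairedDataset", function(x) x@gt)

#' @rdname NetworkSpec-class
#' @param x a \linkS4class{NetworkSpec}
#' @export
setGeneric("isTrained", function(x) standardGeneric("isTrained"))
#' @rdname NetworkSpec-class
#' @export
setMethod("isTrained", "NetworkSpec", function(x) x@trained)

#' @rdname NetworkSpec-class
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname NetworkSpec-class
#' @export
setMethod("networkName", "NetworkSpec", function(x) x@name)

#' @rdname MetricsReport-class
#' @param x a \linkS4class{MetricsReport}
#' @export
setGeneric("metricMeans", function(x) standardGeneric("metricMeans"))
#' @rdname MetricsReport-class
#' @export
setMethod("metricMeans", "MetricsReport", function(x) x@means)

#' @rdname MetricsReport-class
#' @export
setGeneric("metricTable", function(x) standardGeneric("metricTable"))
#' @rdname MetricsReport-class
#' @export
setMethod("metricTable", "MetricsReport", function(x) x@perImage)

setMethod("show", "ScanGeometry", function(object) {
  cat("ScanGeometry <", object@protocolTag, ">\n", sep = "")
  cat("  beam:", object@beam, "| views:", object@nViews,
      sprintf("over [%g, %g) deg", object@angleStart, object@angleEnd), "\n")
  cat("  detectors:", object@nDetectors, "spacing", object@detectorSpacing,
      "| image side:", object@imageSize, "\n")
  if (object@beam == "fan-flat")
    cat("  SAD:", object@sourceAxisDist, " ADD:", object@axisDetectorDist, "\n")
})

setMethod("show", "Sinogram", function(object) {
  cat("Sinogram:", nrow(object@values), "views x", ncol(object@values),
      "detectors (", object@geometry@protocolTag, ",",
      object@geometry@beam, ")\n")
  cat("  noise level:", object@noiseLevel,
      if (!is.na(object@seed)) paste("(seed", object@seed, ")") else "", "\n")
})

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec <", object@family, ">: ", object@size, "x", object@size,
      ", ", nrow(object@ellipses), " ellipses, textureSigma = ",
      object@textureSigma, ", seed = ", object@seed, "\n", sep = "")
})

setMethod("show", "NetworkSpec", function(object) {
  nconv <- sum(vapply(object@layers, function(l) l@kind == "conv", TRUE))
  cat("NetworkSpec <", object@name, "> (", object@kind, ")\n", sep = "")
  cat("  layers:", length(object@layers), "(", nconv, "conv ) | residual:",
      object@residual, "| trained:", object@trained, "\n")
  cat("  parameters:", length(object@params),
      "| input side divisible by:", object@inputDivisor, "\n")
})

setMethod("show", "RFResult", function(object) {
  cat("RFResult: r_t =", paste(object@rf, collapse = " "), "\n")
  cat("  max RF:", object@maxRF, "x", object@maxRF,
      sprintf("(%.2f%% of a %d x %d input)\n", object@percentOfInput,
              object@inputSide, object@inputSide))
})

setMethod("show", "CostReport", function(object) {
  cat("CostReport:\n")
  cat(sprintf("  weight parameters: %s\n  all trainable:     %s\n",
              format(object@weightParams, big.mark = ","),
              format(object@allTrainableParams, big.mark = ",")))
  cat(sprintf("  FLOPs @ %d px: %.4g  (%s)\n", as.integer(object@inputSide),
              object@flops, object@convention))
})

setMethod("show", "PairedDataset", function(object) {
  cat("PairedDataset:", length(object@y), "pairs |", object@geometryTag,
      "| noise", object@noiseLevel, "|", object@split, "split\n")
})

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig:", object@optimizer, "|", object@epochs, "epochs, batch",
      object@batchSize, "\n")
  cat(sprintf("  lr %g -> %g (power %g), momentum %g, grad clip %g, seed %d\n",
              object@lrStart, object@lrEnd, object@lrPower, object@momentum,
              object@gradClip, object@seed))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport <", object@method, "> on", nrow(object@perImage),
      "images (", object@geometryTag, ")\n")
  print(round(object@means, 4))
})

setMethod("show", "OODScenario", function(object) {
  cat("OODScenario <", object@kind, ">: family", object@family, ", noise",
      object@noiseLevel, ",", object@geometryTag, "\n")
})
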