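# Out-of-domain robustness protocol.

#' Define an out-of-domain evaluation scenario
#'
#' \code{"unseen-noise"}: the in-domain (chest) phantom family with the
#' measurement noise doubled relative to training (default 2e-2).
#' \code{"unseen-image"}: the flat-sharp phantom family (noise-free flat
#' regions with small sharp objects, statistics unlike the training images)
#' at the training noise level 1e-2.
#'
#' @param kind \code{"unseen-noise"} or \code{"unseen-image"}.
#' @param geometryTag \code{"full-range"} or \code{"half-range"}.
#' @param noiseLevel override of the scenario noise level.
#' @return an \linkS4class{OODScenario}.
#' @export
oodScenario <- function(kind = c("unseen-noise", "unseen-image"),
                        geometryTag = "full-range", noiseLevel = NULL) {
  kind <- match.arg(kind)
  if (is.null(noiseLevel))
    noiseLevel <- if (kind == "unseen-noise") 2e-2 else 1e-2
  new("OODScenario", kind = kind, noiseLevel = as.numeric(noiseLevel),
      family = if (kind == "unseen-noise") "chest" else "flat-sharp",
      geometryTag = geometryTag)
}

#' Run an out-of-domain evaluation
#'
#' Builds the scenario's paired dataset (scenario family and noise level,
#' fresh seeds), evaluates the trained network and the FBP baseline on it,
#' and always evaluates the paired in-domain reference alongside so the
#' robustness gap is a computed, logged quantity.
#'
#' @param model a trained \linkS4class{NetworkSpec} (untrained models error).
#' @param scenario an \linkS4class{OODScenario}.
#' @param imageSize image side; must be divisible by the model's input
#'   divisor.
#' @param nImages evaluation set size per condition.
#' @param seed master seed (the in-domain reference uses a derived stream).
#' @param beam beam type of the evaluation geometry.
#' @param trainNoise in-domain (training) noise level for the reference.
#' @param filt FBP filter.
#' @param indomain optional precomputed in-domain \linkS4class{PairedDataset}
#'   to reuse as the reference.
#' @return list with \code{scenario}, metric reports \code{oodModel},
#'   \code{oodFBP}, \code{indomainModel}, \code{indomainFBP}, and
#'   \code{deltas} (OOD minus in-domain mean RE / SSIM per method).
#' @export
runOOD <- function(model, scenario, imageSize = 128L, nImages = 10L,
                   seed = 1L, beam = "fan-flat", trainNoise = 1e-2,
                   filt = filterSpec(), indomain = NULL) {
  stopifnot(is(model, "NetworkSpec"), is(scenario, "OODScenario"))
  if (!isTrained(model))
    stop("out-of-domain evaluation requires a trained model")
  geom <- makeGeometry(scenario@geometryTag, imageSize, beam = beam)
  oodGts <- generateDataset(nImages,
                            phantomSpec(scenario@family, imageSize),
                            seed = deriveSeed(seed, 1L))
  oodPairs <- buildPairs(oodGts, geom, scenario@noiseLevel, filt,
                         seed = deriveSeed(seed, 2L), split = "test")
  if (is.null(indomain)) {
    idGts <- generateDataset(nImages, phantomSpec("chest", imageSize),
                             seed = deriveSeed(seed, 3L))
    indomain <- buildPairs(idGts, geom, trainNoise, filt,
                           seed = deriveSeed(seed, 4L), split = "test")
  }
  oodModel <- evaluateMethod(model, oodPairs)
  oodFBP <- evaluateMethod(NULL, oodPairs)
  idModel <- evaluateMethod(model, indomain)
  idFBP <- evaluateMethod(NULL, indomain)
  deltas <- c(
    modelRE = oodModel@means[["re"]] - idModel@means[["re"]],
    modelSSIM = oodModel@means[["ssim"]] - idModel@means[["ssim"]],
    fbpRE = oodFBP@means[["re"]] - idFBP@means[["re"]],
    fbpSSIM = oodFBP@means[["ssim"]] - idFBP@means[["ssim"]])
  list(scenario = scenario, oodModel = oodModel, oodFBP = oodFBP,
       indomainModel = idModel, indomainFBP = idFBP, deltas = deltas)
}
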