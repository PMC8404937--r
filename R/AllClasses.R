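# S4 containers for the simulation / reconstruction / learning workflow.
# Images themselves are plain numeric matrices (height x width, pixel size 1,
# ground truths scaled to [0, 1]); everything with structure beyond a grid
# gets a class with a validity method.

#' PhantomSpec: parametric description of a synthetic ground-truth image
#'
#' A phantom is a sum of constant-intensity ellipses on a square grid, with
#' optional zero-mean Gaussian texture inside the body outline (first ellipse)
#' for the chest-like family.  Ellipse coordinates are normalised to
#' \[-1, 1\] so the same spec rasterises at any size.
#'
#' @slot family one of \code{"chest"}, \code{"flat-sharp"}, \code{"shepp-logan"}.
#' @slot size image side in pixels (>= 16).
#' @slot ellipses data.frame with columns \code{x0, y0, a, b, phi, value}
#'   (centre, semi-axes, rotation in degrees, additive intensity).
#' @slot textureSigma standard deviation of intra-body Gaussian texture;
#'   must be 0 for the flat-sharp family, which is noise-free by contract.
#' @slot seed integer seed controlling the texture stream.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(family = "character", size = "integer",
                 ellipses = "data.frame", textureSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@family %in% c("chest", "flat-sharp", "shepp-logan"))
      msg <- c(msg, "unknown phantom family")
    if (object@size < 16L) msg <- c(msg, "size must be >= 16")
    if (object@family == "flat-sharp" && object@textureSigma != 0)
      msg <- c(msg, "flat-sharp family must have textureSigma = 0")
    if (object@textureSigma < 0) msg <- c(msg, "textureSigma must be >= 0")
    need <- c("x0", "y0", "a", "b", "phi", "value")
    if (nrow(object@ellipses) > 0 && !all(need %in% names(object@ellipses)))
      msg <- c(msg, "ellipse table lacks required columns")
    if (is.null(msg)) TRUE else msg
  })

#' ScanGeometry: acquisition protocol for one 2D scan
#'
#' Presets: \code{"full-range"} is 360 equally spaced views over
#' \[0, 360) degrees (1-degree spacing); \code{"half-range"} is 180 views over
#' \[0, 180) (limited angle).  Beam is either \code{"parallel"} or
#' \code{"fan-flat"} (flat virtual detector through the rotation axis).
#'
#' @slot beam beam type.
#' @slot angleStart,angleEnd angular range in degrees, end exclusive.
#' @slot nViews number of equally spaced views (>= 1).
#' @slot nDetectors number of detector bins.
#' @slot detectorSpacing detector pitch in pixel units.
#' @slot sourceAxisDist,axisDetectorDist fan-beam distances in pixel units.
#' @slot protocolTag preset label.
#' @slot imageSize side of the square image the geometry was built for.
#' @exportClass ScanGeometry
setClass("ScanGeometry",
  representation(beam = "character", angleStart = "numeric",
                 angleEnd = "numeric", nViews = "integer",
                 nDetectors = "integer", detectorSpacing = "numeric",
                 sourceAxisDist = "numeric", axisDetectorDist = "numeric",
                 protocolTag = "character", imageSize = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@beam %in% c("parallel", "fan-flat"))
      msg <- c(msg, "beam must be parallel or fan-flat")
    if (object@nViews < 1L) msg <- c(msg, "nViews must be >= 1")
    if (object@angleEnd <= object@angleStart)
      msg <- c(msg, "angleEnd must exceed angleStart")
    if (object@nDetectors < 2L) msg <- c(msg, "nDetectors must be >= 2")
    if (object@beam == "fan-flat" && object@sourceAxisDist <= 0)
      msg <- c(msg, "fan beam needs a positive source-axis distance")
    if (is.null(msg)) TRUE else msg
  })

#' Sinogram: projection data bound to a geometry
#'
#' @slot values numeric matrix, one row per view, one column per detector bin.
#' @slot geometry the \linkS4class{ScanGeometry} the data were simulated under.
#' @slot noiseLevel relative L2 noise level added (0 for clean data).
#' @slot seed seed of the noise stream (NA for clean data).
#' @exportClass Sinogram
setClass("Sinogram",
  representation(values = "matrix", geometry = "ScanGeometry",
                 noiseLevel = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@values) != object@geometry@nViews)
      msg <- c(msg, "row count must equal geometry nViews")
    if (ncol(object@values) != object@geometry@nDetectors)
      msg <- c(msg, "column count must equal geometry nDetectors")
    if (!all(is.finite(object@values))) msg <- c(msg, "non-finite values")
    if (object@noiseLevel < 0) msg <- c(msg, "noiseLevel must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' FilterSpec: FBP filter window
#'
#' @slot window one of \code{"ram-lak"}, \code{"hann"}, \code{"cosine"}.
#' @slot cutoff cutoff as a fraction of the Nyquist frequency, in (0, 1].
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(window = "character", cutoff = "numeric"),
  validity = function(object) {
    if (!object@window %in% c("ram-lak", "hann", "cosine"))
      return("window must be ram-lak, hann or cosine")
    if (object@cutoff <= 0 || object@cutoff > 1)
      return("cutoff must lie in (0, 1]")
    TRUE
  })

#' LayerSpec: one declarative network layer
#'
#' @slot kind \code{"conv"}, \code{"pool"} or \code{"upsample"}.
#' @slot kernel,stride kernel size and stride (pool layers use 2/2).
#' @slot inChannels,outChannels channel counts.
#' @slot normalization whether batch normalisation follows the convolution.
#' @slot activation \code{"relu"}, \code{"tanh"} or \code{"linear"}.
#' @exportClass LayerSpec
setClass("LayerSpec",
  representation(kind = "character", kernel = "integer", stride = "integer",
                 inChannels = "integer", outChannels = "integer",
                 normalization = "logical", activation = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("conv", "pool", "upsample"))
      msg <- c(msg, "kind must be conv, pool or upsample")
    if (object@kernel < 1L || object@stride < 1L)
      msg <- c(msg, "kernel and stride must be >= 1")
    if (!object@activation %in% c("relu", "tanh", "linear"))
      msg <- c(msg, "activation must be relu, tanh or linear")
    if (is.null(msg)) TRUE else msg
  })

#' NetworkSpec: declarative architecture plus its parameter container
#'
#' Canonical machine representation is an op tape (integer matrix) executed by
#' the single-precision convolution engine; \code{layers} mirrors it as a list
#' of \linkS4class{LayerSpec} for inspection and cost accounting.  In residual
#' mode the forward map returns input + subnetwork output (the subnetwork
#' learns the artefact residual); otherwise the network output is the restored
#' image directly.
#'
#' @slot name architecture label.
#' @slot kind \code{"sequential"} or \code{"encoder-decoder"}.
#' @slot residual logical; residual (input + correction) forward contract.
#' @slot tape integer op matrix, one row per engine op.
#' @slot layers list of \linkS4class{LayerSpec}.
#' @slot inputDivisor spatial dims must be divisible by this (2^L for UNets).
#' @slot params flat numeric parameter vector (see engine docs for layout).
#' @slot state batch-norm running statistics.
#' @slot trained logical flag set by \code{\link{trainNetwork}}.
#' @slot meta list of builder metadata (variant, c0, L, n, init seed).
#' @exportClass NetworkSpec
setClass("NetworkSpec",
  representation(name = "character", kind = "character", residual = "logical",
                 tape = "matrix", layers = "list", inputDivisor = "integer",
                 params = "numeric", state = "numeric", trained = "logical",
                 meta = "list"),
  validity = function(object) {
    if (!object@kind %in% c("sequential", "encoder-decoder"))
      return("kind must be sequential or encoder-decoder")
    TRUE
  })

#' RFResult: analytic receptive-field layout of a layer stack
#'
#' @slot rf per-layer receptive fields r_t, starting at r_0 = 1.
#' @slot increments per-layer non-overlap increments A_t.
#' @slot maxRF receptive field at the last layer.
#' @slot inputSide reference input side for the percentage.
#' @slot percentOfInput maxRF^2 / inputSide^2 * 100.
#' @exportClass RFResult
setClass("RFResult",
  representation(rf = "numeric", increments = "numeric", maxRF = "numeric",
                 inputSide = "numeric", percentOfInput = "numeric"),
  validity = function(object) {
    if (length(object@rf) == 0 || object@rf[1] != 1)
      return("receptive field sequence must start at r_0 = 1")
    if (any(diff(object@rf) < 0)) return("r_t must be nondecreasing")
    if (any(object@increments < 0)) return("increments must be >= 0")
    TRUE
  })

#' CostReport: green-AI cost accounting for one architecture
#'
#' FLOPs use the 2-operations-per-multiply-accumulate convention, counting
#' convolution layers only (biases, normalisation and activations excluded).
#'
#' @slot weightParams convolution kernel weights only.
#' @slot allTrainableParams kernels + biases + batch-norm affine terms.
#' @slot flops forward FLOPs at \code{inputSide}.
#' @slot inputSide input side used for the FLOPs figure.
#' @slot convention human-readable statement of the counting convention.
#' @exportClass CostReport
setClass("CostReport",
  representation(weightParams = "numeric", allTrainableParams = "numeric",
                 flops = "numeric", inputSide = "numeric",
                 convention = "character"),
  validity = function(object) {
    if (object@weightParams > object@allTrainableParams)
      return("weightParams cannot exceed allTrainableParams")
    TRUE
  })

#' PairedDataset: FBP inputs paired with their ground truths
#'
#' Every input y was produced from its ground truth by forward projection,
#' optional noise injection and FBP reconstruction with the settings recorded
#' in \code{provenance}.
#'
#' @slot y list of FBP-reconstructed input images.
#' @slot gt list of ground-truth images in \[0, 1\].
#' @slot geometryTag protocol label ("full-range", "half-range", "mixed", ...).
#' @slot noiseLevel relative noise level used in simulation.
#' @slot seeds per-pair noise seeds.
#' @slot split "train" or "test".
#' @slot provenance list with geometry, filter and master seed.
#' @exportClass PairedDataset
setClass("PairedDataset",
  representation(y = "list", gt = "list", geometryTag = "character",
                 noiseLevel = "numeric", seeds = "numeric",
                 split = "character", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@y) < 1L) msg <- c(msg, "dataset must hold >= 1 pair")
    if (length(object@y) != length(object@gt))
      msg <- c(msg, "y and gt must have equal length")
    if (!object@split %in% c("train", "test")) msg <- c(msg, "bad split label")
    if (is.null(msg)) TRUE else msg
  })

#' TrainConfig: optimisation settings
#'
#' The reference preset is 50 epochs, batch size 8, momentum 0.99, learning
#' rate decaying polynomially from 1e-2 to 1e-5, gradient norm clipped at 5;
#' the shallow network preset uses Adam, the UNet preset SGD with Nesterov
#' momentum.
#'
#' @slot optimizer \code{"adam"} or \code{"sgd-nesterov"}.
#' @slot epochs,batchSize integers.
#' @slot momentum Nesterov momentum (ignored by Adam).
#' @slot lrStart,lrEnd,lrPower polynomial decay parameters.
#' @slot gradClip global gradient L2-norm clip.
#' @slot seed shuffling / init seed.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(optimizer = "character", epochs = "integer",
                 batchSize = "integer", momentum = "numeric",
                 lrStart = "numeric", lrEnd = "numeric", lrPower = "numeric",
                 gradClip = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@optimizer %in% c("adam", "sgd-nesterov"))
      msg <- c(msg, "optimizer must be adam or sgd-nesterov")
    if (object@epochs < 1L || object@batchSize < 1L)
      msg <- c(msg, "epochs and batchSize must be >= 1")
    if (object@lrStart <= 0 || object@lrEnd < 0)
      msg <- c(msg, "learning rates must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' MetricsReport: full-reference quality metrics over an evaluation set
#'
#' @slot perImage data.frame with one row per image (re, psnrPaper, psnrStd,
#'   ssim, fsim).
#' @slot means arithmetic means of the per-image columns.
#' @slot n pixel count per image.
#' @slot geometryTag protocol label of the evaluated dataset.
#' @slot method method label (\code{"FBP"} or a network name).
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perImage = "data.frame", means = "numeric", n = "numeric",
                 geometryTag = "character", method = "character"),
  validity = function(object) {
    if (any(object@perImage$re < 0)) return("RE must be >= 0")
    TRUE
  })

#' OODScenario: out-of-domain evaluation settings
#'
#' \code{"unseen-noise"} keeps the in-domain phantom family but doubles the
#' measurement noise (default 2e-2); \code{"unseen-image"} keeps the training
#' noise level (1e-2) but switches to the flat-sharp phantom family.
#'
#' @slot kind \code{"unseen-noise"} or \code{"unseen-image"}.
#' @slot noiseLevel noise level of the scenario.
#' @slot family phantom family evaluated.
#' @slot geometryTag protocol preset.
#' @exportClass OODScenario
setClass("OODScenario",
  representation(kind = "character", noiseLevel = "numeric",
                 family = "character", geometryTag = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("unseen-noise", "unseen-image"))
      msg <- c(msg, "kind must be unseen-noise or unseen-image")
    if (object@kind == "unseen-noise" && object@family != "chest")
      msg <- c(msg, "unseen-noise must use the in-domain (chest) family")
    if (object@kind == "unseen-image" && object@family != "flat-sharp")
      msg <- c(msg, "unseen-image must use the flat-sharp family")
    if (is.null(msg)) TRUE else msg
  })
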