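# Green-AI accounting: receptive fields, parameters, FLOPs.

# extract the (k, s) ladder relevant for the analytic receptive field:
# sequential nets use all layers; encoder-decoder nets use the encoder chain
# down to the bottleneck (convs and pools before the first upsample), which
# carries the maximal receptive field of the architecture.
rfLayerTable <- function(spec) {
  ks <- list()
  for (l in spec@layers) {
    if (l@kind == "upsample") break
    if (l@kind == "conv") ks[[length(ks) + 1]] <- c(l@kernel, l@stride)
    else if (l@kind == "pool") ks[[length(ks) + 1]] <- c(2, 2)
  }
  if (length(ks) == 0) matrix(numeric(0), 0, 2)
  else do.call(rbind, ks)
}

#' Analytic receptive field of a layer stack
#'
#' Applies the layer-wise recursion r_0 = 1, r_t = r_\{t-1\} + A_t with
#' non-overlap increment A_t = (k_t - 1) * prod(s_1..s_\{t-1\}) (the tap
#' spacing of layer t equals the accumulated stride of the layers before
#' it).  The receptive field grows linearly with depth at fixed kernel size
#' and multiplicatively with the accumulated stride, which is why pooling
#' enlarges it so quickly.  Every value is validated against the brute-force
#' perturbation oracle \code{\link{empiricalRF}}, which measures the same
#' quantity on the instantiated network.
#'
#' @param layers a two-column matrix / data.frame of (kernel, stride) rows,
#'   a list of such pairs, or a \linkS4class{NetworkSpec} (for
#'   encoder-decoder networks the encoder chain to the bottleneck is used).
#' @param inputSide reference side for the area percentage (default 512).
#' @return an \linkS4class{RFResult}; an empty stack yields max RF 1.
#' @examples
#' receptiveField(rbind(c(9, 1), c(5, 1), c(3, 1)))  # max RF 15
#' @export
receptiveField <- function(layers, inputSide = 512) {
  if (is(layers, "NetworkSpec")) layers <- rfLayerTable(layers)
  if (is.list(layers) && !is.data.frame(layers))
    layers <- do.call(rbind, layers)
  layers <- as.matrix(layers)
  if (nrow(layers) > 0 && (any(layers[, 1] < 1) || any(layers[, 2] < 1)))
    stop("kernel sizes and strides must be >= 1")
  r <- 1
  rf <- 1
  inc <- numeric(0)
  sprod <- 1
  if (nrow(layers) > 0) for (t in seq_len(nrow(layers))) {
    a <- (layers[t, 1] - 1) * sprod
    sprod <- sprod * layers[t, 2]
    inc <- c(inc, a)
    r <- r + a
    rf <- c(rf, r)
  }
  new("RFResult", rf = rf, increments = inc, maxRF = r,
      inputSide = as.numeric(inputSide),
      percentOfInput = 100 * r^2 / inputSide^2)
}

#' Empirical receptive field by centre-pixel perturbation
#'
#' Brute-force oracle for the analytic recursion: the stack is instantiated
#' in the convolution engine with all kernel weights 1, zero biases,
#' normalisation bypassed and linear activations (so responses stay
#' nonnegative), and single-pixel impulses are scanned along the centre row
#' and column of a zero image.  The number of impulse positions that change
#' the centre output pixel equals the receptive-field side.
#'
#' @param spec a \linkS4class{NetworkSpec} (sequential) or a (kernel, stride)
#'   matrix as for \code{\link{receptiveField}}; stride-2 entries with
#'   kernel 2 are realised as max-pooling.
#' @param inputSide side of the probe image; must comfortably exceed the
#'   receptive field (an error asks for a larger input otherwise).
#' @return integer receptive-field side length.
#' @export
empiricalRF <- function(spec, inputSide = 96L) {
  if (is(spec, "NetworkSpec")) {
    if (spec@kind != "sequential")
      stop("empirical receptive field probing supports sequential stacks")
    layers <- rfLayerTable(spec)
  } else {
    layers <- as.matrix(if (is.list(spec) && !is.data.frame(spec))
      do.call(rbind, spec) else spec)
  }
  rows <- list()
  for (t in seq_len(nrow(layers))) {
    k <- layers[t, 1]; s <- layers[t, 2]
    rows[[t]] <- if (k == 2 && s == 2) tapeRow(2L)
    else tapeRow(1L, as.integer(k), as.integer(s), 1L, 1L, 0L, 0L)
  }
  tape <- do.call(rbind, rows)
  colnames(tape) <- TAPE_COLS
  lay <- cpp_param_layout(tape, as.integer(inputSide), as.integer(inputSide))
  params <- numeric(lay$nParams)
  for (i in seq_along(lay$wOff))
    params[lay$wOff[i] + seq_len(lay$wLen[i]) - 1] <- 1
  side <- as.integer(inputSide)
  centre <- floor(side / 2)
  probe <- function(alongRow) {
    X <- matrix(0, side * side, side)
    for (j in seq_len(side)) {
      idx <- if (alongRow) centre + side * (j - 1)       # vary column
      else j + side * (centre - 1)                        # vary row
      X[idx, j] <- 1
    }
    out <- cpp_net_forward(tape, side, side, params, numeric(0), X, FALSE)
    os <- as.integer(sqrt(nrow(out)))
    oc <- floor(os / 2)
    hits <- which(out[oc + os * (oc - 1), ] > 0)
    if (length(hits) && (min(hits) <= 1 || max(hits) >= side))
      stop("receptive field reaches the probe border; use a larger inputSide")
    length(hits)
  }
  max(probe(TRUE), probe(FALSE))
}

costConvention <- "2 ops per multiply-accumulate, conv layers only"

#' Count network parameters
#'
#' Each convolution contributes k^2 * c_in * c_out kernel weights plus c_out
#' biases; batch normalisation contributes 2 affine terms per channel;
#' pooling and upsampling contribute nothing.  The headline figure is the
#' kernel-weight count; biases and normalisation terms are included in
#' \code{allTrainableParams}.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @return a \linkS4class{CostReport} (FLOPs field 0; see
#'   \code{\link{countFlops}}).
#' @export
countParameters <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  w <- a <- 0
  for (l in spec@layers) {
    if (l@kind != "conv") next
    kw <- l@kernel^2 * l@inChannels * l@outChannels
    w <- w + kw
    a <- a + kw + l@outChannels + if (l@normalization) 2 * l@outChannels else 0
  }
  new("CostReport", weightParams = w, allTrainableParams = a, flops = 0,
      inputSide = 0, convention = costConvention)
}

#' Count forward FLOPs
#'
#' Sums 2 * H_t * W_t * k_t^2 * c_in * c_out over convolution layers, with
#' H_t, W_t the spatial dimensions after the preceding pools/upsamples.  For
#' any stride-1 pool-free network this equals
#' 2 * pixels * weightParams exactly.
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param inputSide input image side.
#' @return a \linkS4class{CostReport} with the FLOPs field set.
#' @export
countFlops <- function(spec, inputSide = 512) {
  stopifnot(is(spec, "NetworkSpec"))
  if (inputSide %% spec@inputDivisor != 0)
    stop("inputSide must be divisible by ", spec@inputDivisor)
  h <- w <- inputSide
  fl <- 0
  for (l in spec@layers) {
    if (l@kind == "conv") {
      ho <- h %/% l@stride; wo <- w %/% l@stride
      fl <- fl + 2 * ho * wo * l@kernel^2 * l@inChannels * l@outChannels
      h <- ho; w <- wo
    } else if (l@kind == "pool") { h <- h %/% 2; w <- w %/% 2 }
    else if (l@kind == "upsample") { h <- h * 2; w <- w * 2 }
  }
  cp <- countParameters(spec)
  new("CostReport", weightParams = cp@weightParams,
      allTrainableParams = cp@allTrainableParams, flops = fl,
      inputSide = as.numeric(inputSide), convention = costConvention)
}

#' Full cost / receptive-field analysis of an architecture
#'
#' @param spec a \linkS4class{NetworkSpec}.
#' @param inputSide input side for FLOPs and the RF percentage.
#' @param path optional path to write the analysis as JSON.
#' @return list with elements \code{cost} (\linkS4class{CostReport}) and
#'   \code{rf} (\linkS4class{RFResult}).
#' @export
analyzeNetwork <- function(spec, inputSide = 512, path = NULL) {
  cost <- countFlops(spec, inputSide)
  rf <- receptiveField(spec, inputSide)
  if (!is.null(path)) {
    jsonlite::write_json(list(
      network = spec@name,
      weightParams = cost@weightParams,
      allTrainableParams = cost@allTrainableParams,
      flops = cost@flops, inputSide = inputSide,
      convention = cost@convention,
      rf = rf@rf, maxRF = rf@maxRF, percentOfInput = rf@percentOfInput),
      path, auto_unbox = TRUE, digits = NA)
  }
  list(cost = cost, rf = rf)
}
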