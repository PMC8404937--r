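# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-item seed stream, kept below 2^31.
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483587) + 1L
}

assertSquare <- function(img, what = "image") {
  if (!is.matrix(img) || nrow(img) != ncol(img))
    stop(what, " must be a square matrix", call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(img)
}

#' Affinely rescale an image to the unit interval
#'
#' Maps the minimum to 0 and the maximum to 1.  A constant image maps to all
#' zeros (degenerate rule, so that a flat field never becomes all ones).
#'
#' @param img numeric matrix with finite entries.
#' @return matrix of the same dimension with values in \[0, 1\].
#' @examples
#' m <- matrix(c(2, 3, 4, 3), 2)
#' range(scaleToUnit(m))
#' @export
scaleToUnit <- function(img) {
  if (!all(is.finite(img))) stop("image contains non-finite values")
  rng <- range(img)
  if (rng[1] == rng[2]) return(array(0, dim(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}
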