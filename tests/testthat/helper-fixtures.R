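# shared fixtures, all generated in code

# dense parallel-beam geometry over half a turn
parallelGeom <- function(size, nViews = 180L) {
  makeGeometry("custom", size, beam = "parallel", nViews = nViews,
               angleStart = 0, angleEnd = 180)
}

# deterministic noisy-pair fixture on the unit square
ssimFixture <- function() {
  set.seed(42)
  gt <- matrix(runif(1024), 32, 32)
  x <- gt + matrix(rnorm(1024, 0, 0.05), 32, 32)
  list(x = x, gt = gt)
}

# smooth synthetic image for metric monotonicity checks
smoothFixture <- function(n = 64) {
  cc <- seq(-1, 1, length.out = n)
  outer(cc, cc, function(y, x) 0.5 + 0.3 * sin(3 * x) * cos(2 * y) +
          0.2 * exp(-((x - 0.2)^2 + y^2) * 8))
}

# box blur with the given radius (independent of package code)
boxBlur <- function(img, r) {
  if (r == 0) return(img)
  n <- nrow(img)
  out <- img
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ri <- max(1, i - r):min(n, i + r)
    rj <- max(1, j - r):min(n, j + r)
    out[i, j] <- mean(img[ri, rj])
  }
  out
}

# values on the single-precision grid, so float round trips are exact
floatGrid <- function(m) {
  matrix(round(m * 256) / 256, nrow(m), ncol(m))
}

# tiny trained 3L-SSNet shared by out-of-domain tests (computed once)
.testEnv <- new.env()
tinyTrained3L <- function() {
  if (is.null(.testEnv$net)) {
    sz <- 64L
    gts <- generateDataset(40, phantomSpec("chest", sz), seed = 31)
    geom <- makeGeometry("full-range", sz)
    pairs <- buildPairs(gts, geom, 1e-2, seed = 32)
    fit <- trainNetwork(build3LSSNet(seed = 5), pairs,
                        deskTrainConfig("3l-ssnet", epochs = 6L, seed = 33))
    .testEnv$net <- fit$network
  }
  .testEnv$net
}
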