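# full-reference image quality metrics

test_that("relative error satisfies its axioms and scale law", {
  gt <- smoothFixture(32)
  expect_equal(relativeError(gt, gt), 0)
  expect_equal(relativeError(matrix(0, 32, 32), gt), 1)
  expect_equal(relativeError(2 * gt, gt), 1)
  set.seed(1)
  x <- gt + matrix(rnorm(1024, 0, 0.1), 32)
  expect_equal(relativeError(3 * x, 3 * gt), relativeError(x, gt))
  expect_equal(relativeError(x, gt, squared = TRUE), relativeError(x, gt)^2)
  expect_error(relativeError(x, matrix(0, 32, 32)), "all zero")
})

test_that("the two PSNR conventions differ by exactly 10 log10(n)", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(c(16, 32, 64), 1)
    gt <- matrix(runif(n * n), n)
    x <- gt + matrix(rnorm(n * n, 0, 0.05), n)
    p <- psnr(x, gt)
    expect_equal(p[["paper"]] - p[["standard"]], 10 * log10(n * n))
  }
})

test_that("PSNR closed-form behaviours hold", {
  gt <- matrix(runif(16), 4, 4)
  gt <- gt / max(gt)                      # max(gt) = 1, n = 16
  d <- matrix(c(rep(0, 15), 1), 4, 4)     # ||d|| = 1
  p1 <- psnr(gt + d, gt)
  p2 <- psnr(gt + 2 * d, gt)
  expect_equal(p1[["paper"]] - p2[["paper"]], 20 * log10(2))
  expect_equal(p1[["standard"]] - p2[["standard"]], 20 * log10(2))
  # n = 4, max 1, error norm 4 -> paper PSNR = 20 log10(4 * 1 / 4) = 0
  g2 <- diag(1, 2) * 0 + matrix(c(1, 0, 0, 0), 2)
  x2 <- g2 + matrix(2, 2, 2)
  expect_equal(psnr(x2, g2)[["paper"]], 0)
  expect_equal(psnr(gt, gt), c(paper = Inf, standard = Inf))
})

test_that("SSIM matches the reference implementation on a fixture", {
  fx <- ssimFixture()
  expect_equal(ssim(fx$gt, fx$gt), 1)
  # frozen value computed once with the scikit-image implementation
  # (gaussian_weights, sigma 1.5, no sample covariance, data_range of gt)
  expect_equal(ssim(fx$x, fx$gt), 0.9843145377, tolerance = 1e-6)
})

test_that("SSIM collapses for structureless images and decays with noise", {
  fx <- ssimFixture()
  flat <- matrix(mean(fx$gt), 32, 32)
  expect_lt(ssim(flat, fx$gt), 0.5)
  gt <- smoothFixture(64)
  vals <- vapply(c(0.01, 0.05, 0.1), function(s) {
    set.seed(7)
    ssim(gt + matrix(rnorm(4096, 0, s), 64), gt, dataRange = 1)
  }, 1.0)
  expect_true(all(diff(vals) < 0))
})

test_that("SSIM is symmetric under a fixed data range", {
  fx <- ssimFixture()
  expect_equal(ssim(fx$x, fx$gt, dataRange = 1),
               ssim(fx$gt, fx$x, dataRange = 1))
})

test_that("FSIM satisfies its axioms and decays with blur", {
  gt <- smoothFixture(64)
  expect_equal(fsim(gt, gt), 1)
  set.seed(3)
  for (i in 1:3) {
    x <- gt + matrix(rnorm(4096, 0, runif(1, 0.01, 0.3)), 64)
    v <- fsim(x, gt)
    expect_gt(v, 0)
    expect_lte(v, 1)
  }
  vals <- vapply(c(0, 2, 4), function(r) fsim(boxBlur(gt, r), gt), 1.0)
  expect_true(all(diff(vals) < 0))
})

test_that("evaluateMethod aggregates per-image metrics", {
  gts <- generateDataset(2, phantomSpec("chest", 32), seed = 5)
  perfect <- new("PairedDataset", y = gts, gt = gts, geometryTag = "custom",
                 noiseLevel = 0, seeds = numeric(2), split = "test",
                 provenance = list())
  rep <- evaluateMethod(NULL, perfect)
  expect_equal(metricMeans(rep)[["re"]], 0)
  expect_equal(metricMeans(rep)[["ssim"]], 1)
  expect_identical(rep@method, "FBP")
  single <- new("PairedDataset", y = gts[1], gt = list(smoothFixture(32)),
                geometryTag = "custom", noiseLevel = 0, seeds = 0,
                split = "test", provenance = list())
  r1 <- evaluateMethod(NULL, single)
  expect_equal(metricMeans(r1)[["re"]], metricTable(r1)$re[1])
  tab <- metricsTable(rep, r1)
  expect_equal(names(tab), c("method", "geometry", "RE", "PSNR", "PSNR_std",
                             "SSIM", "FSIM"))
  expect_equal(nrow(tab), 2)
})
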