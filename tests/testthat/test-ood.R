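# out-of-domain protocol

test_that("scenario invariants bind noise level and image family", {
  un <- oodScenario("unseen-noise")
  expect_equal(un@noiseLevel, 2e-2)
  expect_identical(un@family, "chest")
  ui <- oodScenario("unseen-image")
  expect_equal(ui@noiseLevel, 1e-2)
  expect_identical(ui@family, "flat-sharp")
})

test_that("an untrained model is rejected", {
  expect_error(runOOD(build3LSSNet(), oodScenario("unseen-noise")),
               "trained")
})

test_that("unseen-noise degrades FBP relative to in-domain inputs", {
  net <- tinyTrained3L()
  res <- runOOD(net, oodScenario("unseen-noise"), imageSize = 64L,
                nImages = 4L, seed = 51)
  expect_gt(metricMeans(res$oodFBP)[["re"]],
            metricMeans(res$indomainFBP)[["re"]])
  expect_named(res$deltas, c("modelRE", "modelSSIM", "fbpRE", "fbpSSIM"))
})

test_that("unseen-image outputs stay finite and bounded", {
  net <- tinyTrained3L()
  res <- runOOD(net, oodScenario("unseen-image"), imageSize = 64L,
                nImages = 4L, seed = 52)
  expect_true(all(is.finite(unlist(metricMeans(res$oodModel)))))
  expect_gt(metricMeans(res$oodModel)[["ssim"]], 0)
  # the paired in-domain baseline is always part of the report
  expect_s4_class(res$indomainModel, "MetricsReport")
  expect_s4_class(res$indomainFBP, "MetricsReport")
})
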