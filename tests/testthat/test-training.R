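# paired-dataset assembly, loss, schedule, optimisation

test_that("buildPairs runs the simulation pipeline per image", {
  disk <- diskPhantom(128, 40)
  ds <- buildPairs(list(disk), parallelGeom(128, 180L), noiseLevel = 0)
  expect_equal(nPairs(ds), 1)
  expect_lt(relativeError(pairInputs(ds)[[1]], disk), 0.05)
  g <- parallelGeom(64, 120L)
  gts <- generateDataset(3, phantomSpec("chest", 64), seed = 2)
  d3 <- buildPairs(gts, g, 1e-2, seed = 7)
  expect_equal(nPairs(d3), 3)
  d3b <- buildPairs(gts, g, 1e-2, seed = 7)
  expect_identical(d3@y, d3b@y)
  expect_error(buildPairs(gts, parallelGeom(32), 1e-2), "does not match")
})

test_that("mergePairs concatenates and tags mixed protocols", {
  gts <- generateDataset(2, phantomSpec("chest", 32), seed = 3)
  a <- buildPairs(gts, makeGeometry("full-range", 32), 1e-2, seed = 1)
  b <- buildPairs(gts, makeGeometry("half-range", 32), 1e-2, seed = 2)
  m <- mergePairs(a, b)
  expect_equal(nPairs(m), 4)
  expect_equal(m@geometryTag, "mixed")
})

test_that("the loss is the per-image summed squared error", {
  a <- matrix(0, 4, 4)
  b <- a
  expect_equal(lossL2(a, b), 0)
  b[1, 1] <- 3
  b[2, 2] <- 4
  expect_equal(lossL2(a, b), 25)
  expect_equal(lossL2(a, b), lossL2(b, a))
  expect_error(lossL2(a, matrix(0, 3, 3)), "mismatch")
})

test_that("the learning rate follows polynomial decay between endpoints", {
  cfg <- trainConfig("adam")
  expect_equal(lrSchedule(0, 100, cfg), 1e-2)
  expect_equal(lrSchedule(100, 100, cfg), 1e-5)
  lrs <- vapply(0:100, lrSchedule, 1.0, totalSteps = 100, cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(lrSchedule(5, 0, cfg), cfg@lrStart)
  p2 <- trainConfig("adam", lrPower = 2)
  expect_lt(lrSchedule(50, 100, p2), lrSchedule(50, 100, cfg))
})

test_that("training reduces the empirical loss", {
  set.seed(11)
  gts <- generateDataset(12, phantomSpec("chest", 32), seed = 12)
  ds <- buildPairs(gts, makeGeometry("full-range", 32), 1e-2, seed = 13)
  fit <- trainNetwork(build3LSSNet(seed = 1), ds,
                      trainConfig("adam", epochs = 4L, seed = 2))
  expect_lt(fit$history$loss[4], fit$history$loss[1])
  expect_true(fit$network@trained)
  expect_equal(nrow(fit$history), 4)
})

test_that("on the identity task the learned residual shrinks", {
  gts <- generateDataset(8, phantomSpec("chest", 32), seed = 21)
  ds <- new("PairedDataset", y = gts, gt = gts, geometryTag = "custom",
            noiseLevel = 0, seeds = numeric(8), split = "train",
            provenance = list())
  net <- buildResUNet(c0 = 4, L = 2, n = 2, seed = 3)
  set.seed(4)   # perturb the zero-initialised head so the residual is active
  net@params <- net@params + rnorm(length(net@params), 0, 0.05)
  res0 <- mean(vapply(gts, function(y)
    mean(abs(netForward(net, y, batchStats = TRUE) - y)), 1.0))
  fit <- trainNetwork(net, ds, trainConfig("sgd-nesterov", epochs = 5L,
                                           seed = 5))
  res1 <- mean(vapply(gts, function(y)
    mean(abs(netForward(fit$network, y) - y)), 1.0))
  expect_lt(res1, res0)
})

test_that("training is deterministic given the config seed", {
  gts <- generateDataset(6, phantomSpec("chest", 32), seed = 31)
  ds <- buildPairs(gts, makeGeometry("half-range", 32), 1e-2, seed = 32)
  cfg <- trainConfig("adam", epochs = 3L, seed = 7)
  f1 <- trainNetwork(build3LSSNet(seed = 9), ds, cfg)
  f2 <- trainNetwork(build3LSSNet(seed = 9), ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$network@params, f2$network@params)
})

test_that("presets encode the reference optimisation settings", {
  p <- paperTrainConfig("resunet")
  expect_identical(p@optimizer, "sgd-nesterov")
  expect_equal(p@epochs, 50L)
  expect_equal(p@batchSize, 8L)
  expect_equal(p@momentum, 0.99)
  expect_equal(c(p@lrStart, p@lrEnd), c(1e-2, 1e-5))
  expect_equal(p@gradClip, 5)
  expect_identical(paperTrainConfig("3l-ssnet")@optimizer, "adam")
  expect_equal(deskTrainConfig("resunet")@epochs, 15L)
})
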