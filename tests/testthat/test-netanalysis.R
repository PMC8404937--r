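# receptive-field calculus and cost accounting

test_that("receptive-field recursion reproduces hand-computed ladders", {
  r <- receptiveField(rbind(c(9, 1), c(5, 1), c(3, 1)))
  expect_equal(r@rf, c(1, 9, 13, 15))
  expect_equal(r@maxRF, 15)
  expect_equal(r@percentOfInput, 100 * 15^2 / 512^2)
  expect_equal(receptiveField(rbind(c(1, 1)))@maxRF, 1)
  expect_equal(receptiveField(matrix(numeric(0), 0, 2))@maxRF, 1)
  # pooled stack: value verified against the perturbation oracle
  m <- rbind(c(3, 1), c(2, 2), c(3, 1))
  expect_equal(receptiveField(m)@maxRF, 8)
  expect_equal(empiricalRF(m, 64L), 8)
  expect_error(receptiveField(rbind(c(0, 1))), ">= 1")
})

test_that("receptive field grows linearly with depth, faster with pooling", {
  depths <- c(2, 4, 8)
  rfs <- vapply(depths, function(d)
    receptiveField(matrix(rep(c(3, 1), d), ncol = 2, byrow = TRUE))@maxRF, 1.0)
  expect_equal(rfs, 1 + 2 * depths)            # linear in depth at k = 3
  pooled <- receptiveField(rbind(c(3, 1), c(2, 2), c(3, 1), c(2, 2), c(3, 1)))
  expect_gt(pooled@maxRF, receptiveField(matrix(rep(c(3, 1), 3),
                                                ncol = 2, byrow = TRUE))@maxRF)
})

test_that("empirical probing agrees with the recursion on random stacks", {
  expect_equal(empiricalRF(rbind(c(3, 1))), 3)
  expect_equal(empiricalRF(build3LSSNet()), 15)
  expect_equal(empiricalRF(build3LSSNet("as-text")), 15)
  set.seed(42)
  tried <- 0
  while (tried < 10) {
    nl <- sample(2:5, 1)
    rows <- list()
    npool <- 0
    for (t in seq_len(nl)) {
      if (npool < 2 && runif(1) < 0.3) {
        rows[[t]] <- c(2, 2); npool <- npool + 1
      } else rows[[t]] <- c(sample(c(1, 3, 5, 7), 1), 1)
    }
    m <- do.call(rbind, rows)
    a <- receptiveField(m)@maxRF
    if (a > 63) next
    tried <- tried + 1
    expect_equal(empiricalRF(m, 96L), a, info = paste(m, collapse = ","))
  }
})

test_that("probing a too-small input is rejected with guidance", {
  expect_error(empiricalRF(rbind(c(9, 1), c(9, 1), c(9, 1)), 24L),
               "larger inputSide")
})

test_that("parameter counting follows the per-layer formulas", {
  one <- buildSequentialNet(list(layerSpec("conv", 3, 1, 1, 1)))
  cp <- countParameters(one)
  expect_equal(cp@weightParams, 9)
  expect_equal(cp@allTrainableParams, 10)
  expect_equal(countParameters(build3LSSNet())@weightParams, 85696)
  expect_equal(countParameters(build3LSSNet("as-text"))@weightParams, 421120)
  # batch-norm affine terms and biases enter the trainable total only
  tc <- countParameters(build3LSSNet())
  expect_equal(tc@allTrainableParams, 85696 + 128 + 64 + 1 + 2 * (128 + 64))
})

test_that("FLOPs counting follows the 2-ops-per-MAC convention", {
  one <- buildSequentialNet(list(layerSpec("conv", 3, 1, 1, 1)))
  expect_equal(countFlops(one, 10)@flops, 1800)
  tc <- build3LSSNet()
  expect_equal(countFlops(tc, 512)@flops, 2 * 512^2 * 85696)
  # halving the input side quarters the FLOPs of a stride-1 network
  expect_equal(countFlops(tc, 256)@flops, countFlops(tc, 512)@flops / 4)
  # closed form for any stride-1 pool-free stack
  net <- buildSequentialNet(list(layerSpec("conv", 5, 1, 1, 3, TRUE, "relu"),
                                 layerSpec("conv", 3, 1, 3, 2)))
  expect_equal(countFlops(net, 32)@flops,
               2 * 32^2 * countParameters(net)@weightParams)
})

test_that("analyzeNetwork emits a machine-readable report", {
  f <- tempfile(fileext = ".json")
  res <- analyzeNetwork(build3LSSNet(), inputSide = 128, path = f)
  js <- jsonlite::read_json(f)
  expect_equal(js$weightParams, 85696)
  expect_equal(js$maxRF, 15)
  expect_equal(js$flops, res$cost@flops)
  unlink(f)
})
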