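# architecture builders and the forward contract

test_that("3L-SSNet variants have the published layer structure", {
  tc <- build3LSSNet("table-consistent")
  expect_equal(vapply(tc@layers, function(l) l@kernel, 1L), c(9L, 3L, 5L))
  expect_equal(vapply(tc@layers, function(l) l@outChannels, 1L),
               c(128L, 64L, 1L))
  at <- build3LSSNet("as-text")
  expect_equal(vapply(at@layers, function(l) l@kernel, 1L), c(9L, 5L, 3L))
  expect_equal(vapply(at@layers, function(l) l@outChannels, 1L),
               c(128L, 128L, 1L))
  for (net in list(tc, at)) {
    expect_false(net@residual)
    expect_true(all(vapply(net@layers, function(l) l@stride == 1L, TRUE)))
    # hidden blocks carry batch-norm + relu, the output conv is linear
    expect_true(all(vapply(net@layers[1:2], function(l) l@normalization, TRUE)))
    expect_identical(net@layers[[3]]@activation, "linear")
    expect_false(net@layers[[3]]@normalization)
    expect_equal(receptiveField(net)@maxRF, 15)
  }
})

test_that("ResUNet has the mirrored encoder-decoder with channel doubling", {
  net <- buildResUNet(c0 = 64)
  kinds <- vapply(net@layers, function(l) l@kind, "")
  convs <- net@layers[kinds == "conv"]
  chans <- vapply(convs, function(l) l@outChannels, 1L)
  expect_true(all(c(64, 128, 256, 512, 1024) %in% chans))
  expect_equal(sum(kinds == "pool"), 4)
  expect_equal(sum(kinds == "upsample"), 4)
  # symmetric level structure: n convs per encoder level and per decoder level
  expect_equal(sum(chans == 1024), 3)             # bottleneck level
  expect_equal(length(convs), 2 * 4 * 3 + 3 + 1)  # enc+dec levels + bottom + out
  expect_true(net@residual)
  expect_identical(convs[[length(convs)]]@activation, "tanh")
  expect_equal(net@inputDivisor, 16L)
})

test_that("forward preserves spatial dimensions and enforces divisibility", {
  net <- buildResUNet(c0 = 4, seed = 1)
  y <- matrix(runif(32 * 32), 32, 32)
  out <- netForward(net, y)
  expect_equal(dim(out), c(32, 32))
  expect_error(netForward(net, matrix(0, 24, 24)), "divisible by 16")
  n3 <- build3LSSNet(seed = 1)
  expect_equal(dim(netForward(n3, matrix(runif(24 * 24), 24))), c(24, 24))
})

test_that("residual forward with a zeroed final layer is the identity", {
  net <- buildResUNet(c0 = 4, L = 2, n = 2, seed = 3)
  lay <- greenCT:::cpp_param_layout(net@tape, 32L, 32L)
  i <- length(lay$wOff)   # final conv: zero weights and bias
  net@params[lay$wOff[i] + seq_len(lay$wLen[i]) - 1] <- 0
  net@params[lay$bOff[i] + seq_len(lay$cout[i]) - 1] <- 0
  y <- floatGrid(matrix(runif(32 * 32), 32, 32))
  expect_identical(netForward(net, y), y)
})

test_that("residual outputs never depart from the input by more than one", {
  net <- buildResUNet(c0 = 4, L = 2, n = 2, seed = 4)
  set.seed(9)
  net@params <- net@params + rnorm(length(net@params), 0, 0.5)
  y <- matrix(runif(32 * 32, -1, 2), 32, 32)
  out <- netForward(net, y)
  expect_lte(max(abs(out - y)), 1 + 1e-6)
})

test_that("an all-zero image stays zero through a zero-bias direct net", {
  net <- build3LSSNet(seed = 6)      # biases and betas start at zero
  out <- netForward(net, matrix(0, 32, 32))
  expect_equal(max(abs(out)), 0)
})

test_that("network serialization round-trips architecture and weights", {
  net <- buildResUNet(c0 = 4, L = 1, n = 2, seed = 8)
  f <- tempfile(fileext = ".rds")
  writeNetwork(net, f)
  back <- readNetwork(f)
  expect_identical(back@params, net@params)
  expect_identical(back@tape, net@tape)
  expect_identical(back@state, net@state)
  expect_identical(back@residual, net@residual)
  js <- jsonlite::fromJSON(networkToJSON(net))
  expect_equal(js$name, "ResUNet")
  expect_equal(nrow(js$layers), length(net@layers))
  unlink(f)
})

test_that("forward is translation-consistent away from borders", {
  net <- buildResUNet(c0 = 4, L = 1, n = 2, seed = 10)
  n <- 32
  base <- matrix(0.5, n, n)
  blob <- function(cx) {
    img <- base
    img[10:14, cx:(cx + 4)] <- 0.9
    img
  }
  o1 <- netForward(net, blob(10))
  o2 <- netForward(net, blob(12))   # stride-aligned shift by 2
  # interior of the shifted output matches the shifted interior
  expect_lt(max(abs(o1[8:18, 8:18] - o2[8:18, 10:20])), 1e-4)
})
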