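# convolution engine: analytic gradients against finite differences

test_that("engine gradients match central finite differences", {
  tapeRow <- greenCT:::tapeRow
  rows <- rbind(tapeRow(4L, slot = 0L),
                tapeRow(1L, 3L, 1L, 1L, 4L, 1L, 1L),   # conv-bn-relu
                tapeRow(4L, slot = 1L),
                tapeRow(2L),                            # pool
                tapeRow(1L, 3L, 1L, 4L, 8L, 1L, 1L),
                tapeRow(3L),                            # upsample
                tapeRow(1L, 3L, 1L, 8L, 4L, 1L, 1L),
                tapeRow(5L, slot = 1L),                 # additive skip
                tapeRow(1L, 3L, 1L, 4L, 1L, 0L, 2L),   # tanh head
                tapeRow(5L, slot = 0L))                 # global residual
  colnames(rows) <- greenCT:::TAPE_COLS
  H <- 8L
  lay <- greenCT:::cpp_param_layout(rows, H, H)
  np <- lay$nParams
  set.seed(1)
  par <- rnorm(np, 0, 0.3)
  st <- numeric(lay$nState)
  off <- 0
  for (i in seq_along(lay$wOff)) {
    if (is.na(lay$gOff[i])) next
    par[lay$gOff[i] + seq_len(lay$cout[i]) - 1] <- runif(lay$cout[i], 0.5, 1.5)
    st[off + lay$cout[i] + seq_len(lay$cout[i])] <- 1
    off <- off + 2 * lay$cout[i]
  }
  B <- 3L
  X <- matrix(runif(H * H * B), H * H, B)
  GT <- matrix(runif(H * H * B), H * H, B)
  res <- greenCT:::cpp_net_train_step(rows, H, H, par, st, X, GT)
  lossAt <- function(p)
    greenCT:::cpp_net_train_step(rows, H, H, p, st, X, GT)$loss
  set.seed(2)
  idx <- sample(np, 50)
  h <- 1e-3
  num <- vapply(idx, function(j) {
    p1 <- par; p1[j] <- p1[j] + h
    p2 <- par; p2[j] <- p2[j] - h
    (lossAt(p1) - lossAt(p2)) / (2 * h)
  }, 1.0)
  scale <- max(abs(res$grad[idx]))
  expect_lt(max(abs(num - res$grad[idx])) / scale, 5e-3)
})

test_that("batch-norm running statistics move toward batch statistics", {
  net <- build3LSSNet(seed = 1)
  H <- 16L
  set.seed(3)
  X <- matrix(runif(H * H * 4, 0.4, 0.6), H * H, 4)
  st0 <- net@state
  res <- greenCT:::cpp_net_train_step(net@tape, H, H, net@params, st0, X, X)
  expect_false(identical(res$state, st0))
  # repeated exposure converges the running mean of the first layer
  st <- st0
  for (i in 1:60)
    st <- greenCT:::cpp_net_train_step(net@tape, H, H, net@params, st,
                                       X, X)$state
  out <- greenCT:::cpp_net_forward(net@tape, H, H, net@params, st, X, TRUE)
  outR <- greenCT:::cpp_net_forward(net@tape, H, H, net@params, st, X, FALSE)
  expect_lt(mean(abs(out - outR)), 0.05)
})
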