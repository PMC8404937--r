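# geometry presets, forward projection, measurement noise

test_that("protocol presets match the two scan designs", {
  gf <- makeGeometry("full-range", 512)
  expect_equal(nViews(gf), 360L)
  ang <- geometryAngles(gf)
  expect_equal(diff(ang)[1], 1)               # 1-degree spacing
  expect_equal(range(ang), c(0, 359))
  gh <- makeGeometry("half-range", 512)
  expect_equal(nViews(gh), 180L)
  expect_lt(max(geometryAngles(gh)), 180)
  g1 <- makeGeometry("custom", 64, nViews = 1)
  expect_equal(nViews(g1), 1L)
})

test_that("detector count default covers the diagonal, rounded to even", {
  g <- makeGeometry("full-range", 128)
  expect_equal(nDetectors(g), 182L)           # ceil(sqrt(2)*128) -> even
  expect_equal(nDetectors(makeGeometry("full-range", 512)), 726L)
})

test_that("forward projection is linear and zero maps to zero", {
  g <- parallelGeom(48, 40L)
  z <- forwardProject(matrix(0, 48, 48), g)
  expect_equal(max(abs(sinogramValues(z))), 0)
  set.seed(1)
  a <- matrix(runif(48 * 48), 48)
  b <- matrix(runif(48 * 48), 48)
  sab <- sinogramValues(forwardProject(2 * a + 3 * b, g))
  sa <- sinogramValues(forwardProject(a, g))
  sb <- sinogramValues(forwardProject(b, g))
  expect_lt(max(abs(sab - 2 * sa - 3 * sb)), 1e-9)
})

test_that("disk projections match the analytic chord length", {
  N <- 128
  R <- 40
  disk <- diskPhantom(N, R)
  g <- parallelGeom(N, 30L)
  sino <- sinogramValues(forwardProject(disk, g))
  off <- greenCT:::detectorOffsets(scanGeometry(forwardProject(disk, g)))
  chord <- ifelse(abs(off) <= R, 2 * sqrt(pmax(R^2 - off^2, 0)), 0)
  for (v in c(1, 10, 25))
    expect_lt(max(abs(sino[v, ] - chord)), 2)  # within 2 pixel lengths
})

test_that("a plug-in projector backend is honoured and validated", {
  g <- parallelGeom(32, 10L)
  img <- diskPhantom(32, 10)
  ref <- forwardProject(img, g)
  viaBackend <- forwardProject(img, g, backend = function(im, gm)
    sinogramValues(forwardProject(im, gm)))
  expect_identical(sinogramValues(viaBackend), sinogramValues(ref))
  expect_error(forwardProject(img, g, backend = function(im, gm)
    matrix(0, 2, 2)), "nViews x nDetectors")
})

test_that("rotationally symmetric phantoms give identical view rows", {
  disk <- diskPhantom(96, 30)
  sino <- sinogramValues(forwardProject(disk, parallelGeom(96, 36L)))
  ref <- colMeans(sino)
  expect_lt(max(abs(sweep(sino, 2, ref))), 2)
})

test_that("total mass is preserved across views (parallel beam)", {
  img <- generatePhantom(phantomSpec("chest", 64, seed = 2))
  sino <- sinogramValues(forwardProject(img, parallelGeom(64, 24L)))
  mass <- rowSums(sino)
  expect_lt(max(abs(mass - sum(img))) / sum(img), 0.01)
})

test_that("noise level is the relative L2 perturbation", {
  img <- generatePhantom(phantomSpec("chest", 64, seed = 4))
  sino <- forwardProject(img, makeGeometry("full-range", 64))
  expect_gte(length(sinogramValues(sino)), 1e4)
  expect_identical(addNoise(sino, 0), sino)
  noisy <- addNoise(sino, 1e-2, seed = 5)
  rel <- sqrt(sum((sinogramValues(noisy) - sinogramValues(sino))^2) /
              sum(sinogramValues(sino)^2))
  expect_lt(abs(rel - 1e-2) / 1e-2, 0.05)
  expect_identical(sinogramValues(addNoise(sino, 1e-2, seed = 5)),
                   sinogramValues(noisy))
  expect_false(identical(sinogramValues(addNoise(sino, 1e-2, seed = 6)),
                         sinogramValues(noisy)))
  expect_error(addNoise(sino, -0.1), "level")
})

test_that("noise is additive and mean-zero across realizations", {
  img <- diskPhantom(48, 15)
  sino <- forwardProject(img, parallelGeom(48, 20L))
  clean <- sinogramValues(sino)
  acc <- 0
  for (s in 1:25) acc <- acc + sinogramValues(addNoise(sino, 5e-2, seed = s))
  one <- sinogramValues(addNoise(sino, 5e-2, seed = 1))
  errMean <- sqrt(sum((acc / 25 - clean)^2))
  errOne <- sqrt(sum((one - clean)^2))
  expect_lt(errMean, errOne / 3)
})
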