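# ramp filtering and filtered back-projection

test_that("ramp filtering is linear and suppresses DC exactly", {
  g <- parallelGeom(48, 10L)
  zero <- forwardProject(matrix(0, 48, 48), g)
  expect_equal(max(abs(sinogramValues(rampFilter(zero)))), 0)
  const <- zero
  const@values <- matrix(3, nViews(g), nDetectors(g))
  filt <- sinogramValues(rampFilter(const))
  expect_lt(abs(mean(filt[1, ])), 1e-6 * 3)
})

test_that("ram-lak frequency response is |f| up to the cutoff", {
  w <- rampFrequencyResponse(filterSpec("ram-lak", 1), 64)
  k <- 0:63
  f <- ifelse(k <= 32, k, k - 64) / 64
  expect_equal(w, abs(f))
  wc <- rampFrequencyResponse(filterSpec("ram-lak", 0.5), 64)
  expect_equal(wc[abs(f) <= 0.25], abs(f)[abs(f) <= 0.25])
  expect_true(all(wc[abs(f) > 0.25] == 0))
  wh <- rampFrequencyResponse(filterSpec("hann", 1), 64)
  expect_true(all(wh <= w + 1e-12))
  expect_equal(wh[1], 0)
})

test_that("dense-view parallel FBP reconstructs a disk accurately", {
  disk <- diskPhantom(128, 40)
  rec <- fbpReconstruct(forwardProject(disk, parallelGeom(128, 180L)))
  expect_lt(relativeError(rec, disk), 0.05)
})

test_that("reconstruction error grows as views are removed", {
  disk <- diskPhantom(96, 30)
  res <- vapply(c(30L, 60L, 120L, 180L), function(nv) {
    relativeError(fbpReconstruct(forwardProject(disk, parallelGeom(96, nv))),
                  disk)
  }, 1.0)
  expect_true(all(diff(res) < 0))     # RE strictly decreasing in views
  expect_gt(res[1], res[4])
})

test_that("the whole FBP map is linear", {
  g <- parallelGeom(48, 30L)
  set.seed(2)
  a <- matrix(runif(48 * 48), 48)
  b <- matrix(runif(48 * 48), 48)
  fa <- fbpReconstruct(forwardProject(a, g))
  fb <- fbpReconstruct(forwardProject(b, g))
  fab <- fbpReconstruct(forwardProject(a + 2 * b, g))
  expect_lt(max(abs(fab - fa - 2 * fb)), 1e-8)
})

test_that("single-view sinograms reconstruct without error", {
  disk <- diskPhantom(48, 15)
  g <- makeGeometry("custom", 48, beam = "parallel", nViews = 1)
  rec <- fbpReconstruct(forwardProject(disk, g))
  expect_true(all(is.finite(rec)))
  expect_gt(relativeError(rec, disk), 0.5)   # heavily streaked, not exact
})

test_that("reconstruction of a radial phantom is rotationally symmetric", {
  disk <- diskPhantom(64, 20)
  rec <- fbpReconstruct(forwardProject(disk, parallelGeom(64, 90L)))
  # 90-degree rotations of a radially symmetric reconstruction agree
  expect_lt(max(abs(rec - t(rec))), 0.05 * max(rec))
  expect_lt(max(abs(rec - rec[64:1, 64:1])), 0.05 * max(rec))
})

test_that("fan-beam half-range data yield limited-angle artefacts", {
  disk <- diskPhantom(64, 20)
  full <- fbpReconstruct(forwardProject(disk, makeGeometry("full-range", 64)))
  half <- fbpReconstruct(forwardProject(disk, makeGeometry("half-range", 64)))
  expect_lt(relativeError(full, disk), 0.12)
  expect_gt(relativeError(half, disk), relativeError(full, disk))
})
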