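# phantom families and image scaling

test_that("empty ellipse list yields an all-zero image", {
  spec <- phantomSpec("shepp-logan", 32,
                      ellipses = greenCT:::canonicalSheppLogan[0, ])
  expect_equal(generatePhantom(spec), matrix(0, 32, 32))
})

test_that("phantom generation is pure in (spec, seed)", {
  for (fam in c("chest", "flat-sharp", "shepp-logan")) {
    s <- phantomSpec(fam, 48, seed = 7)
    expect_identical(generatePhantom(s), generatePhantom(s))
  }
})

test_that("Shepp-Logan centre value equals the sum of covering ellipses", {
  img <- generatePhantom(phantomSpec("shepp-logan", 64))
  # independent point-in-ellipse evaluation at the exact centre coordinates
  size <- 64
  cx <- (((size / 2 + 1) - 1) - (size - 1) / 2) / (size / 2)  # pixel (33, 33)
  inside <- vapply(seq_len(nrow(greenCT:::canonicalSheppLogan)), function(i) {
    e <- greenCT:::canonicalSheppLogan[i, ]
    th <- e$phi * pi / 180
    xr <- (cx - e$x0) * cos(th) + (cx - e$y0) * sin(th)
    yr <- -(cx - e$x0) * sin(th) + (cx - e$y0) * cos(th)
    (xr / e$a)^2 + (yr / e$b)^2 <= 1
  }, TRUE)
  expected <- sum(greenCT:::canonicalSheppLogan$value[inside])
  expect_equal(img[33, 33], expected)
})

test_that("phantom values stay inside the unit interval", {
  for (fam in c("chest", "flat-sharp", "shepp-logan")) {
    imgs <- generateDataset(4, phantomSpec(fam, 48), seed = 9)
    for (im in imgs) {
      expect_true(all(is.finite(im)))
      expect_gte(min(im), 0)
      expect_lte(max(im), 1)
    }
  }
})

test_that("datasets have randomized, seed-reproducible members", {
  imgs <- generateDataset(5, phantomSpec("chest", 32), seed = 3)
  expect_length(imgs, 5)
  for (i in 1:4) for (j in (i + 1):5)
    expect_false(identical(imgs[[i]], imgs[[j]]))
  expect_identical(imgs, generateDataset(5, phantomSpec("chest", 32), seed = 3))
  other <- generateDataset(5, phantomSpec("chest", 32), seed = 4)
  for (i in 1:5) for (j in 1:5)
    expect_false(identical(imgs[[i]], other[[j]]))
  expect_error(generateDataset(0, phantomSpec("chest", 32)), "n must be")
})

test_that("flat-sharp phantoms are piecewise constant with no texture", {
  spec <- phantomSpec("flat-sharp", 64, seed = 11)
  expect_identical(spec@textureSigma, 0)
  img <- generatePhantom(spec)
  # a noise-free sum of constant ellipses takes few distinct values ...
  expect_lte(length(unique(as.numeric(img))), 200)
  # ... and is exactly constant away from region borders: almost every pixel
  # equals all four neighbours bit-for-bit
  n <- nrow(img)
  inner <- img[2:(n - 1), 2:(n - 1)]
  flat <- (inner == img[1:(n - 2), 2:(n - 1)]) &
          (inner == img[3:n, 2:(n - 1)]) &
          (inner == img[2:(n - 1), 1:(n - 2)]) &
          (inner == img[2:(n - 1), 3:n])
  expect_gt(mean(flat), 0.8)
})

test_that("scaleToUnit is an idempotent affine map with a zero degenerate", {
  m <- matrix(c(2, 3, 4, 3.5), 2)
  expect_equal(scaleToUnit(m), (m - 2) / 2)
  u <- matrix(c(0, 0.4, 1, 0.3), 2)
  expect_equal(scaleToUnit(u), u)
  expect_equal(scaleToUnit(scaleToUnit(m)), scaleToUnit(m))
  expect_equal(scaleToUnit(matrix(5, 3, 3)), matrix(0, 3, 3))
})

test_that("flat-sharp family validity forbids texture", {
  expect_error(phantomSpec("flat-sharp", 32, textureSigma = 0.1),
               "textureSigma")
})
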