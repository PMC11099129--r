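# Preprocessing and feature extraction.

test_that("statistical features reproduce hand arithmetic on {1,2,3,4}", {
  f <- statisticalFeatures(c(1, 2, 3, 4))
  expect_equal(round(f[["mean"]], 5), 2.5)
  expect_equal(round(f[["sd"]], 5), 1.11803)
  expect_equal(round(f[["var"]], 5), 1.66667)
  expect_equal(f[["median"]], 2.5)
  expect_equal(f[["skew"]], 0)
  expect_equal(round(f[["hmean"]], 2), 1.92)
  expect_equal(round(f[["gmean"]], 5), 2.21336)
})

test_that("a constant image yields the degenerate convention [c,0,0,c,0,0,c,c]", {
  img <- imageRaster(array(0.3, c(8, 8, 3)))
  f <- statisticalFeatures(img)
  expect_equal(unname(f), c(0.3, 0, 0, 0.3, 0, 0, 0.3, 0.3), tolerance = 1e-12)
  expect_error(statisticalFeatures(1), "q > 1")
})

test_that("all eight statistics match the naive-loop oracle on random rasters", {
  set.seed(31)
  for (i in 1:50) {
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    ch <- sample(c(1L, 3L), 1)
    px <- array(runif(h * w * ch), c(h, w, ch))
    img <- imageRaster(px)
    f <- statisticalFeatures(img)
    o <- naiveStats(as.numeric(oracleLuminance(px)))
    expect_equal(unname(f), unname(o), tolerance = 1e-10)
  }
})

test_that("mean inequalities and scale equivariance hold", {
  set.seed(8)
  for (i in 1:20) {
    z <- runif(50, 0.05, 1)
    f <- statisticalFeatures(z)
    expect_lte(f[["hmean"]], f[["gmean"]] + 1e-12)
    expect_lte(f[["gmean"]], f[["mean"]] + 1e-12)
    cc <- runif(1, 0.5, 3)
    g <- statisticalFeatures(cc * z)
    expect_equal(g[["mean"]], cc * f[["mean"]])
    expect_equal(g[["sd"]], cc * f[["sd"]])
    expect_equal(g[["var"]], cc^2 * f[["var"]])
    expect_equal(g[["median"]], cc * f[["median"]])
    expect_equal(g[["hmean"]], cc * f[["hmean"]])
    expect_equal(g[["gmean"]], cc * f[["gmean"]])
    expect_equal(g[["skew"]], f[["skew"]], tolerance = 1e-9)
    expect_equal(g[["kurt"]], f[["kurt"]], tolerance = 1e-9)
  }
})

test_that("the literal-formula mode evaluates the printed forms", {
  z <- c(1, 2, 3, 4)
  f <- statisticalFeatures(z, mode = "paper_literal")
  expect_equal(f[["sd"]], mean(z^2) - mean(z)^2)     # no square root
  expect_equal(f[["median"]], (4 + 1) / 2)           # index, not value
  expect_equal(f[["hmean"]], 4 * sum(z))             # product, not reciprocal
  expect_equal(f[["gmean"]], prod(z))                # no q-th root
})

test_that("denoising reduces noise variance and never changes shape", {
  set.seed(12)
  img <- imageRaster(array(0.5 + rnorm(40 * 30, 0, 0.05), c(40, 30, 1)))
  out <- denoiseImage(img)
  expect_equal(dim(pixels(out)), dim(pixels(img)))
  expect_lt(var(as.numeric(pixels(out))), var(as.numeric(pixels(img))))
  # constant image is a fixed point
  cst <- imageRaster(array(0.4, c(20, 20, 3)))
  expect_equal(pixels(denoiseImage(cst)), pixels(cst), tolerance = 1e-12)
  # zero strength is the identity
  expect_identical(pixels(denoiseImage(img, strength = 0)), pixels(img))
  expect_error(denoiseImage(img, patch = 0), "positive")
})

test_that("fast denoising matches the naive quadruple-loop oracle", {
  set.seed(13)
  m <- matrix(runif(14 * 11, 0.2, 0.8), 14, 11)
  img <- imageRaster(m)
  fast <- pixels(denoiseImage(img, strength = 0.1, patch = 3, searchWindow = 5))[, , 1]
  slow <- naiveNlm(m, h = 0.1, patch = 3, win = 5)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("standardization enforces the 224 x 224 x 3 convention", {
  # idempotent shape
  a <- imageRaster(array(runif(224 * 224 * 3), c(224, 224, 3)))
  expect_equal(dim(pixels(standardizeImage(a))), c(224L, 224L, 3L))
  # resize of a constant stays constant
  b <- imageRaster(array(0.6, c(448, 448, 3)))
  sb <- standardizeImage(b)
  expect_equal(dim(pixels(sb)), c(224L, 224L, 3L))
  expect_equal(max(abs(pixels(sb) - 0.6)), 0, tolerance = 1e-12)
  # grayscale of any size is replicated to 3 channels
  g <- imageRaster(array(runif(100 * 50), c(100, 50, 1)))
  sg <- standardizeImage(g)
  expect_equal(dim(pixels(sg)), c(224L, 224L, 3L))
  expect_equal(pixels(sg)[, , 1], pixels(sg)[, , 3])
})

test_that("feature extraction concatenates statistics and backbone", {
  set.seed(3)
  img <- standardizeImage(imageRaster(array(runif(64 * 64 * 3), c(64, 64, 3))))
  bb <- descriptorBackbone()
  fv <- extractFeatures(img, bb)
  expect_length(fv, 109L)                     # published total dimension
  expect_equal(names(fv)[1:8],
               c("mean", "sd", "var", "median", "skew", "kurt",
                 "hmean", "gmean"))
  # degenerate backbone: purely statistical
  none <- new("Backbone", name = "none", d = 0L,
              fun = function(image) numeric(0))
  expect_length(extractFeatures(img, none), 8L)
  # determinism
  expect_identical(fv, extractFeatures(img, bb))
  # declared-dimension mismatch is refused
  bad <- new("Backbone", name = "bad", d = 5L,
             fun = function(image) numeric(3))
  expect_error(extractFeatures(img, bad), "declares")
  # the plain random-projection backbone is deterministic too
  rp <- randomProjectionBackbone(d = 7L, size = 64L)
  expect_identical(rp@fun(img), rp@fun(img))
  expect_length(extractFeatures(img, rp), 15L)
})

test_that("image trees round-trip through PNG on disk", {
  imgs <- generateLesions(syntheticSpec(2, 2, imageSize = 32, seed = 5))
  dir <- tempfile()
  writeImageTree(imgs, dir)
  back <- readImageTree(dir)
  expect_length(back, 4L)
  expect_equal(sort(vapply(back, imageLabel, character(1))),
               c("benign", "benign", "malignant", "malignant"))
  # 8-bit quantization at most
  expect_lt(max(abs(pixels(back[[1]]) - pixels(imgs[[1]]))), 1 / 255)
  expect_error(readImageTree(tempfile()), "class folders")
})
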