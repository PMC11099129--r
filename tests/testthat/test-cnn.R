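# Architecture reconstruction, parameter counting, training, tuning.

test_that("the canonical architecture reproduces every published shape/count", {
  spec <- canonicalSpec()
  shapes <- outputShapes(spec)
  expect_equal(shapes[[1]], c(22L, 11L, 16L))
  expect_equal(shapes[[2]], c(22L, 11L, 16L))
  expect_equal(shapes[[3]], c(22L, 11L, 32L))
  expect_equal(shapes[[5]], c(22L, 11L, 64L))
  expect_equal(shapes[[8]], 15488L)
  expect_equal(shapes[[9]], 64L)
  expect_equal(shapes[[10]], 2L)
  pc <- countParameters(spec)
  expect_equal(unname(pc$perLayer),
               c(160L, 0L, 4640L, 0L, 18496L, 0L, 0L, 0L, 991296L, 130L))
  expect_equal(pc$total, 160L + 4640L + 18496L + 991296L + 130L)
})

test_that("parameter counting follows the conv/dense formulas", {
  spec <- networkSpec(list(
    layerSpec("conv", 8L, kernel = c(5L, 5L), activation = "relu"),
    layerSpec("flatten"),
    layerSpec("dense", 2L, activation = "softmax")), c(10L, 10L, 3L))
  pc <- countParameters(spec)
  expect_equal(unname(pc$perLayer[1]), 5 * 5 * 3 * 8 + 8)
  expect_equal(unname(pc$perLayer[3]), 10 * 10 * 8 * 2 + 2)
  # shape propagation errors name the offending layer
  bad <- networkSpec(list(
    layerSpec("dense", 4L),
    layerSpec("dense", 2L, activation = "softmax")), c(4L, 4L, 1L))
  expect_error(outputShapes(bad), "layer 1")
})

test_that("built models are reproducible and softmax-normalized", {
  spec <- canonicalSpec()
  m1 <- buildModel(spec, seed = 5)
  m2 <- buildModel(spec, seed = 5)
  expect_identical(m1@weights, m2@weights)
  m3 <- buildModel(spec, seed = 6)
  expect_false(identical(m1@weights, m3@weights))
  # forward on zeros: valid probability pairs
  x <- array(0, c(22, 11, 1, 3))
  p <- predictModel(m1, x)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # self-consistency: stored weights match the declared counts
  nPar <- sum(vapply(m1@weights, function(w)
    if (length(w)) length(w$W) + length(w$b) else 0L, numeric(1)))
  expect_equal(nPar, countParameters(spec)$total)
})

test_that("feature vectors reshape row-major into the 22 x 11 plane", {
  v <- seq_len(109)
  plane <- reshapeFeatures(v)
  expect_equal(dim(plane), c(22L, 11L, 1L))
  expect_equal(plane[1, 1:11, 1], 1:11)          # row-major fill
  expect_equal(plane[2, 1, 1], 12)
  expect_equal(sum(plane == 0), 242L - 109L)     # 133 trailing zeros
  # exact fit, no padding
  full <- reshapeFeatures(seq_len(242))
  expect_equal(sum(full == 0), 0L)
  expect_error(reshapeFeatures(numeric(243)), "242")
  expect_equal(reshapeFeatures(numeric(10)),
               array(0, c(22, 11, 1)))
})

test_that("training descends the loss and is seed-reproducible", {
  # linearly separable synthetic features
  set.seed(10)
  n <- 40
  lab <- rep(c(0, 1), each = n / 2)
  feat <- matrix(rnorm(n * 109, sd = 0.3), n, 109)
  feat[lab == 1, 1:10] <- feat[lab == 1, 1:10] + 2
  x <- featuresToInput(feat)
  y <- cbind(1 - lab, lab)
  spec <- canonicalSpec()
  m <- buildModel(spec, seed = 1)
  expect_warning(trainModel(m, x, cbind(rep(1, n), rep(0, n)),
                            epochs = 1L, seed = 1), "single-class")
  tr <- trainModel(m, x, y, epochs = 30L, seed = 1)
  expect_lt(tail(tr@history, 1), tr@history[1])
  # epochs = 0 is a no-op
  expect_identical(trainModel(m, x, y, epochs = 0L)@weights, m@weights)
  # fixed seed reproduces the history
  tr2 <- trainModel(m, x, y, epochs = 5L, seed = 3)
  tr3 <- trainModel(m, x, y, epochs = 5L, seed = 3)
  expect_identical(tr2@history, tr3@history)
})

test_that("output-layer tuning never worsens the tuning-fold fitness", {
  set.seed(20)
  n <- 24
  lab <- rep(c(0, 1), each = n / 2)
  feat <- matrix(rnorm(n * 109, sd = 0.5), n, 109)
  feat[lab == 1, 1:8] <- feat[lab == 1, 1:8] + 1.5
  x <- featuresToInput(feat)
  y <- cbind(1 - lab, lab)
  m <- buildModel(canonicalSpec(), seed = 2)
  m <- trainModel(m, x, y, epochs = 3L, seed = 2)
  for (seed in 1:5) {
    before <- modelMSE(m, x, y)
    tuned <- ffoTune(m, x, y, iterMax = 10L, seed = seed)
    expect_lte(modelMSE(tuned, x, y), before + 1e-12)
  }
  # zero-iteration tuning returns the model unchanged
  expect_identical(ffoTune(m, x, y, iterMax = 0L)@weights, m@weights)
  # a config of the wrong dimension is auto-corrected (with a notice)
  cfgBad <- ffoConfig(s = 10, lower = -1, upper = 1, l = 8L, iterMax = 3L)
  expect_message(tunedB <- ffoTune(m, x, y, config = cfgBad), "corrected")
  expect_lte(modelMSE(tunedB, x, y), modelMSE(m, x, y) + 1e-12)
})

test_that("tuned heads beat untrained heads on separable data", {
  set.seed(30)
  n <- 40
  lab <- rep(c(0, 1), each = n / 2)
  feat <- matrix(rnorm(n * 109, sd = 0.4), n, 109)
  feat[lab == 1, 1:12] <- feat[lab == 1, 1:12] + 2
  x <- featuresToInput(feat)
  y <- cbind(1 - lab, lab)
  wins <- 0L
  for (seed in 1:5) {
    m0 <- buildModel(canonicalSpec(), seed = seed)   # untrained head
    acc0 <- mean(max.col(predictModel(m0, x)) - 1 == lab)
    tuned <- ffoTune(m0, x, y, iterMax = 25L, seed = seed)
    acc1 <- mean(max.col(predictModel(tuned, x)) - 1 == lab)
    if (acc1 >= acc0) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("models round-trip through the manifest + weights checkpoint", {
  m <- buildModel(canonicalSpec(), seed = 9)
  dir <- tempfile()
  saveModel(m, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$parameters_total, countParameters(m@spec)$total)
  m2 <- loadModel(dir)
  expect_equal(m2@weights, m@weights)
  x <- array(rnorm(22 * 11 * 2), c(22, 11, 1, 2))
  expect_equal(predictModel(m2, x), predictModel(m, x))
})
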