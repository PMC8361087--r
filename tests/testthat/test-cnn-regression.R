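pt <- asNamespace("phototrait")

randomImages <- function(n, side, seed = 1) {
  set.seed(seed)
  matrix(runif(side * side * 3 * n), side * side * 3, n)
}

modelData <- function(x, y, clim = NULL) {
  list(x = x, clim = clim, targetNorm = y,
       mu = rep(10, length(y)), sigma = rep(0, length(y)),
       targetParams = fitNormalizer(c(0, 2)))
}

test_that("analytic gradients match numerical differentiation", {
  for (mixed in c(FALSE, TRUE)) {
    cfg <- traitModelConfig(mixedData = mixed, imageSize = 32L, seed = 7L)
    m <- buildTraitModel(cfg)
    B <- 2L
    x <- randomImages(B, 32, seed = 5)
    cl <- if (mixed) matrix(runif(6 * B), 6, B) else NULL
    y <- runif(B)
    fw <- pt$nnForward(m@params, m@arch, x, cl, keepCache = TRUE)
    gr <- pt$nnBackward(m@params, m@arch, fw, y, B)
    lossAt <- function(p) mean((pt$nnForward(p, m@arch, x, cl) - y)^2)
    base <- lossAt(m@params)
    eps <- 1e-6
    set.seed(9)
    for (nm in names(m@params)) {
      for (k in sample(length(m@params[[nm]]), min(3, length(m@params[[nm]])))) {
        p2 <- m@params
        p2[[nm]][k] <- p2[[nm]][k] + eps
        num <- (lossAt(p2) - base) / eps
        expect_equal(gr[[nm]][k], num, tolerance = 1e-3,
                     label = sprintf("grad %s[%d]", nm, k))
      }
    }
  }
})

test_that("model construction is deterministic in the seed and reports shape", {
  cfg <- traitModelConfig(imageSize = 32L, seed = 99L)
  m1 <- buildTraitModel(cfg)
  m2 <- buildTraitModel(cfg)
  x <- randomImages(20, 32)
  expect_identical(predict(m1, modelData(x, runif(20))),
                   predict(m2, modelData(x, runif(20))))
  expect_length(predict(m1, modelData(x, runif(20))), 20L)
  expect_gt(parameterCount(m1), 0L)
})

test_that("invalid backbones and climate shapes are rejected", {
  expect_error(traitModelConfig(backbone = "resnet50"), "tiny_test_cnn")
  expect_error(buildTraitModel(traitModelConfig(backbone = "xception")),
               "pretrained")
  cfg <- traitModelConfig(mixedData = TRUE, imageSize = 32L)
  m <- buildTraitModel(cfg)
  x <- randomImages(4, 32)
  expect_error(pt$nnForward(m@params, m@arch, x, matrix(0, 5, 4)), "6 x")
  expect_silent(pt$nnForward(m@params, m@arch, x, matrix(0, 6, 4)))
})

test_that("mixed head widths follow the published regressor design", {
  cfg <- traitModelConfig(mixedData = TRUE, imageSize = 32L)
  m <- buildTraitModel(cfg)
  expect_identical(dim(m@params$img2.W)[2], 4L)       # image branch ends in 4
  expect_identical(vapply(paste0("clim", 1:3, ".W"),
                          function(n) ncol(m@params[[n]]), integer(1)),
                   c(clim1.W = 64L, clim2.W = 32L, clim3.W = 4L))
  expect_identical(vapply(paste0("fus", 1:4, ".W"),
                          function(n) ncol(m@params[[n]]), integer(1)),
                   c(fus1.W = 8L, fus2.W = 8L, fus3.W = 4L, fus4.W = 1L))
  expect_identical(nrow(m@params$fus1.W), 8L)         # 4 image + 4 climate
  # image-only head: 512 then 1
  mi <- buildTraitModel(traitModelConfig(imageSize = 32L))
  expect_identical(ncol(mi@params$img1.W), 512L)
  expect_identical(ncol(mi@params$img2.W), 1L)
})

test_that("zeroed climate input makes the climate branch inert", {
  cfg <- traitModelConfig(mixedData = TRUE, imageSize = 32L, seed = 3L)
  m <- buildTraitModel(cfg)
  x <- randomImages(6, 32)
  z <- matrix(0, 6, 6)
  p1 <- pt$nnForward(m@params, m@arch, x, z)
  p2 <- pt$nnForward(m@params, m@arch, x, z[, sample(6)])
  expect_identical(p1, p2)
})

test_that("image augmentation honours identity, involution and clipping", {
  img <- array(runif(24 * 24 * 3), c(24, 24, 3))
  expect_equal(augmentImage(img, flipH = FALSE, flipV = FALSE, contrast = 1,
                            saturation = 1, brightness = 1), img,
               tolerance = 1e-12)
  flipped <- augmentImage(img, flipH = TRUE, flipV = FALSE, contrast = 1,
                          saturation = 1, brightness = 1)
  back <- augmentImage(flipped, flipH = TRUE, flipV = FALSE, contrast = 1,
                       saturation = 1, brightness = 1)
  expect_equal(back, img, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:50) {
    out <- augmentImage(img)
    expect_true(all(out >= 0 & out <= 1))
    expect_identical(dim(out), dim(img))
  }
})

test_that("batch augmentation agrees with the single-image operator", {
  set.seed(8)
  side <- 16L
  img <- array(runif(side * side * 3), c(side, side, 3))
  X <- matrix(as.vector(img), ncol = 1)
  # fix the RNG so the batch path draws flips/factors reproducibly
  set.seed(123)
  aug <- pt$augmentBatch(X, side)
  set.seed(123)
  fh <- runif(1) < 0.5; fv <- runif(1) < 0.5
  fs <- runif(1, 0.9, 1.1); fc <- runif(1, 0.9, 1.1); fb <- runif(1, 0.9, 1.1)
  ref <- augmentImage(img, flipH = fh, flipV = fv, contrast = fc,
                      saturation = fs, brightness = fb)
  expect_equal(as.vector(ref), as.vector(aug), tolerance = 1e-12)
})

test_that("preprocessing crops to center square and resizes", {
  img <- array(runif(60 * 80 * 3), c(60, 80, 3))
  out <- preprocessImage(img, 32L)
  expect_identical(dim(out), c(32L, 32L, 3L))
  sq <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_equal(preprocessImage(sq, 32L), sq, tolerance = 1e-12)
  gray <- array(0.42, c(50, 70, 3))
  outg <- preprocessImage(gray, 32L)
  expect_equal(as.vector(outg), rep(0.42, 32 * 32 * 3), tolerance = 1e-6)
  expect_warning(preprocessImage(sq, 64L), "upsampling")
  expect_error(readImageFile("no-such-file.png"), "not found")
})

test_that("training reduces error, is deterministic, and honours maxEpochs 0", {
  side <- 32L
  n <- 60
  set.seed(21)
  # target is the mean intensity of the image: learnable by the trunk
  x <- matrix(runif(side * side * 3 * n), side * side * 3, n)
  y <- colMeans(x)
  y <- (y - min(y)) / (max(y) - min(y))
  tr <- modelData(x[, 1:40], y[1:40])
  va <- modelData(x[, 41:60], y[41:60])
  cfg <- traitModelConfig(imageSize = side, seed = 70L, maxEpochs = 4L,
                          batchSize = 10L)
  m0 <- buildTraitModel(cfg)
  mt <- trainTraitModel(m0, tr, va)
  h <- trainingHistory(mt)
  expect_lt(h$train_mae[nrow(h)], h$train_mae[1])
  expect_true(mt@trained)
  # determinism
  mt2 <- trainTraitModel(buildTraitModel(cfg), tr, va)
  expect_equal(trainingHistory(mt2)$train_mae[1], h$train_mae[1],
               tolerance = 1e-6)
  expect_identical(mt2@params, mt@params)
  # no-op training
  cfg0 <- traitModelConfig(imageSize = side, seed = 70L, maxEpochs = 0L)
  m00 <- buildTraitModel(cfg0)
  expect_identical(trainTraitModel(m00, tr, va)@params, m00@params)
  expect_error(trainTraitModel(m0, tr, modelData(x[, 0], numeric(0))),
               "validation")
})

test_that("models serialise to JSON and restore identically", {
  cfg <- traitModelConfig(imageSize = 32L, seed = 12L)
  m <- buildTraitModel(cfg)
  m@normParams <- fitNormalizer(c(0.3, 1.8))
  f <- tempfile(fileext = ".json")
  saveTraitModel(m, f)
  m2 <- loadTraitModel(f)
  x <- randomImages(5, 32)
  expect_equal(predict(m, modelData(x, runif(5))),
               predict(m2, modelData(x, runif(5))), tolerance = 1e-12)
  expect_equal(minTrain(m2@normParams), 0.3)
})
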