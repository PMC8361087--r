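#' Construct a trait model configuration
#'
#' Defaults follow the published training recipe: batch size 20, RMSprop at
#' learning rate 0.001 with inverse-time decay 0.0001, MSE loss, early
#' stopping on validation MAE. The \code{tiny_test_cnn} backbone (three
#' strided 3x3 convolutions, 8/16/32 channels, global average pooling) is a
#' from-scratch architecture sized for desk-scale experiments; the named
#' large backbones are configuration options for full-scale runs with
#' externally supplied weights.
#'
#' @param backbone one of \code{"tiny_test_cnn"} (default),
#'   \code{"inception_resnet_v2"}, \code{"xception"},
#'   \code{"mobilenet_v2_half"}.
#' @param mixedData fuse the image branch with the six bioclim predictors?
#' @param imageSize square input side in pixels (default 64 for the tiny
#'   backbone; the full-scale recipe uses 512).
#' @param batchSize,lr,lrDecay,loss,maxEpochs,patience,seed see
#'   [TraitModelConfig-class].
#' @return a [TraitModelConfig-class].
#' @export
traitModelConfig <- function(backbone = "tiny_test_cnn", mixedData = FALSE,
                             imageSize = 64L, batchSize = 20L, lr = 0.001,
                             lrDecay = 0.0001, loss = "mse", seed = 1L,
                             maxEpochs = 10L, patience = 5L) {
  new("TraitModelConfig", backbone = backbone, mixedData = mixedData,
      imageSize = as.integer(imageSize), batchSize = as.integer(batchSize),
      lr = lr, lrDecay = lrDecay, loss = loss, seed = as.integer(seed),
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience))
}

#' Build an (untrained) trait regression model
#'
#' Initialises the network described by the configuration: convolutional
#' trunk, global average pooling, and the dense regressor (image-only head
#' 512 -> 1; mixed model: image branch to 4 units, climate branch 64-32-4,
#' fused regressor 8-8-4-1; branch/final layers linear, all other dense
#' layers relu). Initialisation is deterministic in \code{config@seed}.
#'
#' @param config a [TraitModelConfig-class].
#' @return an untrained [TraitModel-class].
#' @export
buildTraitModel <- function(config) {
  validObject(config)
  arch <- buildArch(config)
  params <- initParams(arch, config@seed)
  new("TraitModel", config = config, params = params, arch = arch,
      history = data.frame(epoch = integer(), train_mae = numeric(),
                           val_mae = numeric(), lr = numeric()),
      normParams = NULL, trained = FALSE)
}

#' Number of trainable parameters of a model
#'
#' @param model a [TraitModel-class].
#' @return integer count of scalar weights.
#' @export
parameterCount <- function(model) nParams(model@params)

#' Per-epoch training history
#'
#' @param model a trained [TraitModel-class].
#' @return data.frame with columns epoch, train_mae, val_mae, lr.
#' @export
trainingHistory <- function(model) model@history

## ---- image loading and preprocessing -------------------------------------

#' Read an RGB image file
#'
#' Reads PNG directly and other formats (JPEG, TIFF) via EBImage. Grayscale
#' images are replicated to three channels, alpha channels dropped.
#'
#' @param path image file path.
#' @return numeric array (height, width, 3) with values in [0, 1].
#' @export
readImageFile <- function(path) {
  assertThat(file.exists(path), "cannot read image: file not found: %s", path)
  img <- tryCatch({
    if (grepl("\\.png$", path, ignore.case = TRUE)) {
      png::readPNG(path)
    } else {
      d <- EBImage::imageData(EBImage::readImage(path))
      if (length(dim(d)) == 3L) aperm(d, c(2, 1, 3)) else t(d)
    }
  }, error = function(e)
    stop(sprintf("unreadable image '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Center-crop to a square and resize
#'
#' Crops the longer axis symmetrically to a square (removing the spare
#' margins) and bilinearly resamples to \code{imageSize} pixels a side;
#' pixel values are scaled into [0, 1]. Images smaller than the target are
#' upsampled with a warning.
#'
#' @param img numeric array (height, width, 3); values in [0, 1] or [0, 255].
#' @param imageSize target side length in pixels.
#' @return numeric array (imageSize, imageSize, 3) in [0, 1].
#' @export
preprocessImage <- function(img, imageSize) {
  assertThat(length(dim(img)) == 3L && dim(img)[3] == 3L,
             "expected an (H, W, 3) image array")
  if (max(img) > 1) img <- img / 255
  h <- dim(img)[1]; w <- dim(img)[2]
  side <- min(h, w)
  r0 <- (h - side) %/% 2L
  c0 <- (w - side) %/% 2L
  img <- img[r0 + seq_len(side), c0 + seq_len(side), , drop = FALSE]
  if (side < imageSize)
    warning(sprintf("image shorter side %d px below target %d px; upsampling",
                    side, imageSize))
  if (side != imageSize) {
    eb <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    img <- aperm(EBImage::imageData(
      EBImage::resize(eb, w = imageSize, h = imageSize)), c(2, 1, 3))
  }
  clip01(img)
}

#' Photometric and flip augmentation of one image
#'
#' Applies an independent 50\% horizontal and vertical flip and scales
#' contrast, saturation and brightness each by an independent factor drawn
#' uniformly from [0.9, 1.1]; the result is clipped back to [0, 1].
#' Definitions: brightness multiplies all channels; contrast scales
#' deviations about the image mean; saturation scales chroma about the
#' per-pixel luma (0.299 R + 0.587 G + 0.114 B). Pass explicit arguments to
#' fix any factor (all factors 1 and no flips is the identity).
#'
#' @param img numeric (H, W, 3) array in [0, 1].
#' @param flipH,flipV logical or NULL (NULL = random 50\%).
#' @param contrast,saturation,brightness numeric factor or NULL
#'   (NULL = random uniform on [0.9, 1.1]).
#' @return augmented (H, W, 3) array in [0, 1].
#' @export
augmentImage <- function(img, flipH = NULL, flipV = NULL, contrast = NULL,
                         saturation = NULL, brightness = NULL) {
  if (is.null(flipH)) flipH <- stats::runif(1) < 0.5
  if (is.null(flipV)) flipV <- stats::runif(1) < 0.5
  if (is.null(contrast)) contrast <- stats::runif(1, 0.9, 1.1)
  if (is.null(saturation)) saturation <- stats::runif(1, 0.9, 1.1)
  if (is.null(brightness)) brightness <- stats::runif(1, 0.9, 1.1)
  if (flipH) img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
  if (flipV) img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
  luma <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  for (ch in 1:3) img[, , ch] <- luma + (img[, , ch] - luma) * saturation
  img <- mean(img) + (img - mean(img)) * contrast
  img <- img * brightness
  clip01(img)
}

## Batch augmentation on an (H*W*3 x B) matrix; one random flip decision and
## factor triple per image. Uses the current RNG stream.
augmentBatch <- function(X, side) {
  B <- ncol(X)
  HW <- side * side
  fH <- which(stats::runif(B) < 0.5)
  fV <- which(stats::runif(B) < 0.5)
  if (length(fH) || length(fV)) {
    colRev <- as.vector(outer(seq_len(side), (rev(seq_len(side)) - 1) * side, "+"))
    rowRev <- as.vector(outer(rev(seq_len(side)), (seq_len(side) - 1) * side, "+"))
    chan <- function(perm) c(perm, perm + HW, perm + 2 * HW)
    if (length(fH)) X[, fH] <- X[chan(colRev), fH, drop = FALSE]
    if (length(fV)) X[, fV] <- X[chan(rowRev), fV, drop = FALSE]
  }
  fSat <- stats::runif(B, 0.9, 1.1)
  fCon <- stats::runif(B, 0.9, 1.1)
  fBri <- stats::runif(B, 0.9, 1.1)
  i1 <- seq_len(HW)
  luma <- 0.299 * X[i1, , drop = FALSE] + 0.587 * X[i1 + HW, , drop = FALSE] +
    0.114 * X[i1 + 2 * HW, , drop = FALSE]
  luma3 <- rbind(luma, luma, luma)
  X <- luma3 + sweep(X - luma3, 2, fSat, "*")
  m <- colMeans(X)
  X <- sweep(sweep(sweep(X, 2, m, "-"), 2, fCon, "*"), 2, m, "+")
  X <- sweep(X, 2, fBri, "*")
  X[X < 0] <- 0
  X[X > 1] <- 1
  X
}

## ---- dataset assembly for the trainer ------------------------------------

#' Assemble in-memory model data from a manifest data.frame
#'
#' Loads and preprocesses every image referenced by \code{df$image_ref},
#' normalises targets with the supplied train-only parameters and collects
#' the normalised bioclim matrix when present. The result is the input
#' format of [trainTraitModel()] and [predict()].
#'
#' @param df data.frame with columns \code{image_ref}, \code{target} (log10
#'   scale), \code{trait_mean}, \code{trait_sd}, and (for mixed models) the
#'   six normalised bioclim columns \code{bio1_n, ..., bio13_14_n}.
#' @param imageSize side length the images are preprocessed to.
#' @param targetParams the target [NormalizationParams-class].
#' @return list with \code{x} ((H*W*3) x N image matrix), \code{clim}
#'   (6 x N matrix or NULL), \code{targetNorm}, \code{mu}, \code{sigma},
#'   \code{recordId}, \code{imageSize}, \code{targetParams}.
#' @export
makeModelData <- function(df, imageSize, targetParams) {
  n <- nrow(df)
  x <- matrix(0, imageSize * imageSize * 3, n)
  for (i in seq_len(n))
    x[, i] <- as.vector(preprocessImage(readImageFile(df$image_ref[i]),
                                        imageSize))
  climCols <- paste0(BIOCLIM_VARS, "_n")
  clim <- if (all(climCols %in% names(df)))
    t(as.matrix(df[climCols])) else NULL
  list(x = x, clim = clim,
       targetNorm = normalizeValues(df$target, targetParams),
       mu = df$trait_mean, sigma = df$trait_sd,
       recordId = df$record_id, imageSize = imageSize,
       targetParams = targetParams)
}

## Vectorized truncated-normal plasticity draw for a training batch. When no
## species in the batch has a positive SD the deterministic targets are
## returned without touching the RNG stream, so an all-zero-SD dataset makes
## plasticity training bit-identical to baseline training under one seed.
drawPlasticityTargets <- function(mu, sigma, p) {
  if (all(sigma == 0)) return(clip01(normalizeValues(log10(mu), p)))
  lo <- mu - sigma
  if (any(lo <= 0 & sigma > 0)) {
    warning("plasticity: mu - sigma <= 0 for some species; flooring the truncation interval above 0")
    lo <- pmax(lo, .Machine$double.xmin)
  }
  v <- rtruncnormInterval(length(mu), mu, sigma, lo, mu + sigma)
  clip01(normalizeValues(log10(v), p))
}

## ---- training and prediction ---------------------------------------------

#' Train a trait regression model
#'
#' Minimises the mean squared error of (augmented image [, climate]) against
#' the normalised target with RMSprop (batch size, learning rate and decay
#' from the configuration). When \code{plasticity} is TRUE, every
#' presentation of a training observation redraws its target from the
#' truncated species trait distribution (see [plasticityAugment()]);
#' validation always uses the unaugmented mean targets. After each epoch the
#' validation MAE is computed on un-augmented images; training stops when it
#' has not improved for \code{patience} epochs (or at \code{maxEpochs}) and
#' the best-epoch weights are restored. With \code{maxEpochs = 0} the model
#' is returned untouched.
#'
#' The run is deterministic in \code{config@seed} under single-threaded
#' execution: weight initialisation, minibatch order, image augmentation and
#' plasticity draws all derive from it.
#'
#' A narrow relu stack can in rare seeds lose all units early in training,
#' freezing the network at a constant output with no usable gradient. When
#' the end-of-epoch validation predictions are exactly constant the trainer
#' treats the run as collapsed, reinitialises the weights under a seed
#' derived from \code{config@seed} and the restart count, and starts over
#' (at most \code{maxRestarts} times); dead runs are discarded, so the
#' returned model still reflects at most \code{maxEpochs} epochs of
#' training from its final initialisation.
#'
#' @param model an untrained [TraitModel-class] from [buildTraitModel()].
#' @param train,validation model-data lists from [makeModelData()].
#' @param plasticity logical; redraw training targets from the species
#'   trait distributions?
#' @param verbose print per-epoch progress?
#' @param maxRestarts reinitialisation attempts after a collapsed run
#'   (default 5).
#' @return the trained [TraitModel-class] with filled history.
#' @export
trainTraitModel <- function(model, train, validation, plasticity = FALSE,
                            verbose = FALSE, maxRestarts = 5L) {
  cfg <- model@config
  assertThat(length(validation$targetNorm) > 0, "validation set is empty")
  if (cfg@mixedData)
    assertThat(!is.null(train$clim) && !is.null(validation$clim),
               "mixed-data model but no climate columns in the data")
  if (cfg@maxEpochs == 0L) return(model)
  arch <- model@arch
  n <- length(train$targetNorm)
  attempt <- 0L
  params <- model@params
  repeat {
    state <- rmspropInit(params)
    step <- 0L
    best <- Inf
    bestParams <- params
    wait <- 0L
    dead <- FALSE
    hist <- vector("list", cfg@maxEpochs)
    withSeed(deriveSeed(cfg@seed, paste0("train", attempt)), {
      for (epoch in seq_len(cfg@maxEpochs)) {
        ord <- sample(n)
        starts <- seq(1L, n, by = cfg@batchSize)
        maeAcc <- 0
        for (s in starts) {
          idx <- ord[s:min(s + cfg@batchSize - 1L, n)]
          xb <- augmentBatch(train$x[, idx, drop = FALSE], cfg@imageSize)
          yb <- if (plasticity)
            drawPlasticityTargets(train$mu[idx], train$sigma[idx],
                                  train$targetParams)
          else train$targetNorm[idx]
          cb <- if (cfg@mixedData) train$clim[, idx, drop = FALSE] else NULL
          fw <- nnForward(params, arch, xb, cb, keepCache = TRUE)
          grads <- nnBackward(params, arch, fw, yb, length(idx))
          step <- step + 1L
          up <- rmspropStep(params, grads, state, step, cfg@lr, cfg@lrDecay)
          params <- up$params
          state <- up$state
          maeAcc <- maeAcc + sum(abs(fw$pred - yb))
        }
        trainMae <- maeAcc / n
        valPred <- predictBatched(params, arch, validation$x,
                                  validation$clim, cfg@batchSize)
        valMae <- mean(abs(valPred - validation$targetNorm))
        lrNow <- cfg@lr / (1 + cfg@lrDecay * step)
        hist[[epoch]] <- data.frame(epoch = epoch, train_mae = trainMae,
                                    val_mae = valMae, lr = lrNow)
        if (verbose)
          message(sprintf("epoch %d: train MAE %.4f, val MAE %.4f",
                          epoch, trainMae, valMae))
        ## exactly constant predictions = every relu path dead: no gradient
        ## can revive the network, so abandon this run
        if (length(valPred) > 1L && stats::sd(valPred) < 1e-10) {
          dead <- TRUE
          break
        }
        if (valMae < best - 1e-9) {
          best <- valMae
          bestParams <- params
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg@patience) break
        }
      }
    })
    if (!dead || attempt >= maxRestarts) break
    attempt <- attempt + 1L
    if (verbose)
      message(sprintf("collapsed network; reinitialising (restart %d)",
                      attempt))
    params <- initParams(arch, deriveSeed(cfg@seed, paste0("restart", attempt)))
  }
  model@params <- bestParams
  model@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model@normParams <- train$targetParams
  model@trained <- TRUE
  model
}

predictBatched <- function(params, arch, x, clim, batchSize) {
  n <- ncol(x)
  out <- numeric(n)
  for (s in seq(1L, n, by = batchSize)) {
    idx <- s:min(s + batchSize - 1L, n)
    out[idx] <- nnForward(params, arch, x[, idx, drop = FALSE],
                          if (arch$mixed) clim[, idx, drop = FALSE] else NULL)
  }
  out
}

#' Predict normalised trait values
#'
#' @param object a [TraitModel-class].
#' @param newdata a model-data list from [makeModelData()] (fields \code{x}
#'   and, for mixed models, \code{clim}).
#' @param ... ignored.
#' @return numeric vector of predictions on the normalised target scale.
#' @export
setMethod("predict", "TraitModel", function(object, newdata, ...) {
  predictBatched(object@params, object@arch, newdata$x, newdata$clim,
                 object@config@batchSize)
})

#' Save / load a trained model
#'
#' The weights are written as a plain JSON file (shapes + flattened values)
#' with the configuration and normalisation parameters alongside, so model
#' artefacts remain text.
#'
#' @param model a [TraitModel-class].
#' @param path output / input JSON path.
#' @return \code{saveTraitModel}: \code{path} invisibly;
#'   \code{loadTraitModel}: the restored [TraitModel-class].
#' @export
saveTraitModel <- function(model, path) {
  cfg <- model@config
  obj <- list(
    config = list(backbone = cfg@backbone, mixedData = cfg@mixedData,
                  imageSize = cfg@imageSize, batchSize = cfg@batchSize,
                  lr = cfg@lr, lrDecay = cfg@lrDecay, loss = cfg@loss,
                  seed = cfg@seed, maxEpochs = cfg@maxEpochs,
                  patience = cfg@patience),
    normParams = if (is(model@normParams, "NormalizationParams"))
      list(minTrain = model@normParams@minTrain,
           maxTrain = model@normParams@maxTrain) else NULL,
    trained = model@trained,
    history = model@history,
    params = lapply(model@params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p), value = as.vector(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveTraitModel
#' @export
loadTraitModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(traitModelConfig, obj$config)
  model <- buildTraitModel(cfg)
  model@params <- stats::setNames(lapply(names(obj$params), function(nm) {
    p <- obj$params[[nm]]
    if (length(p$dim) == 2) matrix(p$value, p$dim[1], p$dim[2])
    else as.numeric(p$value)
  }), names(obj$params))
  if (!is.null(obj$normParams))
    model@normParams <- new("NormalizationParams",
                            minTrain = obj$normParams$minTrain,
                            maxTrain = obj$normParams$maxTrain)
  if (length(obj$history))
    model@history <- as.data.frame(obj$history)
  model@trained <- isTRUE(obj$trained)
  model
}
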