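## Minimal dense/convolutional network engine used by the trait regressors.
## Everything is double precision, column-major: an image batch is a
## (H*W*C) x B matrix, a feature batch is (F) x B. Convolutions are "valid"
## with square kernels and are computed by im2col gather + one matrix
## multiply; gradients use the exact transpose operations, so a numerical
## gradient check (see the test suite) validates the whole engine.

convOutDim <- function(inDim, k, stride) (inDim - k) %/% stride + 1L

## Precompute the im2col index matrix (nPatch x k*k*C) of linear indices into
## an (H, W, C) column-major array. Patches enumerate the output grid in
## column-major order (row fastest); kernel elements enumerate (dh, dw, c).
im2colIndex <- function(H, W, C, k, stride) {
  Ho <- convOutDim(H, k, stride)
  Wo <- convOutDim(W, k, stride)
  hi0 <- (seq_len(Ho) - 1L) * stride           # top row of each patch - 1
  wi0 <- (seq_len(Wo) - 1L) * stride
  patchBase <- outer(hi0 + 1L, wi0 * H, "+")   # (Ho, Wo) linear index of top-left, c = 1
  kern <- expand.grid(dh = 0:(k - 1L), dw = 0:(k - 1L), c = 0:(C - 1L))
  off <- kern$dh + kern$dw * H + kern$c * (H * W)
  idx <- outer(as.vector(patchBase), off, "+")
  storage.mode(idx) <- "integer"
  attr(idx, "outDim") <- c(Ho, Wo)
  idx
}

## Gather a batch into im2col form: X (HWC x B) -> (nPatch*B x kkC),
## rows ordered patch-fastest then image.
im2colGather <- function(X, idx, B) {
  HWC <- nrow(X)
  nPatch <- nrow(idx)
  kkC <- ncol(idx)
  big <- rep(as.vector(idx), times = B) +
    rep.int((0:(B - 1L)) * HWC, rep.int(nPatch * kkC, B))
  G <- array(X[big], c(nPatch, kkC, B))
  dim(G) <- c(nPatch, kkC, B)
  G <- aperm(G, c(1, 3, 2))
  dim(G) <- c(nPatch * B, kkC)
  G
}

## Scatter-add the gradient of the gathered matrix back onto the input batch.
im2colScatter <- function(dG, idx, B, HWC) {
  nPatch <- nrow(idx)
  dX <- numeric(HWC * B)
  boff <- rep.int((0:(B - 1L)) * HWC, rep.int(nPatch, B))
  for (k in seq_len(ncol(idx))) {
    tidx <- rep(idx[, k], times = B) + boff
    dX[tidx] <- dX[tidx] + dG[, k]
  }
  dim(dX) <- c(HWC, B)
  dX
}

## (nPatch*B x F) conv output -> (nPatch*F x B) input of the next layer.
convToBatch <- function(Y, nPatch, B) {
  Fh <- ncol(Y)
  dim(Y) <- c(nPatch, B, Fh)
  Y <- aperm(Y, c(1, 3, 2))
  dim(Y) <- c(nPatch * Fh, B)
  Y
}

batchToConv <- function(dY, nPatch, B) {
  Fh <- nrow(dY) / nPatch
  dim(dY) <- c(nPatch, Fh, B)
  dY <- aperm(dY, c(1, 3, 2))
  dim(dY) <- c(nPatch * B, Fh)
  dY
}

## ---- architecture construction -------------------------------------------

## Dense head widths follow the published regressor design: image-only head
## GAP -> 512 (relu) -> 1 (linear); mixed model: image branch GAP -> 512
## (relu) -> 4 (linear), climate branch 64 -> 32 -> 4 (last linear), fused
## regressor 8 -> 8 -> 4 -> 1 (last linear).
denseSpec <- function(prefix, widths, inF) {
  lapply(seq_along(widths), function(i) {
    list(name = paste0(prefix, i),
         inF = if (i == 1) inF else widths[i - 1],
         outF = widths[i],
         act = if (i == length(widths)) "linear" else "relu")
  })
}

tinyTrunkSpec <- function(imageSize) {
  channels <- c(3L, 8L, 16L, 32L)
  H <- imageSize
  convs <- list()
  for (i in 1:3) {
    idx <- im2colIndex(H, H, channels[i], k = 3L, stride = 2L)
    od <- attr(idx, "outDim")
    convs[[i]] <- list(name = paste0("conv", i), k = 3L, stride = 2L,
                       inC = channels[i], outC = channels[i + 1],
                       inH = H, inW = H, outH = od[1], outW = od[2],
                       nPatch = od[1] * od[2], idx = idx)
    H <- od[1]
  }
  list(convs = convs, gapF = channels[4])
}

buildArch <- function(config) {
  if (config@backbone != "tiny_test_cnn")
    stop(sprintf(paste0("backbone '%s' requires externally supplied pretrained ",
                        "weights and is not constructible at desk scale; ",
                        "use backbone 'tiny_test_cnn'"), config@backbone),
         call. = FALSE)
  trunk <- tinyTrunkSpec(config@imageSize)
  arch <- list(imageSize = config@imageSize, mixed = config@mixedData,
               convs = trunk$convs, gapF = trunk$gapF)
  if (config@mixedData) {
    arch$imgHead <- denseSpec("img", c(512L, 4L), trunk$gapF)
    arch$climHead <- denseSpec("clim", c(64L, 32L, 4L), 6L)
    arch$fusion <- denseSpec("fus", c(8L, 8L, 4L, 1L), 8L)
  } else {
    arch$imgHead <- denseSpec("img", c(512L, 1L), trunk$gapF)
  }
  arch
}

## Initialisation. Convolutions and wide dense layers use He-normal weights
## (relu) or scaled-normal (linear). Narrow relu layers (<= 64 units; the
## climate branch and the 8-8-4 fusion stack) instead start "all alive":
## weight sd 0.4/sqrt(fan_in) with bias 0.5, so every unit's initial
## preactivation sits near +0.5 and none is dead at the start. With He
## variance a 4-unit relu layer frequently loses all its units during the
## first RMSprop steps, which silences every gradient upstream of it and
## freezes the model at a constant prediction. The final output bias starts
## at 0.5, the center of the normalised target range.
initParams <- function(arch, seed) {
  withSeed(seed, {
    params <- list()
    for (cv in arch$convs) {
      fanIn <- cv$k * cv$k * cv$inC
      params[[paste0(cv$name, ".W")]] <-
        matrix(stats::rnorm(fanIn * cv$outC, sd = sqrt(2 / fanIn)),
               fanIn, cv$outC)
      params[[paste0(cv$name, ".b")]] <- rep(0.05, cv$outC)
    }
    for (spec in c(arch$imgHead, arch$climHead, arch$fusion)) {
      narrow <- spec$act == "relu" && spec$outF <= 64L
      sdW <- if (narrow) 0.4 / sqrt(spec$inF)
      else if (spec$act == "relu") sqrt(2 / spec$inF)
      else sqrt(1 / spec$inF)
      params[[paste0(spec$name, ".W")]] <-
        matrix(stats::rnorm(spec$inF * spec$outF, sd = sdW),
               spec$inF, spec$outF)
      params[[paste0(spec$name, ".b")]] <-
        rep(if (spec$act != "relu") 0 else if (narrow) 0.5 else 0.05,
            spec$outF)
    }
    finalName <- if (arch$mixed) "fus4.b" else "img2.b"
    params[[finalName]] <- 0.5
    params
  })
}

## ---- forward / backward ---------------------------------------------------

denseForward <- function(params, specs, X, cache) {
  A <- X
  for (spec in specs) {
    W <- params[[paste0(spec$name, ".W")]]
    b <- params[[paste0(spec$name, ".b")]]
    Z <- crossprod(W, A) + b
    cache[[spec$name]] <- list(A = A, Z = Z)
    A <- if (spec$act == "relu") pmax(Z, 0) else Z
  }
  list(out = A, cache = cache)
}

denseBackward <- function(params, specs, dOut, cache, grads) {
  dA <- dOut
  for (spec in rev(specs)) {
    cc <- cache[[spec$name]]
    dZ <- if (spec$act == "relu") dA * (cc$Z > 0) else dA
    grads[[paste0(spec$name, ".W")]] <- cc$A %*% t(dZ)
    grads[[paste0(spec$name, ".b")]] <- rowSums(dZ)
    dA <- params[[paste0(spec$name, ".W")]] %*% dZ
  }
  list(dIn = dA, grads = grads)
}

## Full forward pass. Ximg: (H*W*3) x B; Xclim: 6 x B or NULL.
## Returns list(pred = numeric(B), cache) when keepCache, else just pred.
nnForward <- function(params, arch, Ximg, Xclim = NULL, keepCache = FALSE) {
  B <- ncol(Ximg)
  cache <- list()
  X <- Ximg
  for (cv in arch$convs) {
    G <- im2colGather(X, cv$idx, B)
    Z <- G %*% params[[paste0(cv$name, ".W")]]
    Z <- sweep(Z, 2, params[[paste0(cv$name, ".b")]], "+")
    if (keepCache) cache[[cv$name]] <- list(G = G, Z = Z)
    A <- pmax(Z, 0)
    X <- convToBatch(A, cv$nPatch, B)
  }
  ## global average pooling over spatial positions
  nPatch <- arch$convs[[length(arch$convs)]]$nPatch
  dim(X) <- c(nPatch, arch$gapF, B)
  gap <- colMeans(X)                      # (gapF, B)
  if (!is.matrix(gap)) gap <- matrix(gap, arch$gapF, B)
  if (arch$mixed) {
    assertThat(!is.null(Xclim), "mixed-data model needs climate inputs")
    assertThat(nrow(Xclim) == 6L && ncol(Xclim) == B,
               "climate input must be 6 x batch (got %d x %d)",
               nrow(Xclim), ncol(Xclim))
    fi <- denseForward(params, arch$imgHead, gap, cache)
    fc <- denseForward(params, arch$climHead, Xclim, fi$cache)
    fused <- rbind(fi$out, fc$out)
    ff <- denseForward(params, arch$fusion, fused, fc$cache)
    cache <- ff$cache
    pred <- as.numeric(ff$out)
  } else {
    fi <- denseForward(params, arch$imgHead, gap, cache)
    cache <- fi$cache
    pred <- as.numeric(fi$out)
  }
  if (keepCache) list(pred = pred, cache = cache) else pred
}

## Backward pass for the MSE loss 1/B * sum (pred - y)^2.
nnBackward <- function(params, arch, fw, y, Bsize) {
  dPred <- matrix(2 * (fw$pred - y) / Bsize, nrow = 1)
  grads <- list()
  if (arch$mixed) {
    bf <- denseBackward(params, arch$fusion, dPred, fw$cache, grads)
    dImg4 <- bf$dIn[1:4, , drop = FALSE]
    dClim4 <- bf$dIn[5:8, , drop = FALSE]
    bc <- denseBackward(params, arch$climHead, dClim4, fw$cache, bf$grads)
    bi <- denseBackward(params, arch$imgHead, dImg4, fw$cache, bc$grads)
  } else {
    bi <- denseBackward(params, arch$imgHead, dPred, fw$cache, grads)
  }
  grads <- bi$grads
  dGap <- bi$dIn                                  # (gapF, B)
  lastConv <- arch$convs[[length(arch$convs)]]
  nPatch <- lastConv$nPatch
  B <- ncol(dGap)
  dX <- dGap[rep(seq_len(arch$gapF), each = nPatch), , drop = FALSE] / nPatch
  for (i in rev(seq_along(arch$convs))) {
    cv <- arch$convs[[i]]
    dY <- batchToConv(dX, cv$nPatch, B)
    cc <- fw$cache[[cv$name]]
    dZ <- dY * (cc$Z > 0)
    grads[[paste0(cv$name, ".W")]] <- crossprod(cc$G, dZ)
    grads[[paste0(cv$name, ".b")]] <- colSums(dZ)
    if (i > 1L) {
      dG <- tcrossprod(dZ, params[[paste0(cv$name, ".W")]])
      dX <- im2colScatter(dG, cv$idx, B, cv$inH * cv$inW * cv$inC)
    }
  }
  grads
}

## RMSprop with per-step inverse-time learning-rate decay, the convention of
## the framework generation the training recipe comes from:
## lr_t = lr / (1 + decay * t), v = rho v + (1 - rho) g^2,
## theta <- theta - lr_t g / (sqrt(v) + eps); rho = 0.9, eps = 1e-7.
rmspropInit <- function(params) lapply(params, function(p) p * 0)

rmspropStep <- function(params, grads, state, step, lr, decay,
                        rho = 0.9, eps = 1e-7) {
  lrT <- lr / (1 + decay * step)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state[[nm]] <- rho * state[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lrT * g / (sqrt(state[[nm]]) + eps)
  }
  list(params = params, state = state)
}

nParams <- function(params) sum(vapply(params, length, integer(1)))
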