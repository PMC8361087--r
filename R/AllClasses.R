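#' @import methods
NULL

## Six traits handled throughout the package. LA leaf area, GH growth height,
## SLA specific leaf area, LNC leaf nitrogen concentration, SM seed mass,
## SSD stem specific density.
TRAIT_IDS <- c("LA", "GH", "SLA", "LNC", "SM", "SSD")

## Bioclim predictors attached to each photograph: BIO1 annual mean temperature,
## BIO4 temperature seasonality, BIO7 temperature annual range, BIO12 annual
## precipitation, BIO15 precipitation seasonality, plus the derived annual
## precipitation range BIO13 - BIO14.
BIOCLIM_LAYERS <- c("bio1", "bio4", "bio7", "bio12", "bio13", "bio14", "bio15")
BIOCLIM_VARS <- c("bio1", "bio4", "bio7", "bio12", "bio15", "bio13_14")

#' Train-only min-max normalisation parameters
#'
#' Holds the minimum and maximum of the log10-transformed training targets
#' (or of one bioclimatic variable over the training set). All partitions are
#' normalised with these two numbers so that no information about the
#' validation or test distribution leaks into training.
#'
#' @slot minTrain numeric(1), minimum of the training values.
#' @slot maxTrain numeric(1), maximum of the training values; must exceed
#'   \code{minTrain}.
#'
#' @seealso [fitNormalizer()], [normalizeValues()], [denormalizeValues()]
#' @export
setClass("NormalizationParams",
  representation(minTrain = "numeric", maxTrain = "numeric"),
  validity = function(object) {
    if (length(object@minTrain) != 1L || length(object@maxTrain) != 1L)
      return("minTrain and maxTrain must each be a single number")
    if (!is.finite(object@minTrain) || !is.finite(object@maxTrain))
      return("normalization bounds must be finite")
    if (object@maxTrain <= object@minTrain)
      return("degenerate normalization: maxTrain must be strictly greater than minTrain")
    TRUE
  }
)

#' Train / validation / test partition of linked observations
#'
#' The three partitions are disjoint by \code{record_id}. The validation share
#' is one fifth of what remains after the test set is removed (a 4:1
#' train:validation ratio), rounded down.
#'
#' @slot train data.frame of training observations.
#' @slot validation data.frame of validation observations.
#' @slot test data.frame of held-out test observations.
#' @slot seed integer seed that produced the partition.
#'
#' @seealso [makeSplit()]
#' @export
setClass("DatasetSplit",
  representation(train = "data.frame", validation = "data.frame",
                 test = "data.frame", seed = "integer"),
  validity = function(object) {
    ids <- c(object@train$record_id, object@validation$record_id,
             object@test$record_id)
    if (anyDuplicated(ids))
      return("train/validation/test must be disjoint by record_id")
    TRUE
  }
)

#' Configuration of a trait regression model
#'
#' @slot backbone character, one of \code{"tiny_test_cnn"},
#'   \code{"inception_resnet_v2"}, \code{"xception"},
#'   \code{"mobilenet_v2_half"}. Only the tiny backbone is constructible at
#'   desk scale; the large named architectures are configuration slots for
#'   full-scale runs and require externally supplied weights.
#' @slot mixedData logical; if TRUE the model fuses the image branch with a
#'   branch over the six normalised bioclimatic predictors.
#' @slot imageSize integer, input side length in pixels (square input).
#' @slot batchSize integer, minibatch size (default 20).
#' @slot lr numeric, RMSprop learning rate (default 0.001).
#' @slot lrDecay numeric, per-step inverse-time learning-rate decay
#'   (default 0.0001): the step-t rate is lr / (1 + lrDecay * t).
#' @slot loss character, currently \code{"mse"}.
#' @slot seed integer seed for weight initialisation and minibatch order.
#' @slot maxEpochs integer, hard cap on training epochs.
#' @slot patience integer, epochs without validation-MAE improvement before
#'   stopping (best-epoch weights are restored).
#'
#' @seealso [traitModelConfig()], [buildTraitModel()], [trainTraitModel()]
#' @export
setClass("TraitModelConfig",
  representation(backbone = "character", mixedData = "logical",
                 imageSize = "integer", batchSize = "integer",
                 lr = "numeric", lrDecay = "numeric", loss = "character",
                 seed = "integer", maxEpochs = "integer", patience = "integer"),
  validity = function(object) {
    backbones <- c("tiny_test_cnn", "inception_resnet_v2", "xception",
                   "mobilenet_v2_half")
    if (!object@backbone %in% backbones)
      return(paste0("unknown backbone '", object@backbone,
                    "'; valid options: ", paste(backbones, collapse = ", ")))
    if (object@imageSize < 32L) return("imageSize must be at least 32 pixels")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@lr <= 0) return("lr must be positive")
    if (object@loss != "mse") return("only the 'mse' loss is supported")
    if (object@patience < 1L) return("patience must be >= 1")
    TRUE
  }
)

#' A (possibly trained) trait regression model
#'
#' Wraps the network parameters together with the configuration that built
#' them and, after training, the per-epoch history and the normalisation
#' parameters of the targets it was fitted to.
#'
#' @slot config a [TraitModelConfig-class].
#' @slot params list of network weight matrices/vectors.
#' @slot arch internal architecture description.
#' @slot history data.frame with one row per trained epoch
#'   (columns epoch, train_mae, val_mae, lr).
#' @slot normParams the target [NormalizationParams-class] used in training
#'   (may be absent before training).
#' @slot trained logical.
#'
#' @export
setClass("TraitModel",
  representation(config = "TraitModelConfig", params = "list", arch = "list",
                 history = "data.frame", normParams = "ANY",
                 trained = "logical"))

#' Georeferenced raster of trait values
#'
#' A regular WGS84 longitude/latitude grid with cell-edge registration. Row 1
#' is the northernmost row (map orientation); values are only meaningful where
#' \code{mask} is TRUE.
#'
#' @slot values numeric matrix (nrow = rows south from the north edge,
#'   ncol = columns east from the west edge).
#' @slot mask logical matrix of the same shape; TRUE marks a valid cell.
#' @slot resolution numeric, cell size in degrees.
#' @slot xll,yll numeric, longitude/latitude of the lower-left corner
#'   of the grid (cell-edge convention).
#' @slot traitId character tag, e.g. \code{"LA"} (may be \code{""}).
#'
#' @seealso [traitGrid()], [idwGrid()], [readAsciiGrid()], [writeAsciiGrid()]
#' @export
setClass("TraitGrid",
  representation(values = "matrix", mask = "matrix", resolution = "numeric",
                 xll = "numeric", yll = "numeric", traitId = "character"),
  validity = function(object) {
    if (!identical(dim(object@values), dim(object@mask)))
      return("values and mask must have identical dimensions")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (object@resolution <= 0) return("resolution must be positive")
    if (any(!is.finite(object@values[object@mask])))
      return("values must be finite wherever mask is TRUE")
    TRUE
  }
)

#' Stack of co-registered climate rasters
#'
#' A named list of raster layers sharing one grid geometry, used to attach
#' bioclimatic predictors to photograph geolocations.
#'
#' @slot layers named list of numeric matrices (north row first), one per
#'   bioclim variable; NA encodes no-data (ocean) cells.
#' @slot resolution,xll,yll grid geometry shared by every layer
#'   (degrees; lower-left cell-edge corner).
#'
#' @seealso [climateStack()], [readClimateStack()], [extractBioclim()]
#' @export
setClass("ClimateStack",
  representation(layers = "list", resolution = "numeric",
                 xll = "numeric", yll = "numeric"),
  validity = function(object) {
    if (length(object@layers) == 0L) return("at least one layer required")
    if (is.null(names(object@layers)) || any(names(object@layers) == ""))
      return("layers must be named")
    dims <- vapply(object@layers, function(m) dim(m), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      return("all layers must share one grid shape")
    if (object@resolution <= 0) return("resolution must be positive")
    TRUE
  }
)

setMethod("show", "NormalizationParams", function(object) {
  cat(sprintf("NormalizationParams: min_train = %.6g, max_train = %.6g (range %.6g)\n",
              object@minTrain, object@maxTrain,
              object@maxTrain - object@minTrain))
})

setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf("DatasetSplit (seed %d): %d train / %d validation / %d test\n",
              object@seed, nrow(object@train), nrow(object@validation),
              nrow(object@test)))
})

setMethod("show", "TraitModelConfig", function(object) {
  cat(sprintf(paste0("TraitModelConfig: backbone=%s, %s, image %dpx, batch %d,\n",
                     "  RMSprop lr=%g decay=%g, loss=%s, maxEpochs=%d, patience=%d, seed=%d\n"),
              object@backbone,
              if (object@mixedData) "mixed image+climate" else "image-only",
              object@imageSize, object@batchSize, object@lr, object@lrDecay,
              object@loss, object@maxEpochs, object@patience, object@seed))
})

setMethod("show", "TraitModel", function(object) {
  n <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("TraitModel (%s, %s): %d parameters, %s\n",
              object@config@backbone,
              if (object@config@mixedData) "mixed" else "image-only",
              n,
              if (object@trained)
                sprintf("trained %d epochs (best val MAE %.4f)",
                        nrow(object@history), min(object@history$val_mae))
              else "untrained"))
})

setMethod("show", "TraitGrid", function(object) {
  cat(sprintf("TraitGrid%s: %d x %d cells at %g deg, origin (%g, %g), %d unmasked\n",
              if (nzchar(object@traitId)) paste0(" [", object@traitId, "]") else "",
              nrow(object@values), ncol(object@values), object@resolution,
              object@xll, object@yll, sum(object@mask)))
})

setMethod("show", "ClimateStack", function(object) {
  d <- dim(object@layers[[1]])
  cat(sprintf("ClimateStack: %s; %d x %d cells at %g deg, origin (%g, %g)\n",
              paste(names(object@layers), collapse = ", "),
              d[1], d[2], object@resolution, object@xll, object@yll))
})
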