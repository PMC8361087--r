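#' Average the predictions of an ensemble
#'
#' Element-wise arithmetic mean of aligned member prediction vectors.
#'
#' @param memberPredictions list of numeric vectors of equal length, aligned
#'   by record order.
#' @return numeric vector of ensemble predictions.
#' @export
ensemblePredict <- function(memberPredictions) {
  assertThat(length(memberPredictions) >= 1L, "need at least one member")
  lens <- vapply(memberPredictions, length, integer(1))
  assertThat(all(lens == lens[1]),
             "member prediction lengths differ (%s)",
             paste(lens, collapse = ", "))
  Reduce(`+`, memberPredictions) / length(memberPredictions)
}

#' Regression evaluation metrics: MAE, NMAE and R squared
#'
#' MAE is the mean absolute error; NMAE divides it by the range of the test
#' targets and is reported in percent, making performance comparable across
#' traits with different target scales; R squared is the explained variance
#' of the linear fit of predictions versus targets, i.e. the squared Pearson
#' correlation. Constant predictions carry no linear signal and are reported
#' as R squared 0; constant targets make NMAE undefined and are rejected.
#'
#' @param pred,target numeric vectors of equal length (>= 2).
#' @return list with \code{mae}, \code{nmae} (percent), \code{r2}, \code{n}.
#' @export
computeMetrics <- function(pred, target) {
  assertThat(length(pred) == length(target) && length(pred) >= 2L,
             "pred and target must have equal length >= 2")
  assertThat(all(is.finite(pred)) && all(is.finite(target)),
             "pred and target must be finite")
  rng <- max(target) - min(target)
  assertThat(rng > 0, "target range is zero; NMAE undefined")
  mae <- mean(abs(pred - target))
  r <- suppressWarnings(stats::cor(pred, target))
  r2 <- if (is.na(r)) 0 else r^2
  list(mae = mae, nmae = 100 * mae / rng, r2 = r2, n = length(pred))
}

#' k-fold cross-validation of a trait model
#'
#' Repeats the full split-train-evaluate cycle \code{k} times with
#' re-randomised train/validation/test partitions (each fold re-splits under
#' its own derived seed, so test sets differ between folds), evaluates each
#' fold's model on its held-out test set, and pools the prediction-target
#' pairs across folds (N = k x N_test).
#'
#' @param obs linked-observation data.frame (with \code{target} column; see
#'   [logTransformAndTrim()]).
#' @param trainer function(split) returning a prediction function
#'   \code{function(testDf) numeric}; see [traitModelTrainer()] for the
#'   standard CNN trainer, or supply any baseline (e.g. predict-the-mean).
#' @param k number of folds (>= 2).
#' @param seed base seed; fold i derives its own split seed from it.
#' @param testFrac test share per fold (default 0.1).
#' @return list with \code{folds} (per-fold metric lists), \code{pairs}
#'   (data.frame record_id, target, prediction, fold), \code{pooled}
#'   (metrics over all pooled pairs).
#' @export
crossValidate <- function(obs, trainer, k = 3L, seed = 1L, testFrac = 0.1) {
  assertThat(k >= 2L, "k must be at least 2")
  assertThat(nrow(obs) >= 10L * k, "insufficient data for %d folds", k)
  folds <- vector("list", k)
  pairs <- vector("list", k)
  for (i in seq_len(k)) {
    split <- makeSplit(obs, testFrac = testFrac,
                       seed = deriveSeed(seed, paste0("fold", i)))
    predictFun <- trainer(split)
    testDf <- testSet(split)
    pred <- predictFun(testDf)
    folds[[i]] <- computeMetrics(pred, testDf$target)
    pairs[[i]] <- data.frame(record_id = testDf$record_id,
                             target = testDf$target, prediction = pred,
                             fold = i, stringsAsFactors = FALSE)
  }
  allPairs <- do.call(rbind, pairs)
  list(folds = folds, pairs = allPairs,
       pooled = computeMetrics(allPairs$prediction, allPairs$target))
}

#' Standard CNN trainer for cross-validation
#'
#' Returns a \code{trainer} closure for [crossValidate()] that, per fold,
#' fits the target normaliser on that fold's training targets, trains the
#' configured model and predicts the fold's test set on the log10 target
#' scale (denormalised), so fold metrics are comparable to the targets.
#'
#' @param config a [TraitModelConfig-class]; for mixed-data configurations
#'   the bioclim normalisers are refit per fold on that fold's training
#'   partition.
#' @param plasticity train with plasticity target augmentation?
#' @return function(split) -> function(testDf) -> numeric predictions.
#' @export
traitModelTrainer <- function(config, plasticity = FALSE) {
  force(config); force(plasticity)
  function(split) {
    tp <- fitNormalizer(trainSet(split)$target)
    bp <- if (config@mixedData)
      lapply(stats::setNames(BIOCLIM_VARS, BIOCLIM_VARS),
             function(v) fitNormalizer(trainSet(split)[[v]]))
    else list()
    toData <- function(df)
      makeModelData(applyBioclimNorm(df, bp), config@imageSize, tp)
    model <- buildTraitModel(config)
    model <- trainTraitModel(model, toData(trainSet(split)),
                             toData(validationSet(split)),
                             plasticity = plasticity)
    function(testDf) denormalizeValues(predict(model, toData(testDf)), tp)
  }
}

#' Robustness of prediction errors across annotation categories
#'
#' Groups absolute prediction errors by an annotation category (growth form
#' woody/non-woody, image quality low/medium/high, or image-target distance
#' <1 m / 1-5 m / >5 m), reports each category's MAE and share of
#' observations, and tests for a location difference of the absolute errors
#' across categories with a nonparametric k-sample rank test
#' (Wilcoxon rank-sum for two groups, Kruskal-Wallis for more).
#'
#' @param preds data.frame with columns \code{prediction}, \code{target} and
#'   the grouping column named by \code{by}.
#' @param by name of the category column.
#' @return list with \code{table} (data.frame category, n, share_pct, mae)
#'   and \code{p_value}.
#' @export
groupedMAE <- function(preds, by) {
  assertThat(by %in% names(preds), "no column '%s' in preds", by)
  g <- factor(preds[[by]])
  present <- levels(g)[tabulate(g, nbins = nlevels(g)) > 0]
  assertThat(length(present) >= 2L,
             "need at least 2 non-empty categories in '%s' (found %d)",
             by, length(present))
  err <- abs(preds$prediction - preds$target)
  tab <- data.frame(
    category = levels(g),
    n = as.integer(tabulate(g, nbins = nlevels(g))),
    stringsAsFactors = FALSE)
  tab$share_pct <- 100 * tab$n / sum(tab$n)
  tab$mae <- vapply(levels(g), function(l) {
    e <- err[g == l]
    if (length(e)) mean(e) else NA_real_
  }, numeric(1))
  gi <- droplevels(g)
  p <- if (nlevels(gi) == 2L)
    stats::wilcox.test(err ~ gi, exact = FALSE)$p.value
  else stats::kruskal.test(err, gi)$p.value
  list(table = tab, p_value = p)
}
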