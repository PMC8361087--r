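#' Preset synthetic study conditions
#'
#' Three named corpus configurations used to characterise the pipeline:
#' \describe{
#'   \item{informative}{the default corpus: the trait is driven by visible
#'     disc area and greenness with small noise, so an image model can
#'     recover it.}
#'   \item{climate}{disc area and the climate covariate each carry about
#'     half of the trait variance (coefficients 20 on a ~ U(0.08, 0.42) and
#'     6.8 on z ~ U(0, 1) give equal variances), so fusing bioclim
#'     predictors has headroom over an image-only model.}
#'   \item{negative}{the trait is a species-level random effect independent
#'     of every visible and climatic feature; any apparent image signal is
#'     spurious.}
#' }
#'
#' @param condition one of \code{"informative"}, \code{"climate"},
#'   \code{"negative"}.
#' @param seed corpus seed.
#' @return a [syntheticCorpusSpec()].
#' @export
benchmarkSpec <- function(condition = c("informative", "climate", "negative"),
                          seed = 11L) {
  condition <- match.arg(condition)
  switch(condition,
         informative = syntheticCorpusSpec(seed = seed),
         climate = syntheticCorpusSpec(cArea = 20, cGreen = 0, cClim = 6.8,
                                       c0 = 2, seed = seed),
         negative = syntheticCorpusSpec(cArea = 0, cGreen = 0, cClim = 0,
                                        cSpecies = 2, c0 = 20, seed = seed))
}

#' Train and evaluate the tiny model on a synthetic corpus
#'
#' Runs the full pipeline end to end at desk scale: generate (or reuse) a
#' corpus, ingest trait and occurrence tables, attach bioclim predictors,
#' link and sample per species, log-transform, trim, split, normalise with
#' train-only statistics, train the \code{tiny_test_cnn} regressor
#' (64 px images, at most 10 epochs) and score the held-out test set.
#'
#' @param spec a [syntheticCorpusSpec()] (e.g. from [benchmarkSpec()]).
#' @param dir corpus directory; if it does not yet contain a generated
#'   corpus, one is created there.
#' @param mixed train the mixed image+climate model?
#' @param plasticity train with plasticity target augmentation?
#' @param modelSeed seed for model initialisation/training.
#' @param maxEpochs training epoch cap (default 10).
#' @return list with \code{metrics} (list mae/nmae/r2/n on the normalised
#'   scale), \code{model}, \code{prep} (split + normalisers),
#'   \code{predictions} and \code{testTargets} (normalised).
#' @export
syntheticBenchmark <- function(spec, dir, mixed = FALSE, plasticity = FALSE,
                               modelSeed = 21L, maxEpochs = 10L) {
  if (!file.exists(file.path(dir, "traits.csv")))
    generateCorpus(spec, dir)
  stats <- computeSpeciesStats(suppressMessages(
    removeTraitOutliers(readTraitTable(file.path(dir, "traits.csv")), 4)))
  occ <- suppressMessages(filterOccurrences(
    readOccurrenceTable(file.path(dir, "occurrences.csv"))))
  clim <- suppressMessages(extractBioclim(occ,
                                          readClimateStack(file.path(dir, "climate"))))
  occ <- merge(occ, clim, by = "record_id", sort = FALSE)
  prep <- suppressMessages(prepareTraitData(stats, occ, maxPerSpecies = 8,
                                            seed = deriveSeed(spec$seed, "prep")))
  cfg <- traitModelConfig(mixedData = mixed, imageSize = spec$imageSize,
                          seed = as.integer(modelSeed),
                          maxEpochs = as.integer(maxEpochs))
  toData <- function(df)
    makeModelData(applyBioclimNorm(df, prep$bioclimParams),
                  cfg@imageSize, prep$targetParams)
  model <- trainTraitModel(buildTraitModel(cfg),
                           toData(trainSet(prep$split)),
                           toData(validationSet(prep$split)),
                           plasticity = plasticity)
  pred <- predict(model, toData(testSet(prep$split)))
  targ <- normalizeValues(testSet(prep$split)$target, prep$targetParams)
  list(metrics = computeMetrics(pred, targ), model = model, prep = prep,
       predictions = pred, testTargets = targ)
}
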