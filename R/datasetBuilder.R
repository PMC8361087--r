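#' Link trait statistics to photographs with stratified per-species sampling
#'
#' Joins per-species trait statistics (see [computeSpeciesStats()]) to
#' occurrence records via species name (trimmed, case-folded) and samples at
#' most \code{maxPerSpecies} photographs per species, uniformly without
#' replacement under \code{seed}. Each species is a stratum: capping the
#' images per species keeps the model from learning species-specific trait
#' expressions while the number of species keeps the dataset large. Species
#' missing from either source contribute nothing.
#'
#' @param stats data.frame \code{species,trait_id,mean,sd,n_obs} for a single
#'   trait.
#' @param photos occurrence data.frame (filtered, optionally already joined
#'   to bioclim columns).
#' @param maxPerSpecies integer >= 1; trait-specific cap on photographs per
#'   species (the study design uses 8, 2, 3, 3, 1 and 5 for LA, GH, SLA, LNC,
#'   SM and SSD).
#' @param seed integer RNG seed for the per-species sampling.
#' @return data.frame of linked observations: the photo columns plus
#'   \code{trait_id}, \code{trait_mean}, \code{trait_sd}.
#' @export
linkAndSample <- function(stats, photos, maxPerSpecies, seed = 1L) {
  assertThat(length(maxPerSpecies) == 1L && maxPerSpecies >= 1,
             "maxPerSpecies must be a single integer >= 1")
  assertThat(length(unique(stats$trait_id)) <= 1L,
             "stats mix trait_ids; link one trait at a time")
  skey <- speciesKey(stats$species)
  pkey <- speciesKey(photos$species)
  m <- match(pkey, skey)
  cand <- which(!is.na(m))
  picked <- withSeed(seed, {
    unlist(lapply(split(cand, pkey[cand]), function(idx) {
      if (length(idx) <= maxPerSpecies) idx
      else sort(sample(idx, maxPerSpecies))
    }), use.names = FALSE)
  })
  picked <- sort(picked)
  out <- photos[picked, , drop = FALSE]
  out$trait_id <- if (nrow(stats)) stats$trait_id[1] else character(0)
  out$trait_mean <- stats$mean[m[picked]]
  out$trait_sd <- stats$sd[m[picked]]
  rownames(out) <- NULL
  out
}

#' log10-transform targets and trim extreme observations
#'
#' Sets each observation's regression target to \code{log10(trait_mean)}
#' (trait distributions are strongly right-skewed) and removes observations
#' whose log target lies more than \code{kSd} standard deviations from the
#' mean log target. With zero SD (all targets equal) nothing is removed.
#'
#' @param obs linked-observation data.frame with positive \code{trait_mean}.
#' @param kSd positive; trim threshold in SDs (default 3).
#' @return \code{obs} with a \code{target} column (log10 scale), trimmed.
#' @export
logTransformAndTrim <- function(obs, kSd = 3) {
  assertThat(kSd > 0, "kSd must be positive")
  bad <- which(!is.finite(obs$trait_mean) | obs$trait_mean <= 0)
  assertThat(length(bad) == 0,
             "non-positive trait value for record(s): %s",
             paste(utils::head(obs$record_id[bad], 5), collapse = ", "))
  obs$target <- log10(obs$trait_mean)
  m <- mean(obs$target)
  s <- sampleSD(obs$target)
  keep <- if (s == 0) rep(TRUE, nrow(obs)) else abs(obs$target - m) <= kSd * s
  if (any(!keep))
    message(sprintf("logTransformAndTrim: removed %d of %d observations beyond %g SD",
                    sum(!keep), nrow(obs), kSd))
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition observations into train / validation / test
#'
#' First extracts the test set (a random \code{testFrac} share, or exactly
#' \code{nTest} records when supplied), then splits the remainder R into
#' training and validation at a 4:1 ratio: validation gets \code{floor(R/5)}
#' records, training the rest. Sampling is uniform under \code{seed}; the
#' three partitions are disjoint by record.
#'
#' @param obs linked-observation data.frame.
#' @param testFrac fraction in (0,1) for the test set (default 0.1); the test
#'   count is \code{round(testFrac * nrow(obs))}.
#' @param seed integer RNG seed.
#' @param nTest optional explicit test-set size overriding \code{testFrac}
#'   (published dataset summaries often print test counts that are not an
#'   exact 10\%).
#' @return a [DatasetSplit-class].
#' @export
makeSplit <- function(obs, testFrac = 0.1, seed = 1L, nTest = NULL) {
  n <- nrow(obs)
  assertThat(n >= 10L, "need at least 10 observations to split (have %d)", n)
  if (is.null(nTest)) {
    assertThat(testFrac > 0 && testFrac < 1, "testFrac must be in (0,1)")
    nTest <- round(testFrac * n)
  }
  nTest <- as.integer(nTest)
  rest <- n - nTest
  nVal <- rest %/% 5L
  nTrain <- rest - nVal
  assertThat(nTest >= 1L && nVal >= 1L && nTrain >= 1L,
             "split leaves an empty partition (train %d / validation %d / test %d)",
             nTrain, nVal, nTest)
  idx <- withSeed(seed, {
    testIdx <- sample(n, nTest)
    remaining <- setdiff(seq_len(n), testIdx)
    valIdx <- sample(remaining, nVal)
    list(test = sort(testIdx), validation = sort(valIdx),
         train = sort(setdiff(remaining, valIdx)))
  })
  part <- function(i) { d <- obs[i, , drop = FALSE]; rownames(d) <- NULL; d }
  new("DatasetSplit", train = part(idx$train),
      validation = part(idx$validation), test = part(idx$test),
      seed = as.integer(seed))
}

#' Split partition accessors
#'
#' @param x a [DatasetSplit-class].
#' @return the requested partition as a data.frame.
#' @export
trainSet <- function(x) x@train

#' @rdname trainSet
#' @export
validationSet <- function(x) x@validation

#' @rdname trainSet
#' @export
testSet <- function(x) x@test

#' Fit min-max normalisation parameters on training targets only
#'
#' Records the minimum and maximum of the training values. Validation and
#' test values are later normalised with these same bounds, so information
#' about their distribution never leaks into training; their normalised
#' values may fall slightly outside [0, 1].
#'
#' @param trainValues numeric vector (log10 targets, or one bioclim variable
#'   over the training set) with at least two distinct values.
#' @return a [NormalizationParams-class].
#' @export
fitNormalizer <- function(trainValues) {
  v <- trainValues[is.finite(trainValues)]
  assertThat(length(v) >= 2L && max(v) > min(v),
             "cannot fit normalizer: need >= 2 distinct finite values")
  new("NormalizationParams", minTrain = min(v), maxTrain = max(v))
}

#' Min-max normalisation and its inverse
#'
#' \code{normalizeValues} maps x to (x - min_train) / (max_train - min_train);
#' training values land exactly in [0, 1], other partitions approximately
#' (values beyond the training extrema are deliberately not clipped here).
#' \code{denormalizeValues} is the exact algebraic inverse.
#'
#' @param x,y numeric vectors on the original / normalised scale.
#' @param p a [NormalizationParams-class].
#' @return numeric vector.
#' @export
normalizeValues <- function(x, p) {
  stopifnot(is(p, "NormalizationParams"))
  (x - p@minTrain) / (p@maxTrain - p@minTrain)
}

#' @rdname normalizeValues
#' @export
denormalizeValues <- function(y, p) {
  stopifnot(is(p, "NormalizationParams"))
  y * (p@maxTrain - p@minTrain) + p@minTrain
}

#' Normalisation bound accessors
#'
#' @param p a [NormalizationParams-class].
#' @return numeric(1).
#' @export
minTrain <- function(p) p@minTrain

#' @rdname minTrain
#' @export
maxTrain <- function(p) p@maxTrain

#' Plasticity target augmentation (truncated-Gaussian redraw)
#'
#' Encodes intra-specific trait variability by redrawing each training target
#' from the species' trait distribution instead of pinning it at the species
#' mean: a draw v ~ Normal(mu, sigma) truncated to [mu - sigma, mu + sigma]
#' in original trait units (small deviations from the mean stay more likely
#' than large ones), then log10-transformed, normalised with the train-only
#' bounds and clipped to [0, 1]. With sigma = 0 the unaugmented normalised
#' target is returned. A fresh draw is intended for every presentation of an
#' observation during training.
#'
#' Sampling uses the exact inverse-CDF construction
#' \code{qnorm(runif(n, pnorm(a), pnorm(b)))}.
#'
#' @param mu species trait mean, original units (> 0).
#' @param sigma species trait SD, original units (>= 0).
#' @param p target [NormalizationParams-class] (log10 scale).
#' @param n number of draws (default 1).
#' @return numeric vector of n normalised targets in [0, 1].
#' @export
plasticityAugment <- function(mu, sigma, p, n = 1L) {
  assertThat(length(mu) == 1L && length(sigma) == 1L, "mu and sigma are scalars")
  assertThat(is.finite(mu) && mu > 0, "mu must be positive")
  assertThat(is.finite(sigma) && sigma >= 0, "sigma must be non-negative")
  if (sigma == 0)
    return(rep(clip01(normalizeValues(log10(mu), p)), n))
  lo <- mu - sigma
  hi <- mu + sigma
  if (lo <= 0) {
    warning(sprintf("plasticityAugment: mu - sigma = %g <= 0; flooring the truncation interval above 0",
                    lo))
    lo <- .Machine$double.xmin
  }
  v <- rtruncnormInterval(n, mu, sigma, lo, hi)
  clip01(normalizeValues(log10(v), p))
}

## Exact truncated-normal sampler on [lo, hi] via the inverse CDF.
rtruncnormInterval <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' One-call dataset preparation: link, trim, split, fit normalisers
#'
#' Convenience wrapper chaining [linkAndSample()], [logTransformAndTrim()]
#' and [makeSplit()], then fitting the target normaliser and (when bioclim
#' columns are present) one normaliser per bioclim variable on the training
#' partition only.
#'
#' @param stats per-species trait statistics (one trait).
#' @param photos filtered occurrence data.frame, optionally with bioclim
#'   columns.
#' @param maxPerSpecies cap on photographs per species.
#' @param kSd log-target trim threshold in SDs (default 3).
#' @param testFrac,seed,nTest see [makeSplit()].
#' @return list with \code{split} ([DatasetSplit-class]), \code{targetParams}
#'   and \code{bioclimParams} (possibly empty named list).
#' @export
prepareTraitData <- function(stats, photos, maxPerSpecies, kSd = 3,
                             testFrac = 0.1, seed = 1L, nTest = NULL) {
  obs <- linkAndSample(stats, photos, maxPerSpecies, seed = seed)
  obs <- logTransformAndTrim(obs, kSd = kSd)
  split <- makeSplit(obs, testFrac = testFrac,
                     seed = deriveSeed(seed, "split"), nTest = nTest)
  tp <- fitNormalizer(split@train$target)
  bp <- if (all(BIOCLIM_VARS %in% names(split@train)))
    lapply(stats::setNames(BIOCLIM_VARS, BIOCLIM_VARS),
           function(v) fitNormalizer(split@train[[v]]))
  else list()
  list(split = split, targetParams = tp, bioclimParams = bp)
}

#' Add normalised bioclim columns to a data.frame
#'
#' @param df data.frame with the six raw bioclim columns.
#' @param bioclimParams named list of [NormalizationParams-class] per
#'   variable (train-only extrema).
#' @return \code{df} with added \code{bio*_n} columns.
#' @export
applyBioclimNorm <- function(df, bioclimParams) {
  for (v in names(bioclimParams))
    df[[paste0(v, "_n")]] <- normalizeValues(df[[v]], bioclimParams[[v]])
  df
}

#' Assemble and save a dataset manifest
#'
#' Normalises the targets and the six bioclim variables of every partition
#' with train-only parameters and writes one manifest CSV per partition plus
#' a JSON sidecar holding the normalisation bounds, seed and counts. This is
#' the on-disk contract between dataset building and model training.
#'
#' @param split a [DatasetSplit-class] whose partitions carry \code{target}
#'   and bioclim columns.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with elements \code{targetParams} and
#'   \code{bioclimParams} (named list per variable).
#' @export
writeDatasetManifest <- function(split, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tp <- fitNormalizer(split@train$target)
  haveClim <- all(BIOCLIM_VARS %in% names(split@train))
  bp <- if (haveClim)
    lapply(stats::setNames(BIOCLIM_VARS, BIOCLIM_VARS),
           function(v) fitNormalizer(split@train[[v]])) else list()
  for (part in c("train", "validation", "test")) {
    d <- slot(split, part)
    d$target_norm <- normalizeValues(d$target, tp)
    if (haveClim)
      for (v in BIOCLIM_VARS)
        d[[paste0(v, "_n")]] <- normalizeValues(d[[v]], bp[[v]])
    utils::write.csv(d, file.path(outDir, paste0(part, ".csv")),
                     row.names = FALSE)
  }
  side <- list(seed = split@seed,
               n = list(train = nrow(split@train),
                        validation = nrow(split@validation),
                        test = nrow(split@test)),
               target = list(min_train = tp@minTrain, max_train = tp@maxTrain),
               bioclim = lapply(bp, function(p)
                 list(min_train = p@minTrain, max_train = p@maxTrain)))
  jsonlite::write_json(side, file.path(outDir, "normalization.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(targetParams = tp, bioclimParams = bp))
}
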