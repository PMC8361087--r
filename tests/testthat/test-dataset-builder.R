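statsFor <- function(species, mean = 5, sd = 1) {
  data.frame(species = species, trait_id = "LA", mean = mean, sd = sd,
             n_obs = 5L, stringsAsFactors = FALSE)
}

photosFor <- function(species, perSpecies) {
  n <- length(species) * perSpecies
  data.frame(record_id = sprintf("p%04d", seq_len(n)),
             species = rep(species, each = perSpecies),
             image_ref = "x.png", lat = 1, lon = 1,
             coord_uncertainty_km = 1, stringsAsFactors = FALSE)
}

test_that("per-species sampling respects the cap and the seed", {
  st <- statsFor("Abies alba")
  ph <- photosFor("Abies alba", 3)
  expect_identical(nrow(linkAndSample(st, ph, 8, seed = 1)), 3L)

  st2 <- statsFor(c("A a", "B b", "C c"))
  ph2 <- photosFor(c("A a", "B b"), 4)
  one <- linkAndSample(st2, ph2, 1, seed = 2)
  expect_identical(nrow(one), 2L)
  expect_identical(sort(unique(one$species)), c("A a", "B b"))

  ph3 <- photosFor("A a", 20)
  s1 <- linkAndSample(statsFor("A a"), ph3, 5, seed = 42)
  s2 <- linkAndSample(statsFor("A a"), ph3, 5, seed = 42)
  expect_identical(nrow(s1), 5L)
  expect_identical(s1$record_id, s2$record_id)
  s3 <- linkAndSample(statsFor("A a"), ph3, 5, seed = 43)
  expect_false(identical(s1$record_id, s3$record_id))
  expect_error(linkAndSample(statsFor("A a"), ph3, 0), ">= 1")
})

test_that("no species exceeds its cap after linking a full corpus", {
  cp <- informativeCorpus()
  stats <- computeSpeciesStats(readTraitTable(cp$traitsPath))
  occ <- readOccurrenceTable(cp$occurrencesPath)
  for (cap in c(1L, 3L)) {
    linked <- linkAndSample(stats, occ, cap, seed = 9)
    expect_lte(max(table(linked$species)), cap)
  }
})

test_that("log transform and SD trim match a brute-force oracle", {
  obs <- photosFor("A a", 1)
  obs$trait_mean <- 100
  obs$trait_sd <- 0
  expect_equal(logTransformAndTrim(obs)$target, 2.0)

  same <- photosFor("A a", 12)
  same$trait_mean <- 50
  same$trait_sd <- 0
  expect_identical(nrow(logTransformAndTrim(same)), 12L)

  set.seed(77)
  many <- photosFor("A a", 40)
  many$trait_mean <- 10^rnorm(40, 1, 0.1)
  many$trait_sd <- 0
  lt <- log10(many$trait_mean)
  many$trait_mean[40] <- 10^(mean(lt) + 5 * sd(lt))   # plant a 5-SD outlier
  lt <- log10(many$trait_mean)
  keepOracle <- abs(lt - mean(lt)) <= 3 * sd(lt)
  out <- suppressMessages(logTransformAndTrim(many, 3))
  expect_identical(out$record_id, many$record_id[keepOracle])
  expect_false(many$record_id[40] %in% out$record_id)

  bad <- transform(obs, trait_mean = -1)
  expect_error(logTransformAndTrim(bad), bad$record_id[1])
})

test_that("split arithmetic follows test-then-4:1 with floor", {
  obs <- data.frame(record_id = sprintf("r%d", 1:10))
  sp <- makeSplit(obs, seed = 1, nTest = 1)
  expect_identical(nrow(trainSet(sp)), 8L)
  expect_identical(nrow(validationSet(sp)), 1L)
  expect_identical(nrow(testSet(sp)), 1L)
  ids <- c(trainSet(sp)$record_id, validationSet(sp)$record_id,
           testSet(sp)$record_id)
  expect_identical(sort(ids), sort(obs$record_id))
  expect_error(makeSplit(data.frame(record_id = 1:5)), "at least 10")
})

test_that("split sizes reproduce the published dataset summaries", {
  # (N_total, N_test) -> (N_training, N_validation) per trait dataset
  rows <- list(LA = c(10033, 1013, 7216, 1804),
               GH = c(15759, 1575, 11348, 2836),
               SLA = c(13140, 1314, 9461, 2365),
               LNC = c(12364, 1236, 8903, 2225),
               SM = c(9725, 972, 7003, 1750),
               SSD = c(10763, 1076, 7750, 1937))
  for (tr in names(rows)) {
    r <- rows[[tr]]
    obs <- data.frame(record_id = seq_len(r[1]))
    sp <- makeSplit(obs, seed = 4, nTest = r[2])
    expect_identical(nrow(trainSet(sp)), as.integer(r[3]))
    expect_identical(nrow(validationSet(sp)), as.integer(r[4]))
  }
})

test_that("normalisation is exact on boundaries and invertible", {
  p <- fitNormalizer(c(0, 2))
  expect_identical(minTrain(p), 0)
  expect_identical(maxTrain(p), 2)
  expect_identical(normalizeValues(0, p), 0)
  expect_identical(normalizeValues(2, p), 1)
  expect_identical(normalizeValues(1, p), 0.5)
  expect_equal(normalizeValues(1.7, fitNormalizer(c(1, 3))), 0.35)  # (1.7-1)/(3-1)
  # values beyond the training extrema are not clipped
  expect_gt(normalizeValues(2.5, p), 1)
  set.seed(5)
  x <- runif(100, -10, 10)
  expect_equal(denormalizeValues(normalizeValues(x, p), p), x,
               tolerance = 1e-12)
  expect_error(fitNormalizer(c(3, 3, 3)), "distinct")
})

test_that("train-only parameters differ from any range-extending superset", {
  trainT <- c(1, 2, 3)
  valT <- c(0.5, 3.4)
  pTrain <- fitNormalizer(trainT)
  pAll <- fitNormalizer(c(trainT, valT))
  expect_lt(minTrain(pAll), minTrain(pTrain))
  expect_gt(maxTrain(pAll), maxTrain(pTrain))
})

test_that("plasticity draws stay in the truncation interval and keep the mean", {
  p <- fitNormalizer(c(0, 2))   # log10 units: original range [1, 100]
  mu <- 20; sigma <- 4
  expect_identical(plasticityAugment(mu, 0, p, 5),
                   rep(normalizeValues(log10(mu), p), 5))
  set.seed(31)
  y <- plasticityAugment(mu, sigma, p, 1e5)
  v <- 10^denormalizeValues(y, p)   # back to original units (no clip active)
  expect_true(all(v >= mu - sigma - 1e-9 & v <= mu + sigma + 1e-9))
  # symmetric truncation preserves the mean: 3 Monte-Carlo SEs
  expect_lt(abs(mean(v) - mu), 3 * sd(v) / sqrt(length(v)))
  expect_true(all(y >= 0 & y <= 1))
  expect_warning(plasticityAugment(1, 2, p, 10), "flooring")
})

test_that("prepared data normalises targets and bioclim without leakage", {
  cp <- informativeCorpus()
  obs <- linkedObservations(cp)
  prep <- suppressMessages(prepareTraitData(
    computeSpeciesStats(readTraitTable(cp$traitsPath)),
    obs[setdiff(names(obs), c("trait_id", "trait_mean", "trait_sd", "target"))],
    maxPerSpecies = 8, seed = 13))
  tn <- normalizeValues(trainSet(prep$split)$target, prep$targetParams)
  expect_true(all(tn >= 0 & tn <= 1))
  expect_named(prep$bioclimParams,
               c("bio1", "bio4", "bio7", "bio12", "bio15", "bio13_14"))
  d <- applyBioclimNorm(testSet(prep$split), prep$bioclimParams)
  expect_true(all(paste0(names(prep$bioclimParams), "_n") %in% names(d)))
})

test_that("dataset manifests round-trip counts and normalisation bounds", {
  cp <- informativeCorpus()
  obs <- linkedObservations(cp)
  sp <- makeSplit(obs, seed = 2)
  out <- file.path(tempdir(), "manifest-test")
  prm <- writeDatasetManifest(sp, out)
  side <- jsonlite::read_json(file.path(out, "normalization.json"),
                              simplifyVector = TRUE)
  expect_identical(side$n$train, nrow(trainSet(sp)))
  expect_equal(side$target$min_train, minTrain(prm$targetParams))
  tr <- read.csv(file.path(out, "train.csv"))
  expect_true(all(tr$target_norm >= 0 & tr$target_norm <= 1))
})
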