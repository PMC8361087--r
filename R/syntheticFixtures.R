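#' Specification of a synthetic trait-photograph corpus
#'
#' Describes a fully synthetic stand-in for the real data linkage: species
#' with trait distributions, plant-like photographs whose visible features
#' deterministically encode the trait, geolocations on a toy landmass, and
#' smooth climate surfaces. The generator makes the working hypothesis of
#' the method literally true: the trait is an affine function of the visible
#' disc-area fraction of the "leaves", their green color intensity and
#' (optionally) the local climate, so a feature-learning model can recover
#' it and a feature-blind configuration cannot.
#'
#' The trait law, per image i of species s at location x, is
#' \deqn{t_i = c_0 + c_{area} a_i + c_{green} g_i + c_{clim} z(x) + u_s + \epsilon_i}
#' with a the ellipse-area fraction, g the mean foreground greenness, z the
#' min-max scaled annual mean temperature at x, u_s ~ N(0, cSpecies) a
#' species effect independent of all visible features (for negative
#' controls), and noise sd \code{sigmaNoise}. Species are climate-localised:
#' each has a range center and its images scatter around it, so the species
#' mean trait carries the climate signal of its range.
#'
#' @param nSpecies number of species (default 100).
#' @param imagesPerSpecies integer range c(lo, hi) of images per species
#'   (default c(3, 7); the default corpus is ~500 images).
#' @param nTraitRecords trait measurements per species in the trait table
#'   (default 5).
#' @param traitId trait tag for generated tables (default "LA").
#' @param c0,cArea,cGreen,cClim,cSpecies,sigmaNoise trait-law coefficients
#'   (defaults 2, 30, 8, 0, 0, 0.5).
#' @param sdFrac per-species trait SD as a fraction of the mean, feeding the
#'   plasticity sampler (default 0.1).
#' @param areaJitter,greenJitter within-species SD of the per-image visible
#'   features (defaults 0.02, 0.03).
#' @param imageSize square image side in pixels (default 64).
#' @param rangeSd spread of a species' image locations around its range
#'   center, degrees (default 2).
#' @param seed integer seed; the corpus is a deterministic function of the
#'   spec (default 1).
#' @return validated spec list of class \code{syntheticSpec}.
#' @export
syntheticCorpusSpec <- function(nSpecies = 100L, imagesPerSpecies = c(3L, 7L),
                                nTraitRecords = 5L, traitId = "LA",
                                c0 = 2, cArea = 30, cGreen = 8, cClim = 0,
                                cSpecies = 0, sigmaNoise = 0.5, sdFrac = 0.1,
                                areaJitter = 0.02, greenJitter = 0.03,
                                imageSize = 64L, rangeSd = 2, seed = 1L) {
  spec <- list(nSpecies = as.integer(nSpecies),
               imagesPerSpecies = as.integer(imagesPerSpecies),
               nTraitRecords = as.integer(nTraitRecords), traitId = traitId,
               c0 = c0, cArea = cArea, cGreen = cGreen, cClim = cClim,
               cSpecies = cSpecies, sigmaNoise = sigmaNoise, sdFrac = sdFrac,
               areaJitter = areaJitter, greenJitter = greenJitter,
               imageSize = as.integer(imageSize), rangeSd = rangeSd,
               seed = as.integer(seed))
  assertThat(spec$nSpecies >= 1L && spec$nTraitRecords >= 1L &&
               all(spec$imagesPerSpecies >= 1L),
             "all counts must be >= 1")
  assertThat(length(spec$imagesPerSpecies) == 2L &&
               spec$imagesPerSpecies[1] <= spec$imagesPerSpecies[2],
             "imagesPerSpecies must be c(lo, hi) with lo <= hi")
  assertThat(spec$sigmaNoise >= 0 && spec$sdFrac >= 0 && spec$cSpecies >= 0,
             "noise parameters must be non-negative")
  assertThat(spec$imageSize >= 32L, "imageSize must be >= 32")
  assertThat(spec$traitId %in% TRAIT_IDS, "traitId must be one of %s",
             paste(TRAIT_IDS, collapse = ", "))
  class(spec) <- "syntheticSpec"
  spec
}

## Toy landmass: a rectangle in WGS84 with smooth climate gradients.
## Rasters extend beyond the landmass with no-data (ocean) cells so that
## off-land extraction and land masking are exercised.
SYNTH_LAND <- list(lonMin = 0, lonMax = 40, latMin = 0, latMax = 40)
SYNTH_EXTENT <- c(-5, 45, -5, 45)

synthClimateField <- function(layer, lon, lat) {
  switch(layer,
         bio1 = 28 - 0.5 * lat,            # degC, cools poleward
         bio4 = 200 + 10 * lat,            # seasonality grows poleward
         bio7 = 18 + 0.4 * lat,            # degC annual range
         bio12 = 400 + 25 * lon,           # mm, wetter eastward
         bio13 = 80 + 3 * lon,             # mm wettest month
         bio14 = 15 + 0.5 * lon,           # mm driest month
         bio15 = 40 + 0.8 * lat,
         stop("unknown layer ", layer))
}

onSynthLand <- function(lon, lat) {
  lon >= SYNTH_LAND$lonMin & lon <= SYNTH_LAND$lonMax &
    lat >= SYNTH_LAND$latMin & lat <= SYNTH_LAND$latMax
}

## bio1 min-max scaled over the landmass; the climate covariate z of the
## trait law.
synthClimScaled <- function(lat) {
  b <- synthClimateField("bio1", 0, lat)
  lo <- synthClimateField("bio1", 0, SYNTH_LAND$latMax)
  hi <- synthClimateField("bio1", 0, SYNTH_LAND$latMin)
  (b - lo) / (hi - lo)
}

#' Build the toy climate rasters
#'
#' Seven smooth gradient layers (bio1, bio4, bio7, bio12, bio13, bio14,
#' bio15) over the synthetic landmass at the given resolution; cells outside
#' the landmass are no-data.
#'
#' @param resolution cell size in degrees (default 1).
#' @return a [ClimateStack-class].
#' @export
synthClimateStack <- function(resolution = 1) {
  ncolG <- as.integer((SYNTH_EXTENT[2] - SYNTH_EXTENT[1]) / resolution)
  nrowG <- as.integer((SYNTH_EXTENT[4] - SYNTH_EXTENT[3]) / resolution)
  lonC <- gridLonCenters(ncolG, resolution, SYNTH_EXTENT[1])
  latC <- gridLatCenters(nrowG, resolution, SYNTH_EXTENT[3])
  lonM <- matrix(lonC, nrowG, ncolG, byrow = TRUE)
  latM <- matrix(latC, nrowG, ncolG)
  land <- onSynthLand(lonM, latM)
  layers <- lapply(stats::setNames(BIOCLIM_LAYERS, BIOCLIM_LAYERS),
                   function(nm) {
                     m <- synthClimateField(nm, lonM, latM)
                     m[!land] <- NA
                     m
                   })
  climateStack(layers, resolution, SYNTH_EXTENT[1], SYNTH_EXTENT[3])
}

#' Land mask of the toy landmass
#'
#' @param resolution cell size in degrees (default 1).
#' @return a [TraitGrid-class] with value 1 on land, masked elsewhere.
#' @export
synthLandMask <- function(resolution = 1) {
  cs <- synthClimateStack(resolution)
  land <- is.finite(cs@layers$bio1)
  v <- matrix(NA_real_, nrow(land), ncol(land))
  v[land] <- 1
  traitGrid(v, land, resolution, cs@xll, cs@yll)
}

## Render one synthetic plant image: a textured background with a single
## elliptical "leaf" of requested area fraction and green intensity.
## Returns the (S, S, 3) array and the realised pixel-area fraction.
renderSynthImage <- function(size, areaFrac, greenness) {
  S <- size
  areaFrac <- min(max(areaFrac, 0.02), 0.42)
  q <- stats::runif(1, 0.65, 1)               # axis ratio r2/r1
  theta <- stats::runif(1, 0, pi)
  A <- areaFrac * S * S
  r1 <- sqrt(A / (pi * q))
  r2 <- q * r1
  rMax <- max(r1, r2)
  slack <- S / 2 - rMax - 1
  cx <- S / 2 + stats::runif(1, -1, 1) * max(0, min(slack, S / 8))
  cy <- S / 2 + stats::runif(1, -1, 1) * max(0, min(slack, S / 8))
  px <- matrix(seq_len(S) - 0.5, S, S)        # x varies down rows
  py <- matrix(seq_len(S) - 0.5, S, S, byrow = TRUE)
  dx <- px - cx
  dy <- py - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / r1
  v <- (-dx * sin(theta) + dy * cos(theta)) / r2
  inside <- (u * u + v * v) <= 1
  img <- array(0, c(S, S, 3))
  img[, , 1] <- 0.35 + stats::runif(S * S, -0.08, 0.08)
  img[, , 2] <- 0.28 + stats::runif(S * S, -0.08, 0.08)
  img[, , 3] <- 0.20 + stats::runif(S * S, -0.08, 0.08)
  fg <- which(inside)
  img[, , 1][fg] <- 0.15 + stats::runif(length(fg), -0.02, 0.02)
  img[, , 2][fg] <- greenness + stats::runif(length(fg), -0.02, 0.02)
  img[, , 3][fg] <- 0.10 + stats::runif(length(fg), -0.02, 0.02)
  list(img = clip01(img), pixelFrac = sum(inside) / (S * S))
}

#' Generate a complete synthetic corpus
#'
#' Deterministically (in \code{spec$seed}) produces every input the pipeline
#' consumes: a trait table (\code{traits.csv}), an occurrence table
#' (\code{occurrences.csv}), PNG images, the seven climate rasters and a
#' land mask (\code{climate/*.asc}), plus a ground-truth table
#' (\code{ground_truth.csv}) recording each image's requested and realised
#' area fraction, greenness, climate covariate and latent trait value.
#' Species trait records are drawn from Normal(mean_s, sdFrac * mean_s), so
#' the per-species statistics computed by [computeSpeciesStats()] are
#' consistent with the latent species means up to sampling error.
#'
#' @param spec a [syntheticCorpusSpec()].
#' @param outDir output directory (created).
#' @return invisibly, a list with the table paths, the in-memory
#'   data.frames, the [ClimateStack-class] and land-mask grid.
#' @export
generateCorpus <- function(spec, outDir) {
  stopifnot(inherits(spec, "syntheticSpec"))
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "climate"), showWarnings = FALSE)
  withSeed(spec$seed, {
    ns <- spec$nSpecies
    speciesNames <- sprintf("Synthetica specimen%03d", seq_len(ns))
    aS <- stats::runif(ns, 0.08, 0.42)
    gS <- stats::runif(ns, 0.25, 0.95)
    uS <- stats::rnorm(ns, 0, spec$cSpecies)
    centerLon <- stats::runif(ns, SYNTH_LAND$lonMin + 1, SYNTH_LAND$lonMax - 1)
    centerLat <- stats::runif(ns, SYNTH_LAND$latMin + 1, SYNTH_LAND$latMax - 1)
    muS <- spec$c0 + spec$cArea * aS + spec$cGreen * gS +
      spec$cClim * synthClimScaled(centerLat) + uS
    assertThat(all(muS > 0),
               "trait law yields non-positive species means; adjust coefficients")
    ## trait table
    traits <- data.frame(
      species = rep(speciesNames, each = spec$nTraitRecords),
      trait_id = spec$traitId,
      value = stats::rnorm(ns * spec$nTraitRecords,
                           rep(muS, each = spec$nTraitRecords),
                           rep(spec$sdFrac * muS, each = spec$nTraitRecords)),
      stringsAsFactors = FALSE)
    assertThat(all(traits$value > 0),
               "trait law yields non-positive trait records; adjust coefficients")
    ## occurrences + images + ground truth
    nImg <- if (spec$imagesPerSpecies[1] == spec$imagesPerSpecies[2])
      rep(spec$imagesPerSpecies[1], ns)
    else sample(spec$imagesPerSpecies[1]:spec$imagesPerSpecies[2], ns,
                replace = TRUE)
    rows <- vector("list", sum(nImg))
    r <- 0L
    for (s in seq_len(ns)) {
      for (j in seq_len(nImg[s])) {
        r <- r + 1L
        repeat {
          lon <- centerLon[s] + stats::rnorm(1, 0, spec$rangeSd)
          lat <- centerLat[s] + stats::rnorm(1, 0, spec$rangeSd)
          if (onSynthLand(lon, lat)) break
        }
        a <- min(max(aS[s] + stats::rnorm(1, 0, spec$areaJitter), 0.03), 0.42)
        g <- min(max(gS[s] + stats::rnorm(1, 0, spec$greenJitter), 0.05), 1)
        z <- synthClimScaled(lat)
        t <- spec$c0 + spec$cArea * a + spec$cGreen * g + spec$cClim * z +
          uS[s] + stats::rnorm(1, 0, spec$sigmaNoise)
        rend <- renderSynthImage(spec$imageSize, a, g)
        path <- file.path(outDir, "images", sprintf("img_%05d.png", r))
        png::writePNG(rend$img, path)
        rows[[r]] <- data.frame(
          record_id = sprintf("rec%05d", r), species = speciesNames[s],
          image_ref = path, lat = lat, lon = lon,
          coord_uncertainty_km = stats::runif(1, 0, 10),
          area_frac = a, pixel_frac = rend$pixelFrac, greenness = g,
          clim_scaled = z, latent_trait = t, stringsAsFactors = FALSE)
      }
    }
    allRows <- do.call(rbind, rows)
    assertThat(all(allRows$latent_trait > 0),
               "trait law yields non-positive latent traits; adjust coefficients")
    occ <- allRows[c("record_id", "species", "image_ref", "lat", "lon",
                     "coord_uncertainty_km")]
    gt <- allRows[c("record_id", "species", "area_frac", "pixel_frac",
                    "greenness", "clim_scaled", "latent_trait")]
    ## climate rasters + land mask
    cs <- synthClimateStack()
    for (nm in names(cs@layers))
      writeAsciiGrid(cs@layers[[nm]],
                     file.path(outDir, "climate", paste0(nm, ".asc")),
                     cs@resolution, cs@xll, cs@yll)
    lm <- synthLandMask()
    writeTraitGrid(lm, file.path(outDir, "climate", "land.asc"))
    utils::write.csv(traits, file.path(outDir, "traits.csv"),
                     row.names = FALSE)
    utils::write.csv(occ, file.path(outDir, "occurrences.csv"),
                     row.names = FALSE)
    utils::write.csv(gt, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
    invisible(list(
      traitsPath = file.path(outDir, "traits.csv"),
      occurrencesPath = file.path(outDir, "occurrences.csv"),
      groundTruthPath = file.path(outDir, "ground_truth.csv"),
      climateDir = file.path(outDir, "climate"),
      traits = traits, occurrences = occ, groundTruth = gt,
      climate = cs, landMask = lm))
  })
}
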