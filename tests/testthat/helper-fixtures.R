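# Shared fixture builders. Everything is generated in code at test time;
# corpora are cached per session so multiple test files can reuse them.

.fixtureCache <- new.env(parent = emptyenv())

cachedCorpus <- function(tag, spec) {
  if (!is.null(.fixtureCache[[tag]])) return(.fixtureCache[[tag]])
  dir <- file.path(tempdir(), paste0("phototrait-fixture-", tag))
  unlink(dir, recursive = TRUE)
  cp <- generateCorpus(spec, dir)
  .fixtureCache[[tag]] <- cp
  cp
}

# Default informative corpus: trait driven by disc area + greenness.
informativeCorpus <- function()
  cachedCorpus("informative", syntheticCorpusSpec(seed = 11L))

# Run ingest + linkage on a corpus, returning trimmed linked observations
# with bioclim columns.
linkedObservations <- function(cp, maxPerSpecies = 8, seed = 3L) {
  stats <- computeSpeciesStats(
    suppressMessages(removeTraitOutliers(readTraitTable(cp$traitsPath), 4)))
  occ <- suppressMessages(filterOccurrences(readOccurrenceTable(cp$occurrencesPath)))
  clim <- suppressMessages(extractBioclim(occ, readClimateStack(cp$climateDir)))
  occ2 <- merge(occ, clim, by = "record_id", sort = FALSE)
  suppressMessages(logTransformAndTrim(
    linkAndSample(stats, occ2, maxPerSpecies, seed = seed)))
}

# Small in-memory trait record table.
traitRecords <- function(values, species = "Abies alba", trait = "LA") {
  data.frame(species = rep_len(species, length(values)),
             trait_id = rep_len(trait, length(values)),
             value = values, stringsAsFactors = FALSE)
}

# Occurrence rows with controllable validity.
occRecords <- function(n, lat = 10, lon = 10, unc = 5) {
  data.frame(record_id = sprintf("r%03d", seq_len(n)),
             species = "Abies alba", image_ref = "x.png",
             lat = rep_len(lat, n), lon = rep_len(lon, n),
             coord_uncertainty_km = rep_len(unc, n),
             stringsAsFactors = FALSE)
}

# Independent haversine implementation (test-side oracle; the package uses
# geosphere). Radius 6371 km.
oracleHaversineKm <- function(lon1, lat1, lon2, lat2) {
  toRad <- pi / 180
  dlat <- (lat2 - lat1) * toRad
  dlon <- (lon2 - lon1) * toRad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}
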