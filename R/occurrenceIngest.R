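#' Read an occurrence table
#'
#' Reads a GBIF/iNaturalist-export style occurrence CSV with columns
#' \code{record_id,species,image_ref,lat,lon,coord_uncertainty_km}
#' (the uncertainty column may be absent or contain missing values).
#'
#' @param path path to the CSV file.
#' @return data.frame with those columns; \code{coord_uncertainty_km} is NA
#'   where unknown.
#' @export
readOccurrenceTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "species", "image_ref", "lat", "lon")
  assertThat(all(need %in% names(df)),
             "occurrence table %s must have columns %s", path,
             paste(need, collapse = ","))
  if (!"coord_uncertainty_km" %in% names(df))
    df$coord_uncertainty_km <- NA_real_
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  df$coord_uncertainty_km <- as.numeric(df$coord_uncertainty_km)
  assertThat(!anyDuplicated(df$record_id),
             "occurrence table %s has duplicated record_ids", path)
  df[c(need, "coord_uncertainty_km")]
}

#' Geospatial quality filter for occurrence records
#'
#' Drops records with missing coordinates, coordinates outside WGS84 bounds,
#' or a reported coordinate uncertainty strictly greater than
#' \code{maxUncertaintyKm}. Records with valid coordinates but an unknown
#' uncertainty are kept (occurrence exports frequently omit the field).
#' An optional allow-list restricts records to trusted species names, standing
#' in for upstream curation of presumed wrong identifications. Order is
#' preserved and per-reason drop counts are reported via \code{message()}.
#'
#' @param records occurrence data.frame (see [readOccurrenceTable()]).
#' @param maxUncertaintyKm positive; records reporting a larger uncertainty
#'   are dropped (default 100, boundary inclusive: exactly 100 km is kept).
#' @param speciesAllowList optional character vector; if given, records whose
#'   (trimmed, case-folded) species is not listed are dropped.
#' @return the retained records.
#' @export
filterOccurrences <- function(records, maxUncertaintyKm = 100,
                              speciesAllowList = NULL) {
  assertThat(maxUncertaintyKm > 0, "maxUncertaintyKm must be positive")
  missingCoord <- !is.finite(records$lat) | !is.finite(records$lon)
  outOfBounds <- !missingCoord &
    (records$lat < -90 | records$lat > 90 |
       records$lon < -180 | records$lon > 180)
  tooUncertain <- !is.na(records$coord_uncertainty_km) &
    records$coord_uncertainty_km > maxUncertaintyKm
  badSpecies <- if (is.null(speciesAllowList)) rep(FALSE, nrow(records)) else
    !(speciesKey(records$species) %in% speciesKey(speciesAllowList))
  drop <- missingCoord | outOfBounds | tooUncertain | badSpecies
  if (any(drop))
    message(sprintf(paste0("filterOccurrences: dropped %d of %d records ",
                           "(%d missing coords, %d out of bounds, ",
                           "%d uncertainty > %g km, %d species not allowed)"),
                    sum(drop), nrow(records), sum(missingCoord),
                    sum(outOfBounds), sum(tooUncertain), maxUncertaintyKm,
                    sum(badSpecies)))
  records[!drop, , drop = FALSE]
}

#' Attach bioclimatic predictors to occurrence records
#'
#' Looks up, for each record, the climate raster cell containing its
#' geolocation (nearest-cell extraction, no interpolation) and assembles the
#' six predictors used downstream: bio1, bio4, bio7, bio12, bio15 and the
#' derived annual precipitation range bio13_14 = bio13 - bio14. Records whose
#' point falls outside the rasters or on a no-data (ocean) cell in any layer
#' are excluded, mirroring the removal of photographs that cannot be linked
#' to climate data.
#'
#' @param records occurrence data.frame with \code{record_id,lat,lon}.
#' @param stack a [ClimateStack-class] providing layers bio1, bio4, bio7,
#'   bio12, bio13, bio14, bio15.
#' @return data.frame \code{record_id,bio1,bio4,bio7,bio12,bio15,bio13_14},
#'   one row per linkable record, in input order.
#' @export
extractBioclim <- function(records, stack) {
  missing <- setdiff(BIOCLIM_LAYERS, names(stack@layers))
  assertThat(length(missing) == 0, "climate stack lacks layer(s): %s",
             paste(missing, collapse = ", "))
  l1 <- stack@layers[[1]]
  idx <- cellIndex(records$lon, records$lat, nrow(l1), ncol(l1),
                   stack@resolution, stack@xll, stack@yll)
  flat <- ifelse(is.na(idx[, "row"]), NA_integer_,
                 idx[, "row"] + (idx[, "col"] - 1L) * nrow(l1))
  vals <- vapply(BIOCLIM_LAYERS,
                 function(nm) stack@layers[[nm]][flat], numeric(nrow(records)))
  if (nrow(records) == 1L) vals <- matrix(vals, nrow = 1,
                                          dimnames = list(NULL, BIOCLIM_LAYERS))
  ok <- rowSums(!is.finite(vals)) == 0
  if (any(!ok))
    message(sprintf("extractBioclim: %d of %d records not linkable to climate data",
                    sum(!ok), nrow(records)))
  out <- data.frame(record_id = records$record_id[ok],
                    vals[ok, c("bio1", "bio4", "bio7", "bio12", "bio15"),
                         drop = FALSE],
                    bio13_14 = vals[ok, "bio13"] - vals[ok, "bio14"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
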