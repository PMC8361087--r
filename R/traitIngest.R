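#' Read a trait table
#'
#' Reads a long-format trait table with columns \code{species}, \code{trait_id}
#' and \code{value}. Values are expected in the trait's standardized unit and
#' must be strictly positive (the downstream pipeline log10-transforms them).
#' A TRY-export wide table (one column per trait) can be converted with
#' [widenToLong()].
#'
#' @param path path to a CSV file with columns \code{species,trait_id,value}.
#' @return data.frame with columns \code{species} (character),
#'   \code{trait_id} (character, one of LA, GH, SLA, LNC, SM, SSD) and
#'   \code{value} (positive numeric).
#' @export
readTraitTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "trait_id", "value")
  assertThat(all(need %in% names(df)),
             "trait table %s must have columns %s", path,
             paste(need, collapse = ","))
  df$value <- as.numeric(df$value)
  validateTraitRecords(df)
  df[need]
}

#' Convert a wide (one column per trait) table to the long trait format
#'
#' @param df data.frame with a \code{species} column and one numeric column
#'   per trait id (subset of LA, GH, SLA, LNC, SM, SSD); NA cells are dropped.
#' @return long data.frame \code{species,trait_id,value}.
#' @export
widenToLong <- function(df) {
  assertThat("species" %in% names(df), "wide table needs a 'species' column")
  traits <- intersect(names(df), TRAIT_IDS)
  assertThat(length(traits) > 0, "no trait columns (%s) found",
             paste(TRAIT_IDS, collapse = ", "))
  out <- do.call(rbind, lapply(traits, function(tr) {
    keep <- !is.na(df[[tr]])
    data.frame(species = df$species[keep], trait_id = tr,
               value = as.numeric(df[[tr]][keep]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

validateTraitRecords <- function(records) {
  assertThat(all(nzchar(trimws(records$species))),
             "trait records contain empty species names")
  bad <- setdiff(unique(records$trait_id), TRAIT_IDS)
  assertThat(length(bad) == 0, "unknown trait_id(s): %s (expected %s)",
             paste(bad, collapse = ", "), paste(TRAIT_IDS, collapse = ", "))
  assertThat(all(is.finite(records$value) & records$value > 0),
             "trait values must be finite and strictly positive")
  invisible(records)
}

#' Remove outlying trait records by standardized deviation
#'
#' Drops records whose deviation from the pooled trait mean exceeds
#' \code{zMax} pooled standard deviations, i.e. keeps records with
#' \eqn{|v - \bar v| / s \le z_{max}}. The threshold follows the convention of
#' trait-database release notes, where an "error risk" of 4 marks a value four
#' standard deviations from the mean. With zero pooled SD (all values equal)
#' every record is retained. Input order is preserved.
#'
#' @param records data.frame of trait records sharing one \code{trait_id}.
#' @param zMax positive number of pooled SDs tolerated (default 4).
#' @return the retained records; the number removed is reported via
#'   \code{message()}.
#' @export
removeTraitOutliers <- function(records, zMax = 4) {
  assertThat(zMax > 0, "zMax must be positive")
  if (nrow(records) == 0L) return(records)
  ids <- unique(records$trait_id)
  assertThat(length(ids) == 1L,
             "records mix trait_ids (%s); filter one trait at a time",
             paste(ids, collapse = ", "))
  m <- mean(records$value)
  s <- sampleSD(records$value)
  keep <- if (s == 0) rep(TRUE, nrow(records)) else
    abs(records$value - m) / s <= zMax
  if (any(!keep))
    message(sprintf("removeTraitOutliers: removed %d of %d %s records (z > %g)",
                    sum(!keep), nrow(records), ids, zMax))
  records[keep, , drop = FALSE]
}

#' Per-species trait means and standard deviations
#'
#' Aggregates outlier-filtered trait records to one row per
#' (species, trait_id): the arithmetic mean, the sample (n-1) standard
#' deviation (0 when a species has a single record) and the number of
#' contributing records. These per-species distributions are what the
#' plasticity target augmentation draws from. Species names are matched
#' exactly after whitespace trimming and case folding.
#'
#' @param records data.frame of trait records (may mix trait_ids).
#' @return data.frame \code{species,trait_id,mean,sd,n_obs}, ordered by
#'   trait then species. The \code{species} column carries the first-seen
#'   original spelling.
#' @export
computeSpeciesStats <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(species = character(), trait_id = character(),
                      mean = numeric(), sd = numeric(), n_obs = integer()))
  validateTraitRecords(records)
  key <- paste(speciesKey(records$species), records$trait_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(groups, function(idx) {
    v <- records$value[idx]
    data.frame(species = records$species[idx[1]],
               trait_id = records$trait_id[idx[1]],
               mean = mean(v), sd = sampleSD(v), n_obs = length(v),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$trait_id, speciesKey(out$species)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
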