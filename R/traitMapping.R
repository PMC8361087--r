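#' Invert normalised predictions back to original trait units
#'
#' Reverses the min-max normalisation and the log10 transform:
#' value = 10^(norm * (max_train - min_train) + min_train).
#'
#' @param normPredictions numeric vector on the normalised scale.
#' @param p the target [NormalizationParams-class].
#' @return numeric vector of trait values in original units (positive).
#' @export
invertTargets <- function(normPredictions, p) {
  10^denormalizeValues(normPredictions, p)
}

#' Drop map points that were seen during training
#'
#' Removes points whose \code{record_id} appears among the training or
#' validation records of the trait's model, so the map is built only from
#' observations unknown to the network.
#'
#' @param points data.frame with columns \code{record_id,lat,lon,value}.
#' @param trainingIds character/integer vector of ids to exclude.
#' @return the retained points; the number dropped is reported via
#'   \code{message()}.
#' @export
deduplicateAgainstTraining <- function(points, trainingIds) {
  drop <- points$record_id %in% trainingIds
  if (any(drop))
    message(sprintf("deduplicateAgainstTraining: removed %d of %d points",
                    sum(drop), nrow(points)))
  out <- points[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Great-circle distances (km) from each of nCell centers to each point.
## Haversine on a sphere of radius 6371 km; planar distance would be wrong
## at high latitude.
distanceMatrixKm <- function(cellLon, cellLat, ptLon, ptLat) {
  p1 <- cbind(cellLon, cellLat)
  d <- matrix(0, nrow(p1), length(ptLon))
  for (j in seq_along(ptLon))
    d[, j] <- geosphere::distHaversine(p1, c(ptLon[j], ptLat[j]),
                                       r = 6371000)
  d / 1000
}

## Shared geometry/mask scaffolding for the gridded-map builders.
mapGridFrame <- function(points, resolutionDeg, bufferKm, landMask, extent) {
  assertThat(nrow(points) >= 1L, "no points to interpolate")
  assertThat(all(points$lat >= -90 & points$lat <= 90 &
                   points$lon >= -180 & points$lon <= 180),
             "point coordinates out of WGS84 bounds")
  if (is.null(extent)) extent <- c(-180, 180, -90, 90)
  xll <- extent[1]; yll <- extent[3]
  ncolG <- ceiling((extent[2] - extent[1]) / resolutionDeg)
  nrowG <- ceiling((extent[4] - extent[3]) / resolutionDeg)
  lonC <- gridLonCenters(ncolG, resolutionDeg, xll)
  latC <- gridLatCenters(nrowG, resolutionDeg, yll)
  cellLon <- matrix(lonC, nrowG, ncolG, byrow = TRUE)
  cellLat <- matrix(latC, nrowG, ncolG)
  land <- matrix(TRUE, nrowG, ncolG)
  if (!is.null(landMask)) {
    idx <- cellIndex(as.vector(cellLon), as.vector(cellLat),
                     nrow(landMask@values), ncol(landMask@values),
                     landMask@resolution, landMask@xll, landMask@yll)
    flat <- ifelse(is.na(idx[, "row"]), NA_integer_,
                   idx[, "row"] + (idx[, "col"] - 1L) * nrow(landMask@values))
    lv <- landMask@values[flat]
    land <- matrix(is.finite(lv) & lv > 0 & landMask@mask[flat], nrowG, ncolG)
  }
  list(nrowG = nrowG, ncolG = ncolG, xll = xll, yll = yll,
       cellLon = cellLon, cellLat = cellLat, land = land)
}

#' Inverse-distance-weighted interpolation of point predictions onto a grid
#'
#' Evaluates, at every grid-cell center, the IDW mean
#' \eqn{\sum_i d_i^{-power} v_i / \sum_i d_i^{-power}} over all points, with
#' great-circle (haversine) distances. A cell whose center coincides with an
#' observation (distance below \code{exactHitKm}) takes that observation's
#' value exactly (ties averaged). Cells are masked when their nearest
#' observation is farther than \code{bufferKm} (limiting extrapolation) or
#' when they fall off the land mask.
#'
#' @param points data.frame \code{record_id,lat,lon,value} (original units).
#' @param resolutionDeg cell size in degrees (default 0.5).
#' @param power IDW exponent (default 2); all points contribute (no
#'   k-nearest cutoff).
#' @param bufferKm mask radius around observations in km (default 100).
#' @param landMask optional [TraitGrid-class] land raster (> 0 / TRUE = land);
#'   NULL for no land masking.
#' @param extent c(lonMin, lonMax, latMin, latMax); defaults to the full
#'   globe.
#' @param traitId optional tag for the output grid.
#' @param exactHitKm distance below which a cell center is treated as
#'   coincident with an observation (default 1e-6 km).
#' @return a [TraitGrid-class].
#' @export
idwGrid <- function(points, resolutionDeg = 0.5, power = 2, bufferKm = 100,
                    landMask = NULL, extent = NULL, traitId = "",
                    exactHitKm = 1e-6) {
  assertThat(power > 0, "power must be positive")
  assertThat(bufferKm > 0, "bufferKm must be positive")
  fr <- mapGridFrame(points, resolutionDeg, bufferKm, landMask, extent)
  vals <- matrix(NA_real_, fr$nrowG, fr$ncolG)
  mask <- matrix(FALSE, fr$nrowG, fr$ncolG)
  active <- which(fr$land)
  chunk <- max(1L, floor(2e6 / nrow(points)))
  for (s in seq(1L, length(active), by = chunk)) {
    cells <- active[s:min(s + chunk - 1L, length(active))]
    d <- distanceMatrixKm(fr$cellLon[cells], fr$cellLat[cells],
                          points$lon, points$lat)
    nearest <- apply(d, 1, min)
    ok <- nearest <= bufferKm
    if (!any(ok)) next
    dOk <- d[ok, , drop = FALSE]
    v <- numeric(nrow(dOk))
    hit <- dOk < exactHitKm
    hasHit <- rowSums(hit) > 0
    if (any(hasHit))
      v[hasHit] <- vapply(which(hasHit), function(r)
        mean(points$value[hit[r, ]]), numeric(1))
    if (any(!hasHit)) {
      w <- dOk[!hasHit, , drop = FALSE]^(-power)
      v[!hasHit] <- as.vector(w %*% points$value) / rowSums(w)
    }
    vals[cells[ok]] <- v
    mask[cells[ok]] <- TRUE
  }
  traitGrid(vals, mask, resolutionDeg, fr$xll, fr$yll, traitId)
}

#' Per-cell quantile-range map
#'
#' For every retained cell, the difference between the .9 and .1 quantiles
#' (linear interpolation between order statistics, the default quantile
#' convention) of the contributing values: in \code{mode = "points"} these
#' are the raw point values falling inside the cell (cells without points
#' are masked); in \code{mode = "idw"} they are IDW evaluations on an
#' s x s subgrid of the cell. The buffer and land masks of [idwGrid()] apply
#' in both modes.
#'
#' @param points data.frame \code{record_id,lat,lon,value}.
#' @param resolutionDeg,bufferKm,landMask,extent,traitId,power as [idwGrid()].
#' @param qHi,qLo quantile levels (defaults .9 and .1).
#' @param mode \code{"points"} (default) or \code{"idw"}.
#' @param subgrid s for the s x s evaluation subgrid in \code{"idw"} mode
#'   (default 3).
#' @return a [TraitGrid-class] of quantile ranges (0 where a single value
#'   contributes).
#' @export
quantileRangeGrid <- function(points, resolutionDeg = 0.5, qHi = 0.9,
                              qLo = 0.1, bufferKm = 100, landMask = NULL,
                              extent = NULL, traitId = "", power = 2,
                              mode = c("points", "idw"), subgrid = 3L) {
  mode <- match.arg(mode)
  fr <- mapGridFrame(points, resolutionDeg, bufferKm, landMask, extent)
  vals <- matrix(NA_real_, fr$nrowG, fr$ncolG)
  mask <- matrix(FALSE, fr$nrowG, fr$ncolG)
  qrange <- function(v) diff(stats::quantile(v, c(qLo, qHi), names = FALSE,
                                             type = 7))
  if (mode == "points") {
    idx <- cellIndex(points$lon, points$lat, fr$nrowG, fr$ncolG,
                     resolutionDeg, fr$xll, fr$yll)
    flat <- idx[, "row"] + (idx[, "col"] - 1L) * fr$nrowG
    keep <- !is.na(flat)
    for (grp in split(which(keep), flat[keep])) {
      cell <- flat[grp[1]]
      if (!fr$land[cell]) next
      vals[cell] <- qrange(points$value[grp])
      mask[cell] <- TRUE
    }
  } else {
    base <- idwGrid(points, resolutionDeg, power, bufferKm, landMask, extent,
                    traitId)
    sub <- (seq_len(subgrid) - 0.5) / subgrid
    for (cell in which(base@mask)) {
      row <- (cell - 1L) %% fr$nrowG + 1L
      col <- (cell - 1L) %/% fr$nrowG + 1L
      lon0 <- fr$xll + (col - 1L) * resolutionDeg
      lat0 <- fr$yll + (fr$nrowG - row) * resolutionDeg
      pts <- expand.grid(lon = lon0 + sub * resolutionDeg,
                         lat = lat0 + sub * resolutionDeg)
      d <- distanceMatrixKm(pts$lon, pts$lat, points$lon, points$lat)
      w <- pmax(d, 1e-9)^(-power)
      v <- as.vector(w %*% points$value) / rowSums(w)
      vals[cell] <- qrange(v)
      mask[cell] <- TRUE
    }
  }
  traitGrid(vals, mask, resolutionDeg, fr$xll, fr$yll, traitId)
}

#' Latitudinal profile of a trait grid
#'
#' Unweighted mean of the unmasked cell values per latitude band; empty
#' bands are omitted.
#'
#' @param grid a [TraitGrid-class].
#' @param bandDeg band width in degrees (default 1).
#' @return data.frame with \code{lat_band} (band center, degrees),
#'   \code{mean_value} and \code{n_cells}, ordered south to north.
#' @export
latitudinalProfile <- function(grid, bandDeg = 1) {
  assertThat(sum(grid@mask) >= 1L, "grid has no unmasked cells")
  latC <- gridLatCenters(nrow(grid@values), grid@resolution, grid@yll)
  cellLat <- matrix(latC, nrow(grid@values), ncol(grid@values))
  band <- floor(cellLat[grid@mask] / bandDeg) * bandDeg + bandDeg / 2
  v <- grid@values[grid@mask]
  agg <- tapply(v, band, mean)
  out <- data.frame(lat_band = as.numeric(names(agg)),
                    mean_value = as.numeric(agg),
                    n_cells = as.integer(table(band)))
  out[order(out$lat_band), , drop = FALSE]
}

#' Bilinearly resample a grid onto another grid's geometry
#'
#' Evaluates grid \code{b} at the cell centers of \code{a} by bilinear
#' interpolation between the four surrounding cell centers of \code{b}
#' (nearest-cell at b's margins); cells of \code{b} that are masked
#' propagate NA.
#'
#' @param b the [TraitGrid-class] to resample.
#' @param a the [TraitGrid-class] whose geometry to match.
#' @return a [TraitGrid-class] on \code{a}'s geometry.
#' @export
resampleBilinear <- function(b, a) {
  nrA <- nrow(a@values); ncA <- ncol(a@values)
  lonA <- gridLonCenters(ncA, a@resolution, a@xll)
  latA <- gridLatCenters(nrA, a@resolution, a@yll)
  nrB <- nrow(b@values); ncB <- ncol(b@values)
  lonB <- gridLonCenters(ncB, b@resolution, b@xll)
  latB <- gridLatCenters(nrB, b@resolution, b@yll)  # decreasing in row index
  vB <- b@values
  vB[!b@mask] <- NA
  interpAxis <- function(x, centers) {
    ## centers must be increasing; returns lower index and fraction
    i <- findInterval(x, centers)
    i <- pmin(pmax(i, 1L), length(centers) - 1L)
    f <- (x - centers[i]) / (centers[i + 1] - centers[i])
    list(i = i, f = pmin(pmax(f, 0), 1))
  }
  ax <- interpAxis(lonA, lonB)
  latBinc <- rev(latB)                       # south-to-north
  ay <- interpAxis(latA, latBinc)
  rowOf <- function(iInc) nrB - iInc + 1L    # back to north-first rows
  out <- matrix(NA_real_, nrA, ncA)
  for (rr in seq_len(nrA)) {
    i <- ay$i[rr]; fy <- ay$f[rr]
    rLo <- rowOf(i); rHi <- rowOf(i + 1L)
    v00 <- vB[rLo, ax$i]; v01 <- vB[rLo, ax$i + 1L]
    v10 <- vB[rHi, ax$i]; v11 <- vB[rHi, ax$i + 1L]
    out[rr, ] <- (1 - fy) * ((1 - ax$f) * v00 + ax$f * v01) +
      fy * ((1 - ax$f) * v10 + ax$f * v11)
  }
  traitGrid(out, is.finite(out), a@resolution, a@xll, a@yll, b@traitId)
}

#' Pearson comparison of two trait grids
#'
#' Resamples \code{b} bilinearly onto \code{a}'s geometry (unless
#' \code{resample = FALSE} and the geometries already match) and computes the
#' Pearson correlation and its two-sided significance over the jointly
#' unmasked cells.
#'
#' @param a,b [TraitGrid-class] objects.
#' @param resample resample \code{b} onto \code{a} first? (default TRUE).
#' @return list with \code{pearson_r}, \code{p_value}, \code{n_cells}.
#' @export
compareGrids <- function(a, b, resample = TRUE) {
  if (resample) b <- resampleBilinear(b, a)
  assertThat(identical(dim(a@values), dim(b@values)),
             "grids must share one geometry after resampling")
  joint <- a@mask & b@mask
  assertThat(sum(joint) >= 3L,
             "need at least 3 jointly unmasked cells (have %d)", sum(joint))
  ct <- stats::cor.test(a@values[joint], b@values[joint], method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       n_cells = sum(joint))
}

#' Display transform for mapping
#'
#' Rendering helper: leaf area and seed mass span orders of magnitude, so
#' their maps are displayed on a log10 scale. Stored grid values are never
#' altered; this returns a transformed copy for plotting only.
#'
#' @param grid a [TraitGrid-class].
#' @return a [TraitGrid-class] with log10 values when the trait is LA or SM,
#'   otherwise the input unchanged.
#' @export
displayTransform <- function(grid) {
  if (!grid@traitId %in% c("LA", "SM")) return(grid)
  v <- grid@values
  v[grid@mask] <- log10(v[grid@mask])
  traitGrid(v, grid@mask, grid@resolution, grid@xll, grid@yll, grid@traitId)
}
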