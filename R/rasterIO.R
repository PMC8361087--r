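## Plain-text georeferenced raster I/O (ESRI ASCII grid, .asc) and grid
## geometry helpers shared by ClimateStack and TraitGrid. Cell-edge
## registration in WGS84 throughout: (xll, yll) is the outer corner of the
## south-west cell, row 1 of a value matrix is the northernmost row.

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (\code{ncols}, \code{nrows},
#' \code{xllcorner}, \code{yllcorner}, \code{cellsize}, \code{NODATA_value})
#' followed by the value matrix, north row first. No-data cells become NA.
#'
#' @param path path to a \code{.asc} file.
#' @return list with \code{values} (numeric matrix), \code{resolution},
#'   \code{xll}, \code{yll}.
#' @export
readAsciiGrid <- function(path) {
  assertThat(file.exists(path), "raster file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    assertThat(!is.null(hdr[[k]]), "%s: missing '%s' in ASCII grid header",
               path, k)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  assertThat(length(vals) == hdr$ncols * hdr$nrows,
             "%s: expected %d values, found %d", path,
             hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  list(values = m, resolution = hdr$cellsize,
       xll = hdr$xllcorner, yll = hdr$yllcorner)
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix, north row first; NA written as the no-data
#'   value.
#' @param path output path.
#' @param resolution cell size in degrees.
#' @param xll,yll lower-left corner (cell edges).
#' @param nodata number encoding no-data (default -9999).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(values, path, resolution, xll, yll,
                           nodata = -9999) {
  m <- values
  m[!is.finite(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", format(xll, digits = 15)),
               paste("yllcorner", format(yll, digits = 15)),
               paste("cellsize", format(resolution, digits = 15)),
               paste("NODATA_value", nodata)), con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## Row/column of the cell containing (lon, lat); NA outside the grid.
## Points on an interior cell edge belong to the cell north/east of the edge
## except at the outermost edges, which are inclusive.
cellIndex <- function(lon, lat, nrowG, ncolG, resolution, xll, yll) {
  col <- floor((lon - xll) / resolution) + 1
  rowFromS <- floor((lat - yll) / resolution) + 1
  col[lon == xll + ncolG * resolution] <- ncolG
  rowFromS[lat == yll + nrowG * resolution] <- nrowG
  row <- nrowG - rowFromS + 1
  bad <- col < 1 | col > ncolG | row < 1 | row > nrowG |
    !is.finite(lon) | !is.finite(lat)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

## Longitude of column centers / latitude of row centers (row 1 = north).
gridLonCenters <- function(ncolG, resolution, xll)
  xll + (seq_len(ncolG) - 0.5) * resolution
gridLatCenters <- function(nrowG, resolution, yll)
  yll + (rev(seq_len(nrowG)) - 0.5) * resolution

#' Construct a ClimateStack
#'
#' @param layers named list of numeric matrices (north row first) on a shared
#'   grid; NA marks no-data cells.
#' @param resolution,xll,yll shared grid geometry (degrees, lower-left
#'   cell-edge corner).
#' @return a [ClimateStack-class].
#' @export
climateStack <- function(layers, resolution, xll, yll) {
  new("ClimateStack", layers = layers, resolution = resolution,
      xll = xll, yll = yll)
}

#' Read a directory of climate rasters into a ClimateStack
#'
#' Expects files \code{bio1.asc}, \code{bio4.asc}, \code{bio7.asc},
#' \code{bio12.asc}, \code{bio13.asc}, \code{bio14.asc}, \code{bio15.asc}
#' on a shared WGS84 grid.
#'
#' @param dir directory containing the layer files.
#' @param layers layer names to read (default the seven bioclim layers the
#'   pipeline uses).
#' @return a [ClimateStack-class].
#' @export
readClimateStack <- function(dir, layers = BIOCLIM_LAYERS) {
  paths <- file.path(dir, paste0(layers, ".asc"))
  missing <- layers[!file.exists(paths)]
  assertThat(length(missing) == 0, "missing climate layer(s): %s in %s",
             paste(missing, collapse = ", "), dir)
  grids <- lapply(paths, readAsciiGrid)
  g1 <- grids[[1]]
  for (g in grids[-1])
    assertThat(identical(dim(g$values), dim(g1$values)) &&
                 isTRUE(all.equal(c(g$resolution, g$xll, g$yll),
                                  c(g1$resolution, g1$xll, g1$yll))),
               "climate layers in %s do not share one grid geometry", dir)
  climateStack(stats::setNames(lapply(grids, `[[`, "values"), layers),
               g1$resolution, g1$xll, g1$yll)
}

#' Construct a TraitGrid
#'
#' @param values numeric matrix, north row first.
#' @param mask logical matrix, TRUE = valid cell (default: finite values).
#' @param resolution cell size in degrees (default 0.5).
#' @param xll,yll lower-left corner in degrees (defaults -180, -90).
#' @param traitId optional trait tag.
#' @return a [TraitGrid-class].
#' @export
traitGrid <- function(values, mask = NULL, resolution = 0.5,
                      xll = -180, yll = -90, traitId = "") {
  if (is.null(mask)) mask <- is.finite(values)
  v <- values
  v[!mask] <- NA_real_
  new("TraitGrid", values = v, mask = mask, resolution = resolution,
      xll = xll, yll = yll, traitId = traitId)
}

#' Grid values / validity mask / geometry accessors
#'
#' @param x a [TraitGrid-class].
#' @return \code{gridValues}: the value matrix (NA where masked);
#'   \code{gridMask}: the logical mask; \code{gridResolution}: cell size in
#'   degrees.
#' @export
gridValues <- function(x) x@values

#' @rdname gridValues
#' @export
gridMask <- function(x) x@mask

#' @rdname gridValues
#' @export
gridResolution <- function(x) x@resolution

#' Write a TraitGrid as an ESRI ASCII grid
#'
#' Masked cells are written as the no-data value.
#'
#' @param grid a [TraitGrid-class].
#' @param path output path.
#' @param nodata no-data encoding (default -9999).
#' @return \code{path}, invisibly.
#' @export
writeTraitGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  v[!grid@mask] <- NA
  writeAsciiGrid(v, path, grid@resolution, grid@xll, grid@yll, nodata)
}

#' Read a TraitGrid from an ESRI ASCII grid
#'
#' @param path path to a \code{.asc} file.
#' @param traitId optional trait tag.
#' @return a [TraitGrid-class] with no-data cells masked.
#' @export
readTraitGrid <- function(path, traitId = "") {
  g <- readAsciiGrid(path)
  traitGrid(g$values, resolution = g$resolution, xll = g$xll, yll = g$yll,
            traitId = traitId)
}
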