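pointsDf <- function(lon, lat, value) {
  data.frame(record_id = sprintf("m%03d", seq_along(lon)),
             lon = lon, lat = lat, value = value, stringsAsFactors = FALSE)
}

test_that("target inversion reverses normalisation and log transform", {
  p <- fitNormalizer(c(1, 3))     # log10 bounds
  expect_equal(invertTargets(0, p), 10)
  expect_equal(invertTargets(1, p), 1000)
  set.seed(19)
  y <- runif(100)
  expect_equal(normalizeValues(log10(invertTargets(y, p)), p), y,
               tolerance = 1e-12)
})

test_that("training-set deduplication is a set difference", {
  pts <- pointsDf(1:10, 1:10, 1:10)
  expect_identical(deduplicateAgainstTraining(pts, character(0)), pts)
  expect_identical(nrow(suppressMessages(
    deduplicateAgainstTraining(pts, pts$record_id))), 0L)
  drop3 <- c("m002", "m005", "m009")
  out <- suppressMessages(deduplicateAgainstTraining(pts, drop3))
  expect_identical(out$record_id, setdiff(pts$record_id, drop3))
})

test_that("IDW: single point gives a constant field inside the buffer", {
  pts <- pointsDf(10, 10, 7.5)
  g <- idwGrid(pts, resolutionDeg = 0.5, bufferKm = 300,
               extent = c(5, 15, 5, 15))
  expect_gt(sum(gridMask(g)), 0)
  expect_true(all(abs(gridValues(g)[gridMask(g)] - 7.5) < 1e-12))
})

test_that("IDW: a cell center on an observation takes its value exactly", {
  # cell centers of a 1-degree grid from 0: centers at 0.5, 1.5, ...
  pts <- pointsDf(c(2.5, 4.5), c(2.5, 2.5), c(100, 200))
  g <- idwGrid(pts, resolutionDeg = 1, bufferKm = 500, extent = c(0, 6, 0, 6))
  v <- gridValues(g)
  row <- 6 - 2   # lat 2.5 -> 3rd row from south = 4th row from north of 6
  expect_identical(v[row, 3], 100)
  expect_identical(v[row, 5], 200)
  # tie: two coincident observations are averaged
  tie <- pointsDf(c(2.5, 2.5), c(2.5, 2.5), c(100, 300))
  gt <- idwGrid(tie, resolutionDeg = 1, bufferKm = 500, extent = c(0, 6, 0, 6))
  expect_identical(gridValues(gt)[row, 3], 200)
})

test_that("IDW agrees with a hand-computed two-point oracle on a 20x20 grid", {
  pts <- pointsDf(c(3.2, 16.8), c(4.1, 15.3), c(10, 50))
  g <- idwGrid(pts, resolutionDeg = 1, power = 2, bufferKm = 5000,
               extent = c(0, 20, 0, 20))
  v <- gridValues(g)
  lon <- 0.5 + 0:19
  lat <- 19.5 - 0:19     # row 1 is north
  for (rr in c(1, 7, 20)) {
    for (cc in c(1, 11, 20)) {
      d1 <- oracleHaversineKm(lon[cc], lat[rr], pts$lon[1], pts$lat[1])
      d2 <- oracleHaversineKm(lon[cc], lat[rr], pts$lon[2], pts$lat[2])
      w <- c(d1, d2)^-2
      expect_equal(v[rr, cc], sum(w * pts$value) / sum(w), tolerance = 1e-9)
    }
  }
  # convex-combination bound everywhere
  expect_true(all(v[gridMask(g)] >= 10 - 1e-12 & v[gridMask(g)] <= 50 + 1e-12))
})

test_that("IDW is invariant to point order and masks beyond the buffer", {
  set.seed(20)
  pts <- pointsDf(runif(15, 2, 8), runif(15, 2, 8), runif(15, 1, 9))
  g1 <- idwGrid(pts, resolutionDeg = 1, bufferKm = 200, extent = c(0, 10, 0, 10))
  g2 <- idwGrid(pts[sample(15), ], resolutionDeg = 1, bufferKm = 200,
                extent = c(0, 10, 0, 10))
  expect_equal(gridValues(g1), gridValues(g2), tolerance = 1e-12)
  # monotone mask in the buffer radius
  counts <- vapply(c(50, 100, 200), function(b)
    sum(gridMask(idwGrid(pts, resolutionDeg = 1, bufferKm = b,
                         extent = c(0, 10, 0, 10)))), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(idwGrid(pts[0, ]), "no points")
})

test_that("land mask removes off-land cells", {
  lm <- synthLandMask()
  pts <- pointsDf(c(5, -3), c(5, -3), c(1, 2))   # second point off-land
  g <- idwGrid(pts, resolutionDeg = 1, bufferKm = 300, landMask = lm,
               extent = c(-5, 15, -5, 15))
  latC <- rev(seq(-5 + 0.5, 15 - 0.5, by = 1))
  lonC <- seq(-5 + 0.5, 15 - 0.5, by = 1)
  m <- gridMask(g)
  offLand <- outer(latC < 0, lonC > 0, "|") & outer(latC > 0, lonC < 0, "|")
  for (rr in seq_along(latC)) for (cc in seq_along(lonC))
    if (latC[rr] < 0 || lonC[cc] < 0) expect_false(m[rr, cc])
})

test_that("quantile-range maps follow the declared quantile convention", {
  same <- pointsDf(rep(4.5, 6), rep(4.5, 6), rep(3.3, 6))
  g <- quantileRangeGrid(same, resolutionDeg = 1, bufferKm = 500,
                         extent = c(0, 10, 0, 10))
  expect_equal(gridValues(g)[gridMask(g)], 0)
  single <- pointsDf(4.5, 4.5, 8)
  g1 <- quantileRangeGrid(single, resolutionDeg = 1, bufferKm = 500,
                          extent = c(0, 10, 0, 10))
  expect_equal(gridValues(g1)[gridMask(g1)], 0)
  set.seed(22)
  vals <- rnorm(10, 5, 2)
  ten <- pointsDf(runif(10, 4.2, 4.8), runif(10, 4.2, 4.8), vals)
  g10 <- quantileRangeGrid(ten, resolutionDeg = 1, bufferKm = 500,
                           extent = c(0, 10, 0, 10))
  oracle <- quantile(vals, 0.9, type = 7) - quantile(vals, 0.1, type = 7)
  expect_equal(gridValues(g10)[gridMask(g10)], unname(oracle),
               tolerance = 1e-12)
  # idw mode produces a masked grid too
  gI <- quantileRangeGrid(ten, resolutionDeg = 2, bufferKm = 500,
                          extent = c(0, 10, 0, 10), mode = "idw")
  expect_true(all(gridValues(gI)[gridMask(gI)] >= 0))
})

test_that("latitudinal profiles reduce to band means", {
  vals <- matrix(1.5, 4, 8)
  g <- traitGrid(vals, resolution = 1, xll = 0, yll = 0)
  prof <- latitudinalProfile(g, bandDeg = 1)
  expect_equal(prof$mean_value, rep(1.5, 4))
  # field equal to the latitude band center recovers itself
  latC <- rev(1:4 - 0.5)
  g2 <- traitGrid(matrix(latC, 4, 8), resolution = 1, xll = 0, yll = 0)
  p2 <- latitudinalProfile(g2, bandDeg = 1)
  expect_equal(p2$mean_value, p2$lat_band)
  set.seed(23)
  vr <- matrix(rnorm(32), 4, 8)
  mask <- matrix(runif(32) > 0.3, 4, 8)
  g3 <- traitGrid(vr, mask, resolution = 1, xll = 0, yll = 0)
  p3 <- latitudinalProfile(g3, bandDeg = 1)
  for (k in seq_len(nrow(p3))) {
    rr <- which(latC == p3$lat_band[k])
    expect_equal(p3$mean_value[k], mean(vr[rr, mask[rr, ]]))
  }
})

test_that("grid comparison yields exact correlations and joint masking", {
  set.seed(24)
  v <- matrix(rnorm(100), 10, 10)
  a <- traitGrid(v, resolution = 1, xll = 0, yll = 0)
  self <- compareGrids(a, a, resample = FALSE)
  expect_equal(self$pearson_r, 1)
  neg <- compareGrids(a, traitGrid(-v, resolution = 1, xll = 0, yll = 0),
                      resample = FALSE)
  expect_equal(neg$pearson_r, -1)
  mask2 <- matrix(runif(100) > 0.4, 10, 10)
  b <- traitGrid(v + rnorm(100, 0, 0.5), mask2, resolution = 1, xll = 0, yll = 0)
  cmp <- compareGrids(a, b, resample = FALSE)
  joint <- gridMask(a) & mask2
  expect_equal(cmp$pearson_r,
               unname(cor(gridValues(a)[joint], gridValues(b)[joint])),
               tolerance = 1e-12)
  expect_identical(cmp$n_cells, sum(joint))
})

test_that("bilinear resampling is exact on matching geometry and linear fields", {
  lin <- outer(10:1, 1:12, function(r, c) 2 * r + 3 * c)
  b <- traitGrid(lin, resolution = 1, xll = 0, yll = 0)
  same <- resampleBilinear(b, b)
  expect_equal(gridValues(same), gridValues(b), tolerance = 1e-12)
  # coarser target grid: bilinear reproduces a linear field at interior cells
  a <- traitGrid(matrix(0, 5, 6), resolution = 2, xll = 0, yll = 0)
  res <- resampleBilinear(b, a)
  latA <- rev(seq(1, 9, by = 2))
  lonA <- seq(1, 11, by = 2)
  # lin[i, j] = 2*(11 - i) + 3*j, i.e. field(lat, lon) = 2(lat+.5) + 3(lon+.5)
  for (rr in 2:4) for (cc in 2:5)
    expect_equal(gridValues(res)[rr, cc],
                 2 * (latA[rr] + 0.5) + 3 * (lonA[cc] + 0.5),
                 tolerance = 1e-9)
})

test_that("display transform logs LA/SM for rendering only", {
  v <- matrix(c(10, 100, 1000, 10), 2, 2)
  g <- traitGrid(v, resolution = 1, xll = 0, yll = 0, traitId = "LA")
  d <- displayTransform(g)
  expect_equal(gridValues(d), log10(v))
  expect_equal(gridValues(g), v)            # stored values untouched
  gh <- traitGrid(v, resolution = 1, xll = 0, yll = 0, traitId = "GH")
  expect_identical(gridValues(displayTransform(gh)), v)
})

test_that("trait grids round-trip through ASCII raster files", {
  set.seed(25)
  v <- matrix(rnorm(24), 4, 6)
  mask <- matrix(runif(24) > 0.25, 4, 6)
  g <- traitGrid(v, mask, resolution = 0.5, xll = -3, yll = 40, traitId = "SM")
  f <- tempfile(fileext = ".asc")
  writeTraitGrid(g, f)
  g2 <- readTraitGrid(f, traitId = "SM")
  expect_equal(gridValues(g2)[gridMask(g2)], gridValues(g)[gridMask(g)],
               tolerance = 1e-10)
  expect_identical(gridMask(g2), gridMask(g))
})
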