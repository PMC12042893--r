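# field with given cell values on an explicit grid
makeField <- function(vals3d, xEdges, yEdges, units = "degC") {
  dates <- seq(as.Date("2006-01-01"), by = "day",
               length.out = dim(vals3d)[1])
  new("DailyField", values = vals3d, dates = dates,
      xEdges = xEdges, yEdges = yEdges, units = units, crs = "EPSG:4326")
}

# one-row TractSet with an arbitrary rectangle
rectTract <- function(xmin, xmax, ymin, ymax, id = "T01") {
  tr <- tractData(toyTracts(1))
  tr$tract_id <- id
  tr$xmin <- xmin; tr$xmax <- xmax; tr$ymin <- ymin; tr$ymax <- ymax
  new("TractSet", tracts = tr, latticeDim = c(1L, 1L))
}

test_that("zonal mean over equal cells is the plain average", {
  # tract exactly covering a 2x2 block of near-equal-area cells at low lat
  vals <- array(0, dim = c(1, 2, 2))
  vals[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2)  # y fast, x slow
  fld <- makeField(vals, xEdges = c(0, 1, 2), yEdges = c(0.0, 0.001, 0.002))
  tr <- rectTract(0, 2, 0, 0.002)
  expect_equal(as.numeric(zonalMean(fld, tr)), 2.5, tolerance = 1e-6)
})

test_that("zonal mean of a single covered cell is the identity", {
  vals <- array(7.25, dim = c(3, 1, 1))
  fld <- makeField(vals, xEdges = c(-120, -119.8), yEdges = c(38, 38.2))
  tr <- rectTract(-120, -119.8, 38, 38.2)
  expect_equal(as.numeric(zonalMean(fld, tr)), rep(7.25, 3))
})

test_that("irregular overlap matches a brute-force subdivision oracle", {
  set.seed(42)
  xE <- c(-120, -119.9, -119.75, -119.6)
  yE <- c(38, 38.12, 38.2, 38.3)
  vals <- array(0, dim = c(2, 3, 3))
  vals[1, , ] <- matrix(runif(9, 0, 30), 3, 3)
  vals[2, , ] <- matrix(runif(9, 0, 30), 3, 3)
  fld <- makeField(vals, xE, yE)
  tr <- rectTract(-119.97, -119.68, 38.05, 38.27)

  # oracle: chop the tract into a fine lattice of slivers, weight each by
  # its exact spherical-rectangle area, average the covering cell's value
  nx <- 400; ny <- 400
  gx <- seq(-119.97, -119.68, length.out = nx + 1)
  gy <- seq(38.05, 38.27, length.out = ny + 1)
  sliverArea <- function(x1, x2, y1, y2)
    (x2 - x1) * (sin(y2 * pi / 180) - sin(y1 * pi / 180))
  for (day in 1:2) {
    num <- 0; den <- 0
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      cx <- (gx[i] + gx[i + 1]) / 2; cy <- (gy[j] + gy[j + 1]) / 2
      ci <- findInterval(cx, xE); cj <- findInterval(cy, yE)
      a <- sliverArea(gx[i], gx[i + 1], gy[j], gy[j + 1])
      num <- num + a * vals[day, cj, ci]
      den <- den + a
    }
    expect_equal(as.numeric(zonalMean(fld, tr))[day], num / den,
                 tolerance = 1e-3)
  }
})

test_that("equal-area rectangle weights agree with geosphere", {
  skip_if_not_installed("geosphere")
  rect <- function(x1, x2, y1, y2)
    cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2))
  a1 <- geosphere::areaPolygon(rect(-120, -119.5, 38, 38.5))
  a2 <- geosphere::areaPolygon(rect(-120, -119.5, 44, 44.5))
  mine <- hazardCoex:::.rectArea(c(-120, -120), c(-119.5, -119.5),
                                 c(38, 44), c(38.5, 44.5))
  # geosphere integrates on the WGS84 ellipsoid, ours is spherical:
  # area *ratios* agree to ~0.2%
  expect_equal(a1 / a2, mine[1] / mine[2], tolerance = 5e-3)
})

test_that("zonal mean is bounded by intersecting cell values", {
  cfg <- simConfig(seed = 8, nTractsX = 3, nTractsY = 3, years = 2006L,
                   gridCellsPerTract = 2)
  tr <- simulateTracts(cfg)
  fld <- simulateTemperature(cfg, tr)$field
  zm <- zonalMean(fld, tr)
  lo <- apply(fld@values, 1, min)
  hi <- apply(fld@values, 1, max)
  expect_true(all(t(zm) >= lo - 1e-9 & t(zm) <= hi + 1e-9))
})

test_that("a tract outside the grid is an error naming the tract", {
  vals <- array(1, dim = c(1, 1, 1))
  fld <- makeField(vals, xEdges = c(0, 1), yEdges = c(0, 1))
  tr <- rectTract(5, 6, 5, 6, id = "T99")
  expect_error(zonalMean(fld, tr), "T99")
})

test_that("point-in-tract counts match a brute-force oracle and conserve", {
  cfg <- simConfig(seed = 14, nTractsX = 4, nTractsY = 3, years = 2006L)
  tr <- simulateTracts(cfg)
  td <- tractData(tr)
  set.seed(99)
  n <- 100L
  dates <- seq(as.Date("2006-06-01"), by = "day", length.out = 5)
  # scatter widely so some points fall outside the lattice
  p <- data.frame(date = sample(dates, n, replace = TRUE),
                  lon = runif(n, min(td$xmin) - 0.1, max(td$xmax) + 0.1),
                  lat = runif(n, min(td$ymin) - 0.1, max(td$ymax) + 0.1))
  fp <- new("FirePointSet", points = p)
  counts <- pointsToCounts(fp, tr, dates)

  # oracle: O(points x tracts) loop with the same half-open rule
  oracle <- matrix(0L, nrow(td), length(dates),
                   dimnames = dimnames(counts))
  unassigned <- 0L
  for (k in seq_len(n)) {
    hit <- which(p$lon[k] >= td$xmin & p$lon[k] < td$xmax &
                   p$lat[k] >= td$ymin & p$lat[k] < td$ymax)
    if (!length(hit))
      hit <- which(p$lon[k] >= td$xmin & p$lon[k] <= td$xmax &
                     p$lat[k] >= td$ymin & p$lat[k] <= td$ymax)
    if (!length(hit)) { unassigned <- unassigned + 1L; next }
    i <- hit[which.min(td$tract_id[hit])]
    j <- match(format(p$date[k]), colnames(oracle))
    oracle[i, j] <- oracle[i, j] + 1L
  }
  un <- attr(counts, "unassigned")
  attr(counts, "unassigned") <- NULL
  expect_identical(counts, oracle)
  expect_identical(sum(un), unassigned)
  # conservation: tract counts + unassigned account for every point
  expect_identical(sum(counts) + sum(un), n)
})

test_that("a boundary point is assigned to exactly one tract", {
  cfg <- simConfig(seed = 3, nTractsX = 2, nTractsY = 2, years = 2006L)
  tr <- simulateTracts(cfg)
  td <- tractData(tr)
  sharedX <- sort(unique(td$xmin))[2]  # interior vertical edge
  dates <- as.Date("2006-07-01")
  fp <- new("FirePointSet",
            points = data.frame(date = dates, lon = sharedX, lat = 38.1))
  counts <- pointsToCounts(fp, tr, dates)
  expect_identical(sum(counts), 1L)  # counted once, not twice
  # half-open rule: the point belongs to the tract whose xmin it sits on
  owner <- rownames(counts)[which(counts[, 1] == 1L)]
  expect_identical(owner, td$tract_id[td$xmin == sharedX & td$iy == 1][1])
})

test_that("permuting tract order then sorting yields identical matrices", {
  cfg <- simConfig(seed = 8, nTractsX = 3, nTractsY = 3, years = 2006L)
  tr <- simulateTracts(cfg)
  fld <- simulateTemperature(cfg, tr)$field
  perm <- sample(nrow(tractData(tr)))
  trP <- new("TractSet", tracts = tractData(tr)[perm, ],
             latticeDim = tr@latticeDim)
  a <- zonalMean(fld, tr)
  b <- zonalMean(fld, trP)
  expect_equal(b[rownames(a), ], a)
})
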