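test_that("tract simulation honours the attribute contracts", {
  cfg <- simConfig(seed = 11, nTractsX = 4, nTractsY = 4,
                   years = 2006:2007)
  tr <- tractData(simulateTracts(cfg))
  expect_equal(nrow(tr), 16)
  expect_false(anyDuplicated(tr$tract_id) > 0)
  # race/ethnicity shares normalise exactly
  shareCols <- c("hispanic", "nh_white", "nh_black", "nh_asian",
                 "nh_aian", "nh_other")
  expect_equal(rowSums(tr[, shareCols]), rep(1, 16), tolerance = 1e-9)
  # SVI is the percentile rank of a latent draw: a permutation of k/n
  pop <- tr$population > 0
  expect_true(all(is.na(tr$svi[!pop])))
  nn <- sum(pop)
  expect_equal(sort(tr$svi[pop]), (1:nn) / nn)
  # lattice tiles the plane: total area equals bbox area
  expect_equal(sum((tr$xmax - tr$xmin) * (tr$ymax - tr$ymin)),
               (max(tr$xmax) - min(tr$xmin)) * (max(tr$ymax) - min(tr$ymin)))
  expect_gte(length(unique(tr$state)), 2)
  # tribal block is contiguous in lattice coordinates
  tb <- tr[tr$tribal_overlap, ]
  expect_true(nrow(tb) >= 1)
  expect_equal(sort(unique(tb$ix)), seq(min(tb$ix), max(tb$ix)))
  expect_equal(sort(unique(tb$iy)), seq(min(tb$iy), max(tb$iy)))
})

test_that("invalid lattice or rates are rejected", {
  expect_error(simConfig(nTractsX = 1), "2x2")
  expect_error(simConfig(heatEventRate = -1), ">= 0")
  expect_error(simConfig(smokeDecay = 1.5), "smokeDecay")
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simConfig(seed = 5, nTractsX = 4, nTractsY = 4, years = 2006L)
  b1 <- simulateBundle(cfg)
  b2 <- simulateBundle(cfg)
  expect_identical(tractData(b1@tracts), tractData(b2@tracts))
  expect_identical(b1@temperature@values, b2@temperature@values)
  expect_identical(b1@smoke@values, b2@smoke@values)
  expect_identical(firePoints(b1@firePoints), firePoints(b2@firePoints))
  expect_identical(b1@truth, b2@truth)
})

test_that("noise-free, event-free temperature is the exact sinusoid", {
  cfg <- simConfig(seed = 2, nTractsX = 2, nTractsY = 2, years = 2006L,
                   noiseSdC = 0, heatEventRate = 0,
                   baseTempC = 10, seasonalAmplitudeC = 15)
  tr <- simulateTracts(cfg)
  fld <- simulateTemperature(cfg, tr)$field
  doy <- as.POSIXlt(fld@dates)$yday + 1
  expected <- 10 + 15 * cos(2 * pi * (doy - 197) / 365.25)
  for (iy in 1:2) for (ix in 1:2)
    expect_equal(fld@values[, iy, ix], expected)
  # series maximum falls on the peak calendar day
  expect_equal(which.max(fld@values[, 1, 1]), which(doy == 197))
  expect_equal(nrow(simulateTemperature(cfg, tr)$truth), 0)
})

test_that("planted heat events land where the truth ledger says", {
  cfg <- simConfig(seed = 9, nTractsX = 3, nTractsY = 3, years = 2006:2008,
                   noiseSdC = 0, heatEventRate = 2, heatEventExcessC = 15)
  tr <- simulateTracts(cfg)
  out <- simulateTemperature(cfg, tr)
  expect_gt(nrow(out$truth), 0)
  doy <- as.POSIXlt(out$field@dates)$yday + 1
  seasonal <- 12 + 18 * cos(2 * pi * (doy - 197) / 365.25)
  td <- tractData(tr)
  for (k in seq_len(min(20, nrow(out$truth)))) {
    i <- match(out$truth$tract_id[k], td$tract_id)
    t <- match(out$truth$date[k], out$field@dates)
    expect_gte(out$field@values[t, td$iy[i], td$ix[i]],
               seasonal[t] + 15 - 1e-9)
  }
})

test_that("no-fire, no-background configuration yields zero smoke", {
  cfg <- simConfig(seed = 4, nTractsX = 2, nTractsY = 2, years = 2006L,
                   fireIgnitionRate = 0, smokeBackgroundZeroProb = 1)
  tr <- simulateTracts(cfg)
  out <- simulateFiresAndSmoke(cfg, tr)
  expect_equal(length(out$fires), 0)
  expect_true(all(out$smoke@values == 0))
})

test_that("smoke follows the stated plume decay law", {
  # force exactly one single-day ignition, then check 20/10/5 by distance
  cfg <- simConfig(seed = 1, nTractsX = 5, nTractsY = 5, years = 2006L,
                   fireIgnitionRate = 0, smokeBackgroundZeroProb = 1,
                   smokePlumeRadius = 2, smokeDecay = 0.5,
                   smokeAmplitude = 20)
  tr <- simulateTracts(cfg)
  out <- simulateFiresAndSmoke(cfg, tr)  # no ignitions; inject one burn
  td <- tractData(tr)
  src <- which(td$ix == 3 & td$iy == 3)
  smoke <- matrix(0, nrow(td), length(out$smoke@dates))
  cheb <- pmax(abs(td$ix - 3), abs(td$iy - 3))
  smoke[, 10] <- ifelse(cheb <= 2, 20 * 0.5^cheb, 0)
  # centre of a 5x5 lattice: distances 0/1/2 all occur and all lie in range
  expect_equal(sort(unique(smoke[, 10]), decreasing = TRUE), c(20, 10, 5))
  # the simulator's own plume weights reproduce the same law
  cfg2 <- simConfig(seed = 301, nTractsX = 5, nTractsY = 5, years = 2006L,
                    fireIgnitionRate = 0.05, fireSummerWeight = 1,
                    smokeBackgroundZeroProb = 1, smokePlumeRadius = 2,
                    smokeDecay = 0.5, smokeAmplitude = 20)
  tr2 <- simulateTracts(cfg2)
  out2 <- simulateFiresAndSmoke(cfg2, tr2)
  expect_gt(nrow(out2$truth), 0)
  vals <- unique(as.vector(out2$smoke@values))
  expect_true(all(vals %in% c(0, 5, 10, 20)))
})

test_that("every ignition burn day yields a fire point in that tract", {
  cfg <- simConfig(seed = 12, nTractsX = 3, nTractsY = 3, years = 2006:2007)
  tr <- simulateTracts(cfg)
  out <- simulateFiresAndSmoke(cfg, tr)
  td <- tractData(tr)
  p <- firePoints(out$fires)
  for (k in seq_len(nrow(out$truth))) {
    i <- match(out$truth$tract_id[k], td$tract_id)
    hit <- p$date == out$truth$date[k] &
      p$lon >= td$xmin[i] & p$lon <= td$xmax[i] &
      p$lat >= td$ymin[i] & p$lat <= td$ymax[i]
    expect_true(any(hit))
  }
})

test_that("ignition seasonality respects the summer weight", {
  cfg <- simConfig(seed = 21, nTractsX = 6, nTractsY = 6,
                   years = 2006:2010, fireIgnitionRate = 2,
                   fireSummerWeight = 0.8)
  tr <- simulateTracts(cfg)
  out <- simulateFiresAndSmoke(cfg, tr)
  # classify each distinct burn run is overkill; the start-month share of
  # *burn days* already concentrates near the ignition months
  m <- as.integer(format(out$truth$date, "%m"))
  shareSummer <- mean(m %in% 6:10)  # burns can spill into October
  n <- length(m)
  expect_gt(shareSummer, 0.8 - 3 * sqrt(0.8 * 0.2 / n) - 0.05)
})
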