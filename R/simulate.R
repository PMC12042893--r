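#' @include AllClasses.R HazardExperiment.R
NULL

# Daily date axis for a contiguous span of calendar years (leap days kept).
.studyDates <- function(years) {
  years <- sort(unique(as.integer(years)))
  if (!all(diff(years) == 1L) && length(years) > 1L)
    stop("study years must be contiguous")
  seq(as.Date(sprintf("%d-01-01", min(years))),
      as.Date(sprintf("%d-12-31", max(years))), by = "day")
}

# Lattice layout shared by the simulators: tract (ix, iy) spans
# origin + (ix-1..ix)*size lon by origin + (iy-1..iy)*size lat.
.LATTICE_ORIGIN <- c(lon = -120, lat = 38)
.LATTICE_SIZE <- 0.2  # degrees per tract side

.latticeIndex <- function(config) {
  nx <- config@nTractsX
  ny <- config@nTractsY
  data.frame(ix = rep(seq_len(nx), each = ny), iy = rep(seq_len(ny), nx))
}

#' Simulate a tract lattice with sociodemographic attributes
#'
#' Generates an \code{nTractsX} by \code{nTractsY} lattice of square
#' tracts tiling a plane region, each with: population drawn around
#' \code{populationMean} (a configurable fraction exactly zero, mirroring
#' uninhabited tracts), race/ethnicity shares from a Dirichlet draw
#' centred on a Western-US-like mix, social vulnerability as the
#' percentile rank of a latent vulnerability score (missing for
#' zero-population tracts, which are excluded from the ranking), percent
#' aged 65+/with disabilities/below 150\% of poverty, a contiguous
#' tribal-land block in the northeast corner of the lattice, a coastal
#' flag on the westernmost column, and state labels splitting the lattice
#' into two or three pseudo-states by longitude.
#'
#' @param config a [SimConfig-class].
#' @return A [TractSet-class].
#' @examples
#' tr <- simulateTracts(simConfig(seed = 1, nTractsX = 4, nTractsY = 4))
#' @export
simulateTracts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nx <- config@nTractsX
  ny <- config@nTractsY
  n <- nx * ny
  idx <- .latticeIndex(config)

  xmin <- .LATTICE_ORIGIN["lon"] + (idx$ix - 1) * .LATTICE_SIZE
  ymin <- .LATTICE_ORIGIN["lat"] + (idx$iy - 1) * .LATTICE_SIZE

  population <- round(pmax(0, rnorm(n, config@populationMean,
                                    config@populationMean / 4)))
  population[runif(n) < config@zeroPopFraction] <- 0

  # Dirichlet via gamma draws; concentration keeps tract-to-tract spread
  # realistic without degenerate shares.
  w <- c(hispanic = 0.30, nh_white = 0.50, nh_black = 0.04,
         nh_asian = 0.08, nh_aian = 0.02, nh_other = 0.06)
  g <- matrix(rgamma(n * length(w), shape = rep(w * 30, each = n)),
              nrow = n)
  shares <- g / rowSums(g)
  colnames(shares) <- names(w)

  pct65 <- pmin(100, pmax(0, rnorm(n, 16.8, 5)))
  pctDis <- pmin(100, pmax(0, rnorm(n, 12.7, 4)))
  pctPov <- pmin(100, pmax(0, rnorm(n, 19.4, 8)))

  # SVI percentile rank of a latent vulnerability score; uninhabited
  # tracts sit outside the ranking and carry a missing rank.
  latent <- pctPov + pctDis + rnorm(n, 0, 5)
  svi <- rep(NA_real_, n)
  pop <- population > 0
  svi[pop] <- rank(latent[pop], ties.method = "first") / sum(pop)

  # state = contiguous column bands; county = pairs of columns in-state.
  nStates <- if (nx >= 6) 3L else 2L
  stateBand <- cut(idx$ix, breaks = nStates, labels = FALSE)
  state <- sprintf("S%02d", stateBand)
  county <- sprintf("%s-C%02d", state, (idx$ix - 1) %/% 2 + 1)

  blockX <- ceiling(nx / 4)
  blockY <- ceiling(ny / 4)
  tribal <- idx$ix > nx - blockX & idx$iy > ny - blockY
  coastal <- idx$ix == 1L

  tr <- data.frame(
    tract_id = sprintf("%02d%03d%06d", stateBand, (idx$ix - 1) %/% 2 + 1,
                       seq_len(n)),
    state = state, county = county,
    xmin = xmin, xmax = xmin + .LATTICE_SIZE,
    ymin = ymin, ymax = ymin + .LATTICE_SIZE,
    ix = idx$ix, iy = idx$iy,
    population = population,
    shares,
    svi = svi,
    pct_65plus = pct65, pct_disability = pctDis, pct_poverty150 = pctPov,
    tribal_overlap = tribal, coastal = coastal,
    stringsAsFactors = FALSE)
  new("TractSet", tracts = tr, latticeDim = c(nx, ny))
}

# Seasonal daily-maximum curve: sinusoid peaking mid-July (day-of-year 197).
.seasonalTmax <- function(config, dates) {
  doy <- as.POSIXlt(dates)$yday + 1
  config@baseTempC +
    config@seasonalAmplitudeC * cos(2 * pi * (doy - 197) / 365.25)
}

# Grid-cell edges for the field shared by temperature and smoke.
.gridEdges <- function(config) {
  g <- config@gridCellsPerTract
  list(x = .LATTICE_ORIGIN["lon"] +
         (0:(config@nTractsX * g)) * .LATTICE_SIZE / g,
       y = .LATTICE_ORIGIN["lat"] +
         (0:(config@nTractsY * g)) * .LATTICE_SIZE / g)
}

# Cell index ranges covered by tract (ix, iy).
.tractCells <- function(config, ix, iy) {
  g <- config@gridCellsPerTract
  list(x = ((ix - 1) * g + 1):(ix * g), y = ((iy - 1) * g + 1):(iy * g))
}

#' Simulate the daily maximum-temperature field
#'
#' Daily maximum temperature per grid cell = seasonal sinusoid (peaking
#' mid-July) + iid Gaussian noise + planted heat-event excess. Events are
#' drawn per tract-summer (June-August starts) at rate
#' \code{heatEventRate}, last 1-5 days, and add \code{heatEventExcessC}
#' to every cell of the tract. The returned truth ledger lists every
#' planted event day per tract, for recovery tests downstream.
#'
#' @param config a [SimConfig-class].
#' @param tracts the [TractSet-class] from [simulateTracts()].
#' @return list with \code{field} (a [DailyField-class], units "degC")
#'   and \code{truth} (data.frame: tract_id, date, event).
#' @export
simulateTemperature <- function(config, tracts) {
  stopifnot(is(config, "SimConfig"), is(tracts, "TractSet"))
  set.seed(config@seed + 1L)
  dates <- .studyDates(config@years)
  nT <- length(dates)
  g <- config@gridCellsPerTract
  nyC <- config@nTractsY * g
  nxC <- config@nTractsX * g

  seasonal <- .seasonalTmax(config, dates)
  vals <- array(seasonal, dim = c(nT, nyC, nxC))
  if (config@noiseSdC > 0)
    vals <- vals + array(rnorm(nT * nyC * nxC, 0, config@noiseSdC),
                         dim = c(nT, nyC, nxC))

  tr <- tractData(tracts)
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  truth <- list()
  if (config@heatEventRate > 0) {
    for (i in seq_len(nrow(tr))) {
      cells <- .tractCells(config, tr$ix[i], tr$iy[i])
      for (yr in years) {
        nEv <- rpois(1, config@heatEventRate)
        if (nEv == 0) next
        summer <- seq(as.Date(sprintf("%d-06-01", yr)),
                      as.Date(sprintf("%d-08-31", yr)), by = "day")
        for (e in seq_len(nEv)) {
          start <- sample(summer, 1)
          dur <- sample(1:5, 1)
          evDays <- seq(start, by = "day", length.out = dur)
          evDays <- evDays[evDays <= max(dates)]
          ti <- match(evDays, dates)
          vals[ti, cells$y, cells$x] <-
            vals[ti, cells$y, cells$x] + config@heatEventExcessC
          truth[[length(truth) + 1L]] <- data.frame(
            tract_id = tr$tract_id[i], date = evDays,
            event = "heat_event", stringsAsFactors = FALSE)
        }
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(tract_id = character(), date = as.Date(character()),
               event = character(), stringsAsFactors = FALSE)
  truth <- unique(truth)
  edges <- .gridEdges(config)
  field <- new("DailyField", values = vals, dates = dates,
               xEdges = as.numeric(edges$x), yEdges = as.numeric(edges$y),
               units = "degC", crs = "EPSG:4326")
  list(field = field, truth = truth)
}

#' Simulate fire ignitions, fire points, and the smoke field
#'
#' Ignitions are Poisson per tract-year at \code{fireIgnitionRate}, with a
#' fraction \code{fireSummerWeight} of ignitions starting in June through
#' September. Each ignition burns 1-7 consecutive days; every burn day
#' drops at least one fire point uniformly inside the tract. The smoke
#' surface on a burn day is \code{smokeAmplitude} at the source tract,
#' decayed by \code{smokeDecay} per tract of Chebyshev (lattice) distance
#' out to \code{smokePlumeRadius} tracts; overlapping plumes combine by
#' maximum. A zero-inflated exponential background (zero with probability
#' \code{smokeBackgroundZeroProb}) underlies the plumes; tract smoke is
#' the maximum of plume and background, and the gridded field broadcasts
#' the tract value to its cells, so smoke is constant within a tract.
#'
#' @param config a [SimConfig-class].
#' @param tracts the [TractSet-class] from [simulateTracts()].
#' @return list with \code{fires} (a [FirePointSet-class]), \code{smoke}
#'   (a [DailyField-class], units "ug m-3"), and \code{truth} (data.frame:
#'   tract_id, date, event = "ignition_burn", one row per burn tract-day).
#' @export
simulateFiresAndSmoke <- function(config, tracts) {
  stopifnot(is(config, "SimConfig"), is(tracts, "TractSet"))
  set.seed(config@seed + 2L)
  dates <- .studyDates(config@years)
  nT <- length(dates)
  tr <- tractData(tracts)
  n <- nrow(tr)
  years <- sort(unique(as.integer(format(dates, "%Y"))))

  pts <- list()
  burns <- list()  # (tractRow, dayIndex)
  for (i in seq_len(n)) {
    for (yr in years) {
      nIgn <- rpois(1, config@fireIgnitionRate)
      if (nIgn == 0) next
      for (k in seq_len(nIgn)) {
        month <- if (runif(1) < config@fireSummerWeight)
          sample(6:9, 1) else sample(c(1:5, 10:12), 1)
        first <- as.Date(sprintf("%d-%02d-01", yr, month))
        ndays <- as.integer(format(seq(first, by = "month",
                                       length.out = 2)[2] - 1, "%d"))
        start <- first + sample.int(ndays, 1) - 1L
        dur <- sample(1:7, 1)
        bDays <- seq(start, by = "day", length.out = dur)
        bDays <- bDays[bDays <= max(dates)]
        for (d in bDays) {
          nPts <- 1L + rpois(1, 0.5)
          pts[[length(pts) + 1L]] <- data.frame(
            date = rep(as.Date(d, origin = "1970-01-01"), nPts),
            lon = runif(nPts, tr$xmin[i], tr$xmax[i]),
            lat = runif(nPts, tr$ymin[i], tr$ymax[i]))
          burns[[length(burns) + 1L]] <-
            c(i, match(as.Date(d, origin = "1970-01-01"), dates))
        }
      }
    }
  }
  pts <- if (length(pts)) do.call(rbind, pts) else
    data.frame(date = as.Date(character()), lon = numeric(),
               lat = numeric())

  # Tract-level smoke: zero-inflated background, overridden by plumes.
  bg <- matrix(rexp(n * nT, rate = 0.5), nrow = n)
  bg[matrix(runif(n * nT), nrow = n) < config@smokeBackgroundZeroProb] <- 0
  smokeTract <- bg
  radius <- floor(config@smokePlumeRadius)
  cheb <- pmax(abs(outer(tr$ix, tr$ix, "-")), abs(outer(tr$iy, tr$iy, "-")))
  plumeWt <- ifelse(cheb <= radius, config@smokeDecay^cheb, 0)
  for (b in burns) {
    contrib <- config@smokeAmplitude * plumeWt[, b[1]]
    smokeTract[, b[2]] <- pmax(smokeTract[, b[2]], contrib)
  }

  g <- config@gridCellsPerTract
  nyC <- config@nTractsY * g
  nxC <- config@nTractsX * g
  vals <- array(0, dim = c(nT, nyC, nxC))
  for (i in seq_len(n)) {
    cells <- .tractCells(config, tr$ix[i], tr$iy[i])
    vals[, cells$y, cells$x] <- smokeTract[i, ]
  }

  truth <- if (length(burns)) {
    b <- do.call(rbind, burns)
    unique(data.frame(tract_id = tr$tract_id[b[, 1]], date = dates[b[, 2]],
                      event = "ignition_burn", stringsAsFactors = FALSE))
  } else data.frame(tract_id = character(), date = as.Date(character()),
                    event = character(), stringsAsFactors = FALSE)

  edges <- .gridEdges(config)
  smoke <- new("DailyField", values = vals, dates = dates,
               xEdges = as.numeric(edges$x), yEdges = as.numeric(edges$y),
               units = "ug m-3", crs = "EPSG:4326")
  list(fires = new("FirePointSet", points = pts), smoke = smoke,
       truth = truth)
}

#' Synthetic study bundle
#'
#' All inputs of one synthetic study region, sharing a date axis and
#' spatial domain, plus the planted-event truth ledger used by recovery
#' tests.
#'
#' @slot config the generating [SimConfig-class].
#' @slot tracts [TractSet-class].
#' @slot temperature [DailyField-class] (degC).
#' @slot firePoints [FirePointSet-class].
#' @slot smoke [DailyField-class] (ug m-3).
#' @slot truth data.frame (tract_id, date, event) listing every planted
#'   heat-event day and ignition burn day.
#' @export
setClass("SyntheticBundle", representation(
  config = "SimConfig", tracts = "TractSet", temperature = "DailyField",
  firePoints = "FirePointSet", smoke = "DailyField", truth = "data.frame"))

setMethod("show", "SyntheticBundle", function(object) {
  cat("SyntheticBundle\n")
  show(object@tracts)
  show(object@temperature)
  show(object@smoke)
  show(object@firePoints)
  cat(sprintf("  truth ledger: %d planted heat-event days, %d burn days\n",
              sum(object@truth$event == "heat_event"),
              sum(object@truth$event == "ignition_burn")))
})

#' Generate the full synthetic bundle
#'
#' Runs the component simulators in the fixed order tracts, temperature,
#' fires-and-smoke, each seeded deterministically from the configuration
#' seed, so an identical configuration yields a bit-identical bundle.
#'
#' @param config a [SimConfig-class].
#' @return A [SyntheticBundle-class].
#' @examples
#' bundle <- simulateBundle(simConfig(seed = 7, years = 2006:2007))
#' @export
simulateBundle <- function(config) {
  tracts <- simulateTracts(config)
  temp <- simulateTemperature(config, tracts)
  fs <- simulateFiresAndSmoke(config, tracts)
  truth <- rbind(temp$truth, fs$truth)
  new("SyntheticBundle", config = config, tracts = tracts,
      temperature = temp$field, firePoints = fs$fires, smoke = fs$smoke,
      truth = truth)
}
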