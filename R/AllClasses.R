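#' @import methods
#' @importFrom stats quantile rnorm rpois runif rgamma rexp pnorm sd
#' @importFrom utils read.csv write.csv head
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic study region and its daily hazard inputs.
#' Tracts form an \code{nTractsX} by \code{nTractsY} lattice of equal
#' lon/lat squares; every tract is subdivided into
#' \code{gridCellsPerTract} by \code{gridCellsPerTract} grid cells for the
#' gridded temperature and smoke surfaces.
#'
#' Daily maximum temperature is a seasonal sinusoid (mean \code{baseTempC},
#' amplitude \code{seasonalAmplitudeC}, peaking mid-July) plus Gaussian
#' noise (\code{noiseSdC}) plus planted heat-event excess
#' (\code{heatEventExcessC} for events drawn per tract-summer at rate
#' \code{heatEventRate}, each lasting 1-5 days). Fire ignitions are drawn
#' per tract-year at rate \code{fireIgnitionRate} with a fraction
#' \code{fireSummerWeight} of ignitions in June-September; each burns 1-7
#' consecutive days and drops at least one fire point per burn day. Smoke
#' on burn days decays multiplicatively (\code{smokeDecay} per tract of
#' Chebyshev distance) from \code{smokeAmplitude} at the source out to
#' \code{smokePlumeRadius} tracts, over a zero-inflated exponential
#' background (zero with probability \code{smokeBackgroundZeroProb}).
#'
#' @slot seed integer seed; identical configurations with identical seeds
#'   yield bit-identical synthetic bundles.
#' @slot nTractsX,nTractsY lattice dimensions (each >= 2).
#' @slot years integer calendar years covered (length >= 1).
#' @slot gridCellsPerTract grid cells per tract side (>= 1).
#' @slot baseTempC,seasonalAmplitudeC,noiseSdC temperature model, degrees C.
#' @slot heatEventRate expected planted heat events per tract-summer.
#' @slot heatEventExcessC excess added on planted event days, degrees C.
#' @slot fireIgnitionRate expected ignitions per tract-year.
#' @slot fireSummerWeight fraction of ignitions in Jun-Sep, in [0,1].
#' @slot smokePlumeRadius plume reach in tracts (Chebyshev distance).
#' @slot smokeDecay per-tract multiplicative decay, in (0,1).
#' @slot smokeAmplitude smoke at the source tract on burn days, ug/m3.
#' @slot smokeBackgroundZeroProb probability a tract-day has zero
#'   background smoke.
#' @slot populationMean mean tract population, persons.
#' @slot zeroPopFraction fraction of tracts with exactly zero population
#'   (these get a missing social vulnerability rank).
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nTractsX = "integer", nTractsY = "integer",
  years = "integer",
  gridCellsPerTract = "integer",
  baseTempC = "numeric", seasonalAmplitudeC = "numeric", noiseSdC = "numeric",
  heatEventRate = "numeric", heatEventExcessC = "numeric",
  fireIgnitionRate = "numeric", fireSummerWeight = "numeric",
  smokePlumeRadius = "numeric", smokeDecay = "numeric",
  smokeAmplitude = "numeric", smokeBackgroundZeroProb = "numeric",
  populationMean = "numeric", zeroPopFraction = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nTractsX < 2L || object@nTractsY < 2L)
    msg <- c(msg, "tract lattice must be at least 2x2")
  if (length(object@years) < 1L)
    msg <- c(msg, "need at least one study year")
  if (object@gridCellsPerTract < 1L)
    msg <- c(msg, "gridCellsPerTract must be >= 1")
  for (fld in c("heatEventRate", "fireIgnitionRate", "populationMean",
                "noiseSdC", "heatEventExcessC", "smokeAmplitude"))
    if (slot(object, fld) < 0)
      msg <- c(msg, sprintf("%s must be >= 0", fld))
  for (fld in c("fireSummerWeight", "smokeBackgroundZeroProb",
                "zeroPopFraction"))
    if (slot(object, fld) < 0 || slot(object, fld) > 1)
      msg <- c(msg, sprintf("%s must be in [0,1]", fld))
  if (object@smokeDecay <= 0 || object@smokeDecay >= 1)
    msg <- c(msg, "smokeDecay must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults describe a small Western-US-like study region: a 6x6 tract
#' lattice observed over 15 years, tracts of roughly 4000 people, a
#' temperate seasonal cycle whose summer peak sits near the 32.22 C
#' extreme-heat absolute threshold, about one planted heat event per
#' tract-summer, sparse fire ignitions concentrated (80\%) in June through
#' September, and smoke plumes that halve per tract of distance out to two
#' tracts from the source.
#'
#' @param seed integer RNG seed.
#' @param nTractsX,nTractsY lattice dimensions.
#' @param years calendar years (default a 15-year window, 2006-2020).
#' @param gridCellsPerTract grid cells per tract side.
#' @param baseTempC,seasonalAmplitudeC,noiseSdC temperature model (C).
#' @param heatEventRate,heatEventExcessC planted heat events.
#' @param fireIgnitionRate,fireSummerWeight fire ignition process.
#' @param smokePlumeRadius,smokeDecay,smokeAmplitude,smokeBackgroundZeroProb
#'   smoke model.
#' @param populationMean,zeroPopFraction tract populations; the default
#'   zero-population fraction mirrors the 62-in-18,106 rate of uninhabited
#'   tracts typical of a Western US tract inventory.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nTractsX = 4, nTractsY = 4, years = 2006:2007)
#' @export
simConfig <- function(seed = 1L,
                      nTractsX = 6L, nTractsY = 6L,
                      years = 2006:2020,
                      gridCellsPerTract = 1L,
                      baseTempC = 12, seasonalAmplitudeC = 18,
                      noiseSdC = 3,
                      heatEventRate = 1, heatEventExcessC = 6,
                      fireIgnitionRate = 0.8, fireSummerWeight = 0.8,
                      smokePlumeRadius = 2, smokeDecay = 0.5,
                      smokeAmplitude = 20, smokeBackgroundZeroProb = 0.9,
                      populationMean = 4000, zeroPopFraction = 62 / 18106) {
  new("SimConfig",
      seed = as.integer(seed),
      nTractsX = as.integer(nTractsX), nTractsY = as.integer(nTractsY),
      years = as.integer(years),
      gridCellsPerTract = as.integer(gridCellsPerTract),
      baseTempC = baseTempC, seasonalAmplitudeC = seasonalAmplitudeC,
      noiseSdC = noiseSdC,
      heatEventRate = heatEventRate, heatEventExcessC = heatEventExcessC,
      fireIgnitionRate = fireIgnitionRate,
      fireSummerWeight = fireSummerWeight,
      smokePlumeRadius = smokePlumeRadius, smokeDecay = smokeDecay,
      smokeAmplitude = smokeAmplitude,
      smokeBackgroundZeroProb = smokeBackgroundZeroProb,
      populationMean = populationMean, zeroPopFraction = zeroPopFraction)
}

#' Tract table with lattice geometry and sociodemographic attributes
#'
#' One row per census tract. Geometry is axis-aligned lon/lat rectangles
#' (columns \code{xmin,xmax,ymin,ymax}), which keeps all spatial
#' aggregation exactly computable. Attribute columns follow the usual
#' tract-inventory layout: population, race/ethnicity population shares
#' (summing to 1 for populated tracts), social vulnerability index
#' percentile rank in [0,1] (missing for zero-population tracts), percent
#' aged 65+, percent with disabilities, percent below 150\% of the poverty
#' line, a tribal-land overlap flag, and a coastal flag.
#'
#' @slot tracts data.frame of tract attributes, one row per tract.
#' @slot latticeDim integer lattice dimensions (nx, ny), or c(NA, NA) for
#'   tracts read from a file without lattice provenance.
#' @export
setClass("TractSet", representation(
  tracts = "data.frame",
  latticeDim = "integer"
))

.RACE_COLS <- c("hispanic", "nh_white", "nh_black", "nh_asian",
                "nh_aian", "nh_other")

setValidity("TractSet", function(object) {
  tr <- object@tracts
  msg <- character()
  need <- c("tract_id", "state", "county", "xmin", "xmax", "ymin", "ymax",
            "population", .RACE_COLS, "svi", "pct_65plus", "pct_disability",
            "pct_poverty150", "tribal_overlap", "coastal")
  miss <- setdiff(need, names(tr))
  if (length(miss))
    return(sprintf("missing tract columns: %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(tr$tract_id))
    msg <- c(msg, "tract_id values must be unique")
  if (any(tr$population < 0))
    msg <- c(msg, "population must be >= 0")
  pop <- tr$population > 0
  if (any(pop)) {
    s <- rowSums(tr[pop, .RACE_COLS, drop = FALSE])
    if (any(abs(s - 1) > 1e-6))
      msg <- c(msg, "race/ethnicity shares must sum to 1 for populated tracts")
    if (any(is.na(tr$svi[pop])))
      msg <- c(msg, "svi must be present for populated tracts")
  }
  if (any(!is.na(tr$svi) & (tr$svi < 0 | tr$svi > 1)))
    msg <- c(msg, "svi must lie in [0,1]")
  if (any(!pop & !is.na(tr$svi)))
    msg <- c(msg, "svi must be missing for zero-population tracts")
  if (any(tr$xmax <= tr$xmin) || any(tr$ymax <= tr$ymin))
    msg <- c(msg, "degenerate tract rectangles")
  if (length(msg)) msg else TRUE
})

#' @describeIn TractSet-class number of tracts.
#' @param x,object a \code{TractSet}.
#' @export
setMethod("length", "TractSet", function(x) nrow(x@tracts))

setMethod("show", "TractSet", function(object) {
  tr <- object@tracts
  cat(sprintf("TractSet with %d tracts across %d state(s)\n",
              nrow(tr), length(unique(tr$state))))
  cat(sprintf("  population: total %.0f, %d zero-population tract(s)\n",
              sum(tr$population), sum(tr$population == 0)))
  cat(sprintf("  bbox: lon [%.3f, %.3f], lat [%.3f, %.3f]\n",
              min(tr$xmin), max(tr$xmax), min(tr$ymin), max(tr$ymax)))
})

#' @describeIn TractSet-class tract identifiers, in table order.
#' @export
tractIds <- function(x) x@tracts$tract_id

#' @describeIn TractSet-class the attribute data.frame.
#' @export
tractData <- function(x) x@tracts

#' Gridded daily surface
#'
#' A daily gridded field (maximum temperature in degrees C, or smoke PM2.5
#' in ug/m3) over an axis-aligned lon/lat grid. Cell edges are stored
#' explicitly; cell (iy, ix) spans \code{xEdges[ix]..xEdges[ix+1]} by
#' \code{yEdges[iy]..yEdges[iy+1]}.
#'
#' @slot values numeric array, time x y x x.
#' @slot dates Date vector, strictly increasing, daily with no gaps.
#' @slot xEdges,yEdges numeric grid-cell edges, strictly increasing.
#' @slot units unit string ("degC" or "ug m-3").
#' @slot crs coordinate reference, "EPSG:4326".
#' @export
setClass("DailyField", representation(
  values = "array",
  dates = "Date",
  xEdges = "numeric", yEdges = "numeric",
  units = "character", crs = "character"
))

setValidity("DailyField", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3L)
    return("values must be a 3-d array (time x y x x)")
  if (d[1] != length(object@dates))
    msg <- c(msg, "time dimension must match number of dates")
  if (d[2] != length(object@yEdges) - 1L ||
      d[3] != length(object@xEdges) - 1L)
    msg <- c(msg, "spatial dimensions must match grid edges")
  dd <- as.integer(diff(object@dates))
  if (length(dd) && any(dd != 1L))
    msg <- c(msg, "dates must be consecutive days with no gaps")
  if (anyNA(object@values))
    msg <- c(msg, "field values must be finite")
  if (identical(object@units, "ug m-3") && any(object@values < 0))
    msg <- c(msg, "smoke values must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DailyField", function(object) {
  d <- dim(object@values)
  cat(sprintf("DailyField [%s]: %d days x %d x %d cells, %s .. %s\n",
              object@units, d[1], d[2], d[3],
              format(min(object@dates)), format(max(object@dates))))
})

#' Active-fire point records
#'
#' @slot points data.frame with columns \code{date} (Date), \code{lon},
#'   \code{lat} (degrees).
#' @export
setClass("FirePointSet", representation(points = "data.frame"))

setValidity("FirePointSet", function(object) {
  p <- object@points
  if (!all(c("date", "lon", "lat") %in% names(p)))
    return("fire points need date, lon, lat columns")
  if (nrow(p) && !inherits(p$date, "Date"))
    return("date column must be Date")
  TRUE
})

setMethod("show", "FirePointSet", function(object) {
  cat(sprintf("FirePointSet with %d points", nrow(object@points)))
  if (nrow(object@points))
    cat(sprintf(" (%s .. %s)", format(min(object@points$date)),
                format(max(object@points$date))))
  cat("\n")
})

#' @describeIn FirePointSet-class number of fire points.
#' @param x,object a \code{FirePointSet}.
#' @export
setMethod("length", "FirePointSet", function(x) nrow(x@points))

#' @describeIn FirePointSet-class the point records.
#' @export
firePoints <- function(x) x@points

#' Per-tract extreme-heat thresholds
#'
#' The relative threshold is the warm-season (May-September) 95th
#' percentile of daily maximum temperature over the baseline years; the
#' absolute threshold defaults to 32.22 C (90 F). A tract-day is extreme
#' heat when its maximum temperature meets or exceeds both.
#'
#' @slot relativeC named numeric, per-tract relative threshold (C).
#' @slot absoluteC single absolute threshold (C).
#' @slot percentile percentile used for the relative threshold.
#' @slot baselineYears integer years of the baseline window.
#' @slot warmSeasonMonths integer months of the warm season.
#' @export
setClass("EHThresholds", representation(
  relativeC = "numeric", absoluteC = "numeric", percentile = "numeric",
  baselineYears = "integer", warmSeasonMonths = "integer"
))

setValidity("EHThresholds", function(object) {
  if (any(!is.finite(object@relativeC)))
    return("relative thresholds must be finite")
  if (length(object@absoluteC) != 1L)
    return("absoluteC must be a single value")
  TRUE
})

setMethod("show", "EHThresholds", function(object) {
  cat(sprintf(
    "EHThresholds: %d tracts, p%g warm-season baseline %d-%d, absolute %.2f C\n",
    length(object@relativeC), object@percentile,
    min(object@baselineYears), max(object@baselineYears), object@absoluteC))
  cat(sprintf("  relative thresholds %.2f .. %.2f C; %.1f%% below absolute\n",
              min(object@relativeC), max(object@relativeC),
              100 * mean(object@relativeC < object@absoluteC)))
})

#' @describeIn EHThresholds-class share of tracts whose relative threshold
#'   falls below the absolute threshold (the absolute gate binds there).
#' @param object an \code{EHThresholds}.
#' @export
shareBelowAbsolute <- function(object)
  mean(object@relativeC < object@absoluteC)

#' Mann-Kendall trend test result
#'
#' @slot n series length.
#' @slot S integer-valued Mann-Kendall statistic.
#' @slot varS tie-corrected variance of S.
#' @slot Z continuity-corrected normal deviate.
#' @slot p two-sided normal-approximation p-value.
#' @slot direction "increasing", "decreasing", or "none" at level alpha.
#' @slot alpha significance level used for the direction label.
#' @export
setClass("TrendResult", representation(
  n = "integer", S = "numeric", varS = "numeric", Z = "numeric",
  p = "numeric", direction = "character", alpha = "numeric"
))

setValidity("TrendResult", function(object) {
  msg <- character()
  if (abs(object@S) > object@n * (object@n - 1) / 2)
    msg <- c(msg, "|S| exceeds n(n-1)/2")
  if (object@p < 0 || object@p > 1)
    msg <- c(msg, "p must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrendResult", function(object) {
  cat(sprintf(
    "Mann-Kendall: n = %d, S = %d, var(S) = %.2f, Z = %.3f, p = %.3f (%s)\n",
    object@n, object@S, object@varS, object@Z, object@p, object@direction))
})
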