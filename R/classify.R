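#' @include AllClasses.R HazardExperiment.R
NULL

.checkTractDayMatrix <- function(m, what = "matrix") {
  if (!is.matrix(m)) stop(what, " must be a tracts x days matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must carry tract ids as rownames and dates as colnames")
  invisible(m)
}

#' Derive per-tract extreme-heat thresholds
#'
#' The relative threshold of a tract is the \code{percentile}-th
#' percentile (linear interpolation between order statistics, the
#' standard type-7 rule) of its daily maximum temperatures over all
#' warm-season days (May-September by default) of the baseline years
#' (by default the first five study years). The absolute threshold is a
#' fixed 32.22 C (90 F) unless overridden.
#'
#' @param tmax numeric tracts x days matrix of daily maximum temperature
#'   (degC), dates as colnames.
#' @param baselineYears integer years; default first 5 years present.
#' @param warmSeasonMonths integer months of the warm season (default
#'   May-September).
#' @param percentile percentile for the relative threshold (default 95).
#' @param absoluteC absolute threshold (default 32.22 C).
#' @return An [EHThresholds-class]. The share of tracts whose relative
#'   threshold undercuts the absolute one (so the absolute gate binds) is
#'   available via [shareBelowAbsolute()].
#' @export
deriveEHThresholds <- function(tmax, baselineYears = NULL,
                               warmSeasonMonths = 5:9, percentile = 95,
                               absoluteC = 32.22) {
  .checkTractDayMatrix(tmax, "tmax")
  dates <- as.Date(colnames(tmax))
  years <- as.integer(format(dates, "%Y"))
  if (is.null(baselineYears))
    baselineYears <- head(sort(unique(years)), 5L)
  baselineYears <- as.integer(baselineYears)
  if (!all(baselineYears %in% years))
    stop("baseline years outside the study window")
  sel <- years %in% baselineYears &
    as.integer(format(dates, "%m")) %in% warmSeasonMonths
  if (!any(sel)) stop("empty baseline window")
  rel <- apply(tmax[, sel, drop = FALSE], 1, quantile,
               probs = percentile / 100, type = 7, names = FALSE)
  new("EHThresholds", relativeC = stats::setNames(rel, rownames(tmax)),
      absoluteC = absoluteC, percentile = percentile,
      baselineYears = baselineYears,
      warmSeasonMonths = as.integer(warmSeasonMonths))
}

#' Classify extreme-heat tract-days
#'
#' A tract-day is extreme heat when the daily maximum temperature both
#' meets-or-exceeds the tract's relative threshold and meets-or-exceeds
#' the absolute threshold (both comparisons inclusive). Classification
#' runs over every day of every year; the threshold pair makes winter
#' flags effectively impossible without restricting the season.
#'
#' @param tmax numeric tracts x days matrix (degC).
#' @param thresholds an [EHThresholds-class] derived on the same tracts.
#' @return logical tracts x days matrix.
#' @export
classifyEH <- function(tmax, thresholds) {
  .checkTractDayMatrix(tmax, "tmax")
  stopifnot(is(thresholds, "EHThresholds"))
  if (!identical(rownames(tmax), names(thresholds@relativeC)))
    stop("thresholds were derived on a different tract set")
  tmax >= thresholds@relativeC & tmax >= thresholds@absoluteC
}

#' Classify wildfire-burn-zone tract-days
#'
#' A tract-day is a burn-zone day when at least one active-fire point
#' fell in the tract that day.
#'
#' @param fireCounts integer tracts x days matrix of fire-point counts.
#' @return logical tracts x days matrix.
#' @export
classifyWFBZ <- function(fireCounts) {
  .checkTractDayMatrix(fireCounts, "fireCounts")
  if (any(fireCounts < 0)) stop("negative fire counts")
  fireCounts >= 1
}

#' Classify wildfire-smoke tract-days
#'
#' A tract-day is a smoke day when smoke PM2.5 strictly exceeds the
#' threshold (0 ug/m3 by default; 5 ug/m3 in the sensitivity setting).
#'
#' @param smoke numeric tracts x days matrix of smoke PM2.5 (ug/m3).
#' @param thresholdUgm3 strict exceedance threshold (default 0).
#' @return logical tracts x days matrix.
#' @export
classifyWFS <- function(smoke, thresholdUgm3 = 0) {
  .checkTractDayMatrix(smoke, "smoke")
  if (any(smoke < 0)) stop("negative smoke values")
  smoke > thresholdUgm3
}

#' Classify all hazards on a HazardExperiment
#'
#' Derives extreme-heat thresholds from the \code{tmax} assay and adds
#' logical assays \code{eh}, \code{wfbz}, \code{wfs}, and
#' \code{any_hazard}; thresholds and the smoke threshold are recorded in
#' \code{metadata()}.
#'
#' @param he a [HazardExperiment-class] with assays \code{tmax},
#'   \code{fire_count}, \code{smoke}.
#' @param wfsThresholdUgm3 smoke threshold, ug/m3 (default 0).
#' @param baselineYears,warmSeasonMonths,percentile,absoluteC passed to
#'   [deriveEHThresholds()].
#' @return The experiment with flag assays added.
#' @export
classifyHazards <- function(he, wfsThresholdUgm3 = 0, baselineYears = NULL,
                            warmSeasonMonths = 5:9, percentile = 95,
                            absoluteC = 32.22) {
  stopifnot(is(he, "HazardExperiment"))
  thr <- deriveEHThresholds(assay(he, "tmax"), baselineYears,
                            warmSeasonMonths, percentile, absoluteC)
  eh <- classifyEH(assay(he, "tmax"), thr)
  wfbz <- classifyWFBZ(assay(he, "fire_count"))
  wfs <- classifyWFS(assay(he, "smoke"), wfsThresholdUgm3)
  assay(he, "eh") <- eh
  assay(he, "wfbz") <- wfbz
  assay(he, "wfs") <- wfs
  assay(he, "any_hazard") <- eh | wfbz | wfs
  metadata(he)$eh_thresholds <- thr
  metadata(he)$wfs_threshold <- wfsThresholdUgm3
  he
}
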