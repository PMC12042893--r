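#' @include AllClasses.R HazardExperiment.R classify.R
NULL

#' Exposure days per tract
#'
#' Sums a logical tract-by-day flag matrix into per-tract exposure-day
#' totals, overall and partitioned by calendar year.
#'
#' @param flags logical tracts x days matrix (dates as colnames).
#' @return list: \code{E} named per-tract totals; \code{Ey} tracts x
#'   years matrix of per-year totals (rows sum to \code{E}).
#' @export
exposureDaysPerTract <- function(flags) {
  .checkTractDayMatrix(flags, "flags")
  if (!is.logical(flags)) stop("flags must be logical")
  years <- format(as.Date(colnames(flags)), "%Y")
  yl <- sort(unique(years))
  Ey <- vapply(yl, function(y)
    rowSums(flags[, years == y, drop = FALSE]), numeric(nrow(flags)))
  Ey <- matrix(Ey, nrow = nrow(flags),
               dimnames = list(rownames(flags), yl))
  list(E = rowSums(flags), Ey = Ey)
}

#' Tract-day and person-day exposure metrics
#'
#' The seven summary metrics of tract-level exposure accounting, given
#' per-tract exposure-day totals \eqn{E_i} over the study window:
#' \describe{
#'   \item{T_year}{region tract-days per year, \eqn{\sum_i E_i / N_{years}}.}
#'   \item{T_ct_year}{days per tract per year, \eqn{T_{year} / N_{cts}}.}
#'   \item{PDE_i}{person-days per tract, \eqn{P_i E_i} (everyone in an
#'     exposed tract is assumed exposed).}
#'   \item{T_person_year}{region person-days per year.}
#'   \item{T_person_ct_year}{person-days per tract per year.}
#'   \item{T_S_year}{state tract-days per year (sums over states to
#'     T_year).}
#'   \item{T_person_S_year}{state person-days per year.}
#' }
#'
#' @param E named per-tract exposure-day totals over the whole window.
#' @param populations per-tract populations, aligned with \code{E}.
#' @param states per-tract state labels, aligned with \code{E}.
#' @param nYears number of study years (>= 1).
#' @param hazard optional label recorded in the output rows.
#' @return tidy data.frame: hazard, scope ("region", "state", "tract"),
#'   scope_id, metric, value, units.
#' @examples
#' computeMetrics(c(a = 10, b = 0), c(1000, 2000), c("S1", "S1"), 2)
#' @export
computeMetrics <- function(E, populations, states, nYears, hazard = NA) {
  if (nYears < 1) stop("nYears must be >= 1")
  if (length(populations) != length(E) || length(states) != length(E))
    stop("populations and states must align with E")
  if (anyNA(populations)) stop("missing populations")
  nCts <- length(E)
  PDE <- populations * E
  Tyear <- sum(E) / nYears
  Tperson <- sum(PDE) / nYears

  row <- function(scope, id, metric, value, units)
    data.frame(hazard = hazard, scope = scope, scope_id = id,
               metric = metric, value = value, units = units,
               stringsAsFactors = FALSE)
  out <- rbind(
    row("region", "all", "T_year", Tyear, "tract-days/yr"),
    row("region", "all", "T_ct_year", Tyear / nCts, "days/tract/yr"),
    row("region", "all", "T_person_year", Tperson, "person-days/yr"),
    row("region", "all", "T_person_ct_year", Tperson / nCts,
        "person-days/tract/yr"))
  for (s in sort(unique(states))) {
    i <- states == s
    out <- rbind(out,
      row("state", s, "T_S_year", sum(E[i]) / nYears, "tract-days/yr"),
      row("state", s, "T_person_S_year", sum(PDE[i]) / nYears,
          "person-days/yr"))
  }
  ids <- if (is.null(names(E))) as.character(seq_along(E)) else names(E)
  out <- rbind(out, row("tract", ids, "PDE_i", PDE, "person-days"))
  rownames(out) <- NULL
  out
}

#' Monthly distribution of flagged tract-days
#'
#' Percent of all flagged tract-days falling in each calendar month.
#' Percentages sum to 100 whenever any tract-day is flagged; an all-empty
#' flag matrix yields all zeros with a warning.
#'
#' @param flags logical tracts x days matrix.
#' @return named numeric of length 12 (months "01".."12").
#' @export
monthlyDistribution <- function(flags) {
  .checkTractDayMatrix(flags, "flags")
  months <- format(as.Date(colnames(flags)), "%m")
  perMonth <- vapply(sprintf("%02d", 1:12), function(m)
    sum(flags[, months == m, drop = FALSE]), 0)
  tot <- sum(perMonth)
  if (tot == 0) {
    warning("no flagged tract-days; monthly distribution is all zero")
    return(perMonth)
  }
  100 * perMonth / tot
}

#' Annual tract-day totals
#'
#' Region-wide flagged tract-days per calendar year; the input series of
#' the trend tests. Totals sum to the region's overall exposure days.
#'
#' @param flags logical tracts x days matrix.
#' @return named numeric, one entry per year.
#' @export
annualSeries <- function(flags) {
  colSums(exposureDaysPerTract(flags)$Ey)
}

#' Exposure summary for every hazard and combination
#'
#' Runs [computeMetrics()] on every flag assay of a classified (and
#' optionally coexposed) [HazardExperiment-class].
#'
#' @param he a [HazardExperiment-class].
#' @return tidy data.frame of metric rows across hazards/combinations.
#' @export
exposureSummary <- function(he) {
  stopifnot(is(he, "HazardExperiment"))
  rd <- rowData(he)
  nYears <- length(unique(colData(he)$year))
  do.call(rbind, lapply(flagNames(he), function(nm) {
    E <- exposureDaysPerTract(hazardFlags(he, nm))$E
    computeMetrics(E, rd$population, rd$state, nYears, hazard = nm)
  }))
}
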