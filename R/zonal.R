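#' @include AllClasses.R HazardExperiment.R
NULL

# Area of a lon/lat-aligned rectangle under the cylindrical equal-area
# projection (exact on the sphere, up to the constant R^2 which cancels
# in normalized weights): dLon[rad] * (sin(lat2) - sin(lat1)).
.rectArea <- function(xmin, xmax, ymin, ymax) {
  (xmax - xmin) * pi / 180 * (sin(ymax * pi / 180) - sin(ymin * pi / 180))
}

#' Area-weighted zonal mean of a gridded field over tracts
#'
#' For every tract-day, the mean of intersecting grid-cell values
#' weighted by intersection area. Areas are computed on an equal-area
#' representation (cylindrical equal-area, exact for the lon/lat-aligned
#' rectangles used throughout) and normalized per tract. The result is
#' bounded by the min and max of the intersecting cells.
#'
#' @param field a [DailyField-class].
#' @param tracts a [TractSet-class] overlapping the field.
#' @return numeric matrix, tracts x days, dimnames = tract ids x dates.
#' @examples
#' cfg <- simConfig(seed = 1, years = 2006L, nTractsX = 2, nTractsY = 2)
#' tr <- simulateTracts(cfg)
#' tm <- simulateTemperature(cfg, tr)$field
#' dim(zonalMean(tm, tr))
#' @export
zonalMean <- function(field, tracts) {
  stopifnot(is(field, "DailyField"), is(tracts, "TractSet"))
  tr <- tractData(tracts)
  xe <- field@xEdges
  ye <- field@yEdges
  ny <- length(ye) - 1L
  nx <- length(xe) - 1L
  nCell <- ny * nx
  n <- nrow(tr)

  # weight matrix W[tract, cell], cell flattened as (iy within ix)
  W <- matrix(0, nrow = n, ncol = nCell)
  cellX1 <- rep(xe[-length(xe)], each = ny)
  cellX2 <- rep(xe[-1], each = ny)
  cellY1 <- rep(ye[-length(ye)], nx)
  cellY2 <- rep(ye[-1], nx)
  for (i in seq_len(n)) {
    ox1 <- pmax(tr$xmin[i], cellX1)
    ox2 <- pmin(tr$xmax[i], cellX2)
    oy1 <- pmax(tr$ymin[i], cellY1)
    oy2 <- pmin(tr$ymax[i], cellY2)
    hit <- ox2 > ox1 & oy2 > oy1
    if (any(hit))
      W[i, hit] <- .rectArea(ox1[hit], ox2[hit], oy1[hit], oy2[hit])
  }
  tot <- rowSums(W)
  if (any(tot <= 0))
    stop("tracts with no intersecting grid cells: ",
         paste(tr$tract_id[tot <= 0], collapse = ", "))
  W <- W / tot

  nT <- dim(field@values)[1]
  V <- matrix(field@values, nrow = nT)  # day x cell, same flattening
  out <- W %*% t(V)
  dimnames(out) <- list(tr$tract_id, format(field@dates))
  out
}

#' Count fire points per tract-day
#'
#' Spatial join of fire points to tracts. Containment uses closed
#' lower/left and open upper/right edges; a point on the outermost
#' upper/right boundary of the domain falls back to closed containment;
#' any residual tie goes to the lowest tract_id. Points outside all
#' tracts are tallied in the \code{"unassigned"} attribute (per date),
#' never dropped silently, so the per-date sum of counts plus unassigned
#' equals the number of points.
#'
#' @param fires a [FirePointSet-class].
#' @param tracts a [TractSet-class].
#' @param dates Date vector covering the point dates.
#' @return integer matrix, tracts x days, with attribute
#'   \code{unassigned}: named integer vector of unassigned points per
#'   date (zero-length when all points fall inside a tract).
#' @export
pointsToCounts <- function(fires, tracts, dates) {
  stopifnot(is(fires, "FirePointSet"), is(tracts, "TractSet"))
  p <- firePoints(fires)
  tr <- tractData(tracts)
  if (nrow(p) && (min(p$date) < min(dates) || max(p$date) > max(dates)))
    stop("fire point dates outside the date axis")

  ord <- order(tr$tract_id)
  assign1 <- function(lon, lat) {
    for (i in ord) {  # ascending tract_id => first half-open hit is lowest id
      if (lon >= tr$xmin[i] && lon < tr$xmax[i] &&
          lat >= tr$ymin[i] && lat < tr$ymax[i]) return(i)
    }
    for (i in ord) {  # closed fallback for the domain's outer max edges
      if (lon >= tr$xmin[i] && lon <= tr$xmax[i] &&
          lat >= tr$ymin[i] && lat <= tr$ymax[i]) return(i)
    }
    NA_integer_
  }
  who <- if (nrow(p))
    vapply(seq_len(nrow(p)), function(k) assign1(p$lon[k], p$lat[k]), 0L)
  else integer()

  counts <- matrix(0L, nrow = nrow(tr), ncol = length(dates),
                   dimnames = list(tr$tract_id, format(dates)))
  inDom <- !is.na(who)
  if (any(inDom)) {
    tab <- table(factor(who[inDom], levels = seq_len(nrow(tr))),
                 factor(format(p$date[inDom]), levels = format(dates)))
    counts[] <- as.integer(tab)
  }
  un <- table(format(p$date[!inDom]))
  attr(counts, "unassigned") <-
    stats::setNames(as.integer(un), names(un))
  counts
}

#' Build the hazard container from raw inputs
#'
#' Aggregates the temperature and smoke fields to tract-day matrices via
#' [zonalMean()], joins fire points to tract-day counts via
#' [pointsToCounts()], and assembles a [HazardExperiment-class] with
#' assays \code{tmax}, \code{fire_count}, \code{smoke}. The count of
#' unassigned fire points is recorded in \code{metadata()}.
#'
#' @param tracts a [TractSet-class].
#' @param temperature [DailyField-class], degC.
#' @param fires [FirePointSet-class].
#' @param smoke [DailyField-class], ug m-3.
#' @return A [HazardExperiment-class].
#' @export
buildHazardExperiment <- function(tracts, temperature, fires, smoke) {
  if (!identical(temperature@dates, smoke@dates))
    stop("temperature and smoke fields have different date axes")
  tmax <- zonalMean(temperature, tracts)
  smk <- zonalMean(smoke, tracts)
  cnt <- pointsToCounts(fires, tracts, temperature@dates)
  un <- attr(cnt, "unassigned")
  attr(cnt, "unassigned") <- NULL
  he <- hazardExperiment(tracts, temperature@dates,
                         list(tmax = tmax, fire_count = cnt, smoke = smk))
  metadata(he)$unassigned_fire_points <- sum(un)
  he
}
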