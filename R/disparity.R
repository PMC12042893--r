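#' @include AllClasses.R metrics.R
NULL

.groupPop <- function(tr, groups) {
  gp <- as.matrix(tr[, groups, drop = FALSE]) * tr$population
  colnames(gp) <- groups
  gp
}

.composition <- function(category, tr, groups, scheme) {
  gp <- .groupPop(tr, groups)
  out <- do.call(rbind, lapply(levels(category), function(lv) {
    inCat <- category == lv
    data.frame(category = lv, group = groups,
               percent = 100 * colSums(gp[inCat, , drop = FALSE]) /
                 colSums(gp),
               scheme = scheme, stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Racial/ethnic composition across exposure quintiles
#'
#' Tracts are binned by overall exposure quintile (breaks at the
#' 20/40/60/80th percentiles of the unweighted tract exposure-day
#' distribution; a tract tied with a break falls in the lower quintile),
#' and for each racial/ethnic group the percentage of that group's
#' population living in each quintile is reported. Under an even
#' distribution every group would show 20\% per quintile. Zero-population
#' tracts are excluded, mirroring their exclusion from vulnerability
#' ranking.
#'
#' @param E named per-tract exposure-day totals.
#' @param tracts a [TractSet-class].
#' @param groups race/ethnicity share columns (default all six).
#' @return data.frame: category ("Q1".."Q5"), group, percent (per group,
#'   percents sum to 100), scheme = "quintile".
#' @export
quintileComposition <- function(E, tracts, groups = .RACE_COLS) {
  tr <- tractData(tracts)
  stopifnot(length(E) == nrow(tr))
  keep <- tr$population > 0
  tr <- tr[keep, , drop = FALSE]
  E <- E[keep]
  if (length(unique(E)) == 1L)
    stop("all exposure values identical; quintile bins are degenerate - ",
         "use manualCategoryComposition()")
  breaks <- quantile(E, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  q <- 1L + rowSums(outer(E, breaks, ">"))
  category <- factor(paste0("Q", q), levels = paste0("Q", 1:5))
  .composition(category, tr, groups, "quintile")
}

#' Racial/ethnic composition across manual exposure-day categories
#'
#' For heavily zero-inflated exposures (burn zones and their
#' coexposures), quintiles are uninformative; manual day-count categories
#' are used instead. Edges \code{c(0, e1, e2, ...)} define categories
#' \code{[0]}, \code{[1, e1]}, \code{(e1, e2]}, ..., and an open-ended
#' top category. The default edges give 0, 1-2, 3-5, 6-10, and >= 11
#' days; cut-points are configurable.
#'
#' @param E named per-tract exposure-day totals.
#' @param tracts a [TractSet-class].
#' @param edges strictly increasing numeric starting at 0.
#' @param groups race/ethnicity share columns.
#' @return data.frame as [quintileComposition()], scheme = "manual".
#' @export
manualCategoryComposition <- function(E, tracts, edges = c(0, 2, 5, 10),
                                      groups = .RACE_COLS) {
  if (edges[1] != 0 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing and start at 0")
  tr <- tractData(tracts)
  stopifnot(length(E) == nrow(tr))
  keep <- tr$population > 0
  tr <- tr[keep, , drop = FALSE]
  E <- E[keep]
  labs <- c("0",
            vapply(seq_along(edges)[-1], function(k) {
              lo <- edges[k - 1] + 1
              hi <- edges[k]
              if (lo == hi) sprintf("%g", hi) else sprintf("%g-%g", lo, hi)
            }, ""),
            sprintf(">=%g", edges[length(edges)] + 1))
  cat_idx <- 1L + rowSums(outer(E, edges, ">"))
  category <- factor(labs[cat_idx], levels = labs)
  .composition(category, tr, groups, "manual")
}

#' High-vulnerability exposure overlay
#'
#' Flags tracts that are both highly socially vulnerable (SVI strictly
#' above \code{sviCut}, by default the top decile, > 0.9) and exposed at
#' least one day; tallies flagged tracts per state. Populated tracts with
#' a missing SVI are excluded with a warning naming how many.
#'
#' @param E named per-tract exposure-day totals.
#' @param tracts a [TractSet-class].
#' @param sviCut vulnerability cut-point (default 0.9).
#' @return list: \code{tracts} (tract_id, state, svi, days, flagged),
#'   \code{states} (state, n_flagged).
#' @export
sviOverlay <- function(E, tracts, sviCut = 0.9) {
  tr <- tractData(tracts)
  stopifnot(length(E) == nrow(tr))
  missingSvi <- tr$population > 0 & is.na(tr$svi)
  if (any(missingSvi))
    warning(sprintf("%d populated tract(s) missing SVI excluded",
                    sum(missingSvi)))
  keep <- !is.na(tr$svi)
  flagged <- tr$svi > sviCut & E >= 1
  flagged[!keep] <- FALSE
  perTract <- data.frame(tract_id = tr$tract_id, state = tr$state,
                         svi = tr$svi, days = as.numeric(E),
                         flagged = flagged, stringsAsFactors = FALSE)
  states <- aggregate(flagged ~ state, data = perTract, FUN = sum)
  names(states) <- c("state", "n_flagged")
  list(tracts = perTract, states = states)
}

#' Mean exposure days in flagged versus unflagged tracts
#'
#' Compares mean per-tract exposure days between tracts with and without
#' a binary attribute (tribal-land overlap by default), optionally after
#' restricting to a subset (e.g. tracts with at least one burn-zone day,
#' the restriction used for tribal-land comparisons).
#'
#' @param E named per-tract exposure-day totals.
#' @param tracts a [TractSet-class].
#' @param flagName logical tract column to split on (default
#'   \code{"tribal_overlap"}).
#' @param restrict optional logical vector over tracts; only restricted
#'   tracts enter the comparison.
#' @return data.frame: group (TRUE/FALSE on the flag), n_tracts,
#'   mean_days.
#' @export
compareGroups <- function(E, tracts, flagName = "tribal_overlap",
                          restrict = NULL) {
  tr <- tractData(tracts)
  stopifnot(length(E) == nrow(tr))
  if (!flagName %in% names(tr)) stop("no tract column '", flagName, "'")
  keep <- if (is.null(restrict)) rep(TRUE, nrow(tr)) else restrict
  stopifnot(length(keep) == nrow(tr))
  flag <- as.logical(tr[[flagName]])[keep]
  Ek <- E[keep]
  if (!any(flag) || !any(!flag))
    stop("restriction leaves an empty side of the comparison")
  data.frame(group = c(TRUE, FALSE),
             n_tracts = c(sum(flag), sum(!flag)),
             mean_days = c(mean(Ek[flag]), mean(Ek[!flag])))
}

#' Most-exposed tracts with sociodemographic profile
#'
#' Ranks tracts by cumulative exposure days (descending, ties broken by
#' tract_id) and reports the sociodemographic columns of the top \code{n}
#' alongside the all-tract average days for comparison. Non-white
#' race/ethnicity percent is 100 minus the non-Hispanic-white share.
#'
#' @param E named per-tract exposure-day totals.
#' @param tracts a [TractSet-class].
#' @param n number of tracts to report (default 10; capped at the tract
#'   count).
#' @return data.frame: state, tract_id, county, pct_65plus,
#'   pct_disability, pct_nonwhite, pct_poverty150, days, cohort_avg_days.
#' @export
topTracts <- function(E, tracts, n = 10) {
  stopifnot(n >= 1)
  tr <- tractData(tracts)
  stopifnot(length(E) == nrow(tr))
  ord <- order(-E, tr$tract_id)
  top <- head(ord, n)
  data.frame(state = tr$state[top], tract_id = tr$tract_id[top],
             county = tr$county[top],
             pct_65plus = tr$pct_65plus[top],
             pct_disability = tr$pct_disability[top],
             pct_nonwhite = 100 * (1 - tr$nh_white[top]),
             pct_poverty150 = tr$pct_poverty150[top],
             days = as.numeric(E[top]),
             cohort_avg_days = mean(E),
             stringsAsFactors = FALSE)
}
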