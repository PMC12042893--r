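#' @include AllClasses.R HazardExperiment.R
NULL

.alignCheck <- function(a, b) {
  if (!identical(dim(a), dim(b)) || !identical(dimnames(a), dimnames(b)))
    stop("hazard flag matrices are misaligned")
}

# d-1 / d / d+1 neighborhood OR, truncated at the series boundaries.
.windowAny <- function(m) {
  n <- ncol(m)
  prev <- cbind(FALSE, m[, -n, drop = FALSE])
  nxt <- cbind(m[, -1, drop = FALSE], FALSE)
  m | prev | nxt
}

.pairSameDay <- function(a, b) { .alignCheck(a, b); a & b }

# Pair (A,B) under the 2-day window: day d is flagged when A is active on
# d and B within one day of d, or vice versa. Both participating days of
# an adjacent A/B pair are flagged.
.pairTwoDay <- function(a, b) {
  .alignCheck(a, b)
  (a & .windowAny(b)) | (b & .windowAny(a))
}

#' Same-day coexposure flags
#'
#' A coexposure tract-day has two or more hazards occurring in the same
#' tract on the same day: elementwise AND per combination.
#'
#' @param eh,wfbz,wfs aligned logical tracts x days matrices.
#' @return named list of logical matrices: \code{eh_wfbz}, \code{eh_wfs},
#'   \code{wfbz_wfs}, \code{eh_wfbz_wfs}; attribute \code{window} =
#'   \code{"same_day"}.
#' @export
coexposeSameDay <- function(eh, wfbz, wfs) {
  out <- list(eh_wfbz = .pairSameDay(eh, wfbz),
              eh_wfs = .pairSameDay(eh, wfs),
              wfbz_wfs = .pairSameDay(wfbz, wfs),
              eh_wfbz_wfs = eh & wfbz & wfs)
  attr(out, "window") <- "same_day"
  out
}

#' Two-day-window coexposure flags
#'
#' Day \code{d} is flagged for a pair when one hazard is active on
#' \code{d} and the other within one day of \code{d} (so both days of an
#' adjacent pair are flagged; series boundaries use only the neighbors
#' that exist). The triple flag requires all three pairs to satisfy the
#' two-day rule on day \code{d}, which implies at least one hazard is
#' active on \code{d}. Two-day flags always contain the same-day flags.
#'
#' @inheritParams coexposeSameDay
#' @return as [coexposeSameDay()], attribute \code{window} =
#'   \code{"two_day"}.
#' @export
coexposeTwoDay <- function(eh, wfbz, wfs) {
  out <- list(eh_wfbz = .pairTwoDay(eh, wfbz),
              eh_wfs = .pairTwoDay(eh, wfs),
              wfbz_wfs = .pairTwoDay(wfbz, wfs),
              eh_wfbz_wfs = .pairTwoDay(eh, wfbz) & .pairTwoDay(eh, wfs) &
                .pairTwoDay(wfbz, wfs))
  attr(out, "window") <- "two_day"
  out
}

#' Add coexposure assays to a HazardExperiment
#'
#' @param he a classified [HazardExperiment-class] (assays \code{eh},
#'   \code{wfbz}, \code{wfs} present).
#' @param window \code{"same_day"} (default) or \code{"two_day"}.
#' @return The experiment with the four combination assays added and the
#'   window recorded in \code{metadata()}.
#' @export
coexpose <- function(he, window = c("same_day", "two_day")) {
  stopifnot(is(he, "HazardExperiment"))
  window <- match.arg(window)
  if (!all(.HAZARDS %in% assayNames(he)))
    stop("classify hazards before building coexposure flags")
  f <- if (window == "same_day") coexposeSameDay else coexposeTwoDay
  combos <- f(hazardFlags(he, "eh"), hazardFlags(he, "wfbz"),
              hazardFlags(he, "wfs"))
  for (nm in names(combos)) assay(he, nm) <- combos[[nm]]
  metadata(he)$coexposure_window <- window
  he
}
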