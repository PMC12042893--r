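#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames assay<- rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Tract-by-day hazard container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are census tracts and
#' whose columns are calendar days. Assays hold tract-by-day matrices:
#' continuous inputs (\code{tmax}, \code{smoke}, \code{fire_count}) and
#' logical hazard/coexposure flags (\code{eh}, \code{wfbz}, \code{wfs},
#' \code{eh_wfbz}, \code{eh_wfs}, \code{wfbz_wfs}, \code{eh_wfbz_wfs}).
#' \code{rowData} carries the tract attributes of the underlying
#' \linkS4class{TractSet}; \code{colData} carries \code{date}, \code{year}
#' and \code{month}. \code{metadata} records classification settings
#' (thresholds object, smoke threshold, coexposure window).
#'
#' @export
setClass("HazardExperiment", contains = "SummarizedExperiment")

setValidity("HazardExperiment", function(object) {
  cd <- colData(object)
  if (!"date" %in% names(cd))
    return("colData must carry a 'date' column")
  d <- as.integer(diff(as.Date(cd$date)))
  if (length(d) && any(d != 1L))
    return("columns must be consecutive days")
  if (!"tract_id" %in% names(rowData(object)))
    return("rowData must carry tract_id")
  TRUE
})

#' Assemble a HazardExperiment from tract-by-day matrices
#'
#' @param tracts a [TractSet-class].
#' @param dates Date vector of consecutive days.
#' @param assays named list of tract-by-day matrices (rows in
#'   \code{tractIds(tracts)} order).
#' @return A [HazardExperiment-class].
#' @export
hazardExperiment <- function(tracts, dates, assays) {
  stopifnot(is(tracts, "TractSet"), inherits(dates, "Date"))
  ids <- tractIds(tracts)
  for (nm in names(assays)) {
    a <- assays[[nm]]
    if (!identical(dim(a), c(length(ids), length(dates))))
      stop(sprintf("assay '%s' is not %d tracts x %d days",
                   nm, length(ids), length(dates)))
    dimnames(assays[[nm]]) <- list(ids, format(dates))
  }
  se <- SummarizedExperiment(
    assays = assays,
    rowData = DataFrame(tractData(tracts), row.names = ids),
    colData = DataFrame(date = dates,
                        year = as.integer(format(dates, "%Y")),
                        month = as.integer(format(dates, "%m")),
                        row.names = format(dates)))
  new("HazardExperiment", se)
}

setMethod("show", "HazardExperiment", function(object) {
  cat(sprintf("HazardExperiment: %d tracts x %d days (%s .. %s)\n",
              nrow(object), ncol(object),
              format(min(hazardDates(object))),
              format(max(hazardDates(object)))))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  md <- metadata(object)
  if (!is.null(md$wfs_threshold))
    cat(sprintf("  wfs threshold: > %g ug/m3\n", md$wfs_threshold))
  if (!is.null(md$coexposure_window))
    cat(sprintf("  coexposure window: %s\n", md$coexposure_window))
})

#' @describeIn HazardExperiment-class the Date axis (one per column).
#' @param x a \code{HazardExperiment}.
#' @export
hazardDates <- function(x) as.Date(colData(x)$date)

#' @describeIn HazardExperiment-class a named logical flag matrix for one
#'   hazard or coexposure combination.
#' @param name assay name, e.g. \code{"eh"} or \code{"eh_wfs"}.
#' @export
hazardFlags <- function(x, name) {
  if (!name %in% assayNames(x))
    stop(sprintf("no '%s' assay; available: %s", name,
                 paste(assayNames(x), collapse = ", ")))
  a <- assay(x, name)
  storage.mode(a) <- "logical"
  a
}

.HAZARDS <- c("eh", "wfbz", "wfs")
.COMBOS <- c("eh_wfbz", "eh_wfs", "wfbz_wfs", "eh_wfbz_wfs")

#' @describeIn HazardExperiment-class names of hazard/coexposure flag
#'   assays present.
#' @export
flagNames <- function(x) intersect(c(.HAZARDS, "any_hazard", .COMBOS),
                                   assayNames(x))
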