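#' @include AllClasses.R
NULL

.TRACT_PROPS <- c("tract_id", "state", "county", "ix", "iy", "population",
                  .RACE_COLS, "svi", "pct_65plus", "pct_disability",
                  "pct_poverty150", "tribal_overlap", "coastal")

#' Write tracts as GeoJSON
#'
#' Writes a FeatureCollection of rectangular tract polygons (EPSG:4326,
#' the GeoJSON default CRS) with all attributes as feature properties.
#'
#' @param tracts a [TractSet-class].
#' @param path output file.
#' @export
writeTracts <- function(tracts, path) {
  tr <- tractData(tracts)
  feats <- lapply(seq_len(nrow(tr)), function(i) {
    ring <- list(c(tr$xmin[i], tr$ymin[i]), c(tr$xmax[i], tr$ymin[i]),
                 c(tr$xmax[i], tr$ymax[i]), c(tr$xmin[i], tr$ymax[i]),
                 c(tr$xmin[i], tr$ymin[i]))
    props <- as.list(tr[i, intersect(.TRACT_PROPS, names(tr))])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  gj <- list(type = "FeatureCollection",
             latticeDim = tracts@latticeDim,
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}

#' Read tracts from GeoJSON
#'
#' Expects a FeatureCollection of axis-aligned rectangular polygons with
#' the tract attribute properties written by [writeTracts()]. Coordinates
#' are taken as EPSG:4326 (the GeoJSON default).
#'
#' @param path GeoJSON file.
#' @return A [TractSet-class].
#' @export
readTracts <- function(path) {
  if (!file.exists(path)) stop("tract file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    if (is.null(f$properties$tract_id))
      stop(sprintf("feature %d has no tract_id", i))
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    p <- f$properties
    p$svi <- if (is.null(p$svi)) NA_real_ else as.numeric(p$svi)
    c(list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys)),
      p)
  })
  tr <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (anyDuplicated(tr$tract_id))
    stop("duplicate tract_id in ", path)
  dim <- if (!is.null(gj$latticeDim))
    as.integer(unlist(gj$latticeDim)) else c(NA_integer_, NA_integer_)
  new("TractSet", tracts = tr, latticeDim = dim)
}

#' Write a gridded daily field as headered CSV
#'
#' Text serialisation of a [DailyField-class]: a JSON metadata header
#' comment (units, CRS, grid-cell edges) followed by long-format rows
#' \code{date,y,x,value} with 1-based cell indices.
#'
#' @param field a [DailyField-class].
#' @param path output file.
#' @export
writeField <- function(field, path) {
  meta <- jsonlite::toJSON(list(units = field@units, crs = field@crs,
                                x_edges = field@xEdges,
                                y_edges = field@yEdges),
                           auto_unbox = TRUE, digits = NA)
  d <- dim(field@values)
  df <- data.frame(
    date = format(rep(field@dates, d[2] * d[3])),
    y = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    x = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(field@values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# hazardCoex DailyField v1", paste0("# ", meta)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gridded daily field
#'
#' Reads the headered-CSV field format written by [writeField()].
#' Temperature fields declared in Kelvin or degrees Fahrenheit are
#' converted to degrees Celsius on read (so a 90 degF surface reads as
#' 32.22 degC). A missing CRS or a gap in the daily date axis is an
#' error.
#'
#' @param path field file.
#' @return A [DailyField-class].
#' @export
readField <- function(path) {
  if (!file.exists(path)) stop("field file not found: ", path)
  hdr <- readLines(path, n = 2L)
  if (!startsWith(hdr[1], "# hazardCoex DailyField"))
    stop("not a hazardCoex field file: ", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", hdr[2]))
  if (is.null(meta$crs)) stop("field file has no CRS declared: ", path)
  df <- read.csv(path, comment.char = "#")
  dates <- sort(unique(as.Date(df$date)))
  gaps <- which(as.integer(diff(dates)) != 1L)
  if (length(gaps))
    stop(sprintf("gap in date axis after %s", format(dates[gaps[1]])))
  ny <- length(meta$y_edges) - 1L
  nx <- length(meta$x_edges) - 1L
  vals <- array(NA_real_, dim = c(length(dates), ny, nx))
  vals[cbind(match(as.Date(df$date), dates), df$y, df$x)] <- df$value
  if (anyNA(vals)) stop("field file has missing cells: ", path)
  units <- meta$units
  if (units %in% c("K", "degK")) {
    vals <- vals - 273.15
    units <- "degC"
  } else if (units == "degF") {
    vals <- round((vals - 32) * 5 / 9, 2)
    units <- "degC"
  }
  new("DailyField", values = vals, dates = dates,
      xEdges = as.numeric(meta$x_edges), yEdges = as.numeric(meta$y_edges),
      units = units, crs = meta$crs)
}

#' Write fire points as CSV
#'
#' @param fires a [FirePointSet-class].
#' @param path output file (columns date, lon, lat).
#' @export
writeFirePoints <- function(fires, path) {
  p <- firePoints(fires)
  write.csv(data.frame(date = format(p$date), lon = p$lon, lat = p$lat),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fire points from CSV
#'
#' Malformed rows are rejected with a message naming the offending line.
#'
#' @param path CSV with columns date (ISO 8601), lon, lat.
#' @return A [FirePointSet-class].
#' @export
readFirePoints <- function(path) {
  if (!file.exists(path)) stop("fire point file not found: ", path)
  df <- read.csv(path, colClasses = "character")
  need <- c("date", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("fire point CSV needs columns date, lon, lat")
  d <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & nzchar(df$date))
  bad <- union(bad, which(!nzchar(df$date)))
  if (length(bad))
    stop(sprintf("unparseable date at line %d of %s: '%s'",
                 bad[1] + 1L, path, df$date[bad[1]]))
  lon <- suppressWarnings(as.numeric(df$lon))
  lat <- suppressWarnings(as.numeric(df$lat))
  bad <- which(is.na(lon) | is.na(lat))
  if (length(bad))
    stop(sprintf("unparseable coordinate at line %d of %s", bad[1] + 1L,
                 path))
  new("FirePointSet", points = data.frame(date = d, lon = lon, lat = lat))
}

#' Write a plain data.frame as CSV
#'
#' @param table data.frame.
#' @param path output file.
#' @export
writeTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}
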