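#' @include AllClasses.R simulate.R io.R zonal.R classify.R coexposure.R
#' @include metrics.R trend.R disparity.R
#' @importFrom stats aggregate setNames
#' @importFrom tools md5sum
NULL

#' Default run configuration
#'
#' A single flat key/value document (YAML on disk) drives the pipeline.
#' Keys: \code{seed}; the simulation block (\code{n_tracts_x},
#' \code{n_tracts_y}, \code{years}); classification settings
#' (\code{wfs_threshold}, \code{percentile}, \code{baseline_years},
#' \code{warm_season_months}); the coexposure \code{window}
#' (\code{"same_day"} or \code{"two_day"}); disparity settings
#' (\code{manual_edges}, \code{svi_cut}).
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
runConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    n_tracts_x = 4L, n_tracts_y = 4L,
    years = 2006:2007,
    wfs_threshold = 0,
    percentile = 95,
    baseline_years = NULL,
    warm_season_months = 5:9,
    window = "same_day",
    manual_edges = c(0, 2, 5, 10),
    svi_cut = 0.9)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  do.call(runConfig, config)
}

.flagsToCsv <- function(m, path) {
  df <- data.frame(tract_id = rownames(m),
                   `colnames<-`(m * 1L, colnames(m)),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
}

#' Run the full pipeline
#'
#' simulate, classify, coexpose, summarise, trend-test and run disparity
#' analyses under one configuration, writing every stage's artifacts plus
#' a run manifest into \code{outdir}. The run is deterministic given the
#' seed: rerunning the same configuration reproduces byte-identical
#' outputs. Each stage reads the previous stage's on-disk outputs, so
#' every stage is independently re-runnable on files alone.
#'
#' @param config a [runConfig()] list or path to a YAML file of the same
#'   keys.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runAll <- function(config = runConfig(), outdir = tempfile("hazardrun")) {
  cfg <- .readRunConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, cfgPath)
  warningsCount <- 0L

  # stage 1: simulate
  sim <- simConfig(seed = cfg$seed, nTractsX = cfg$n_tracts_x,
                   nTractsY = cfg$n_tracts_y, years = cfg$years)
  bundle <- simulateBundle(sim)
  writeTracts(bundle@tracts, file.path(outdir, "tracts.geojson"))
  writeField(bundle@temperature, file.path(outdir, "tmax.csv"))
  writeField(bundle@smoke, file.path(outdir, "smoke.csv"))
  writeFirePoints(bundle@firePoints, file.path(outdir, "fire_points.csv"))
  writeTable(transform(bundle@truth, date = format(date)),
             file.path(outdir, "truth_ledger.csv"))
  message("stage simulate: ", length(bundle@tracts), " tracts, ",
          length(bundle@temperature@dates), " days")

  # stage 2: aggregate + classify (from the on-disk stage-1 outputs)
  tracts <- readTracts(file.path(outdir, "tracts.geojson"))
  he <- buildHazardExperiment(tracts,
                              readField(file.path(outdir, "tmax.csv")),
                              readFirePoints(file.path(outdir,
                                                       "fire_points.csv")),
                              readField(file.path(outdir, "smoke.csv")))
  he <- classifyHazards(he, wfsThresholdUgm3 = cfg$wfs_threshold,
                        baselineYears = cfg$baseline_years,
                        warmSeasonMonths = cfg$warm_season_months,
                        percentile = cfg$percentile)
  thr <- metadata(he)$eh_thresholds
  writeTable(data.frame(tract_id = names(thr@relativeC),
                        relative_c = thr@relativeC,
                        absolute_c = thr@absoluteC),
             file.path(outdir, "eh_thresholds.csv"))
  for (nm in .HAZARDS)
    .flagsToCsv(hazardFlags(he, nm),
                file.path(outdir, sprintf("flags_%s.csv", nm)))
  message("stage classify: wfs threshold > ", cfg$wfs_threshold, " ug/m3")

  # stage 3: coexpose
  he <- coexpose(he, cfg$window)
  for (nm in .COMBOS)
    .flagsToCsv(hazardFlags(he, nm),
                file.path(outdir, sprintf("flags_%s.csv", nm)))
  message("stage coexpose: window ", cfg$window)

  # stage 4: metrics
  summary <- exposureSummary(he)
  writeTable(summary, file.path(outdir, "exposure_summary.csv"))
  monthly <- do.call(rbind, lapply(flagNames(he), function(nm) {
    pct <- withCallingHandlers(
      monthlyDistribution(hazardFlags(he, nm)),
      warning = function(w) {
        warningsCount <<- warningsCount + 1L
        invokeRestart("muffleWarning")
      })
    data.frame(hazard = nm, month = 1:12, percent = as.numeric(pct))
  }))
  writeTable(monthly, file.path(outdir, "monthly_distribution.csv"))

  # stage 5: trends
  trends <- trendTable(he)
  writeTable(trends, file.path(outdir, "trend_table.csv"))

  # stage 6: disparity
  rd <- rowData(he)
  Eof <- function(nm) exposureDaysPerTract(hazardFlags(he, nm))$E
  comp <- do.call(rbind, c(
    lapply(c("eh", "wfs", "eh_wfs"), function(nm) {
      tab <- tryCatch(quintileComposition(Eof(nm), tracts),
                      error = function(e) NULL)
      if (is.null(tab)) return(NULL)
      cbind(hazard = nm, tab)
    }),
    lapply(c("wfbz", "eh_wfbz", "wfbz_wfs", "eh_wfbz_wfs"), function(nm)
      cbind(hazard = nm,
            manualCategoryComposition(Eof(nm), tracts,
                                      edges = cfg$manual_edges)))))
  writeTable(comp, file.path(outdir, "composition.csv"))
  overlay <- do.call(rbind, lapply(flagNames(he), function(nm) {
    ov <- withCallingHandlers(
      sviOverlay(Eof(nm), tracts, sviCut = cfg$svi_cut),
      warning = function(w) {
        warningsCount <<- warningsCount + 1L
        invokeRestart("muffleWarning")
      })
    cbind(hazard = nm, ov$states)
  }))
  writeTable(overlay, file.path(outdir, "svi_overlay.csv"))
  hadWfbz <- Eof("wfbz") >= 1
  tribal <- do.call(rbind, lapply(.COMBOS, function(nm) {
    tab <- tryCatch(compareGroups(Eof(nm), tracts, "tribal_overlap",
                                  restrict = hadWfbz),
                    error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    cbind(hazard = nm, tab)
  }))
  if (!is.null(tribal))
    writeTable(tribal, file.path(outdir, "tribal_comparison.csv"))
  top <- do.call(rbind, lapply(.COMBOS, function(nm)
    cbind(hazard = nm, topTracts(Eof(nm), tracts, n = 10))))
  writeTable(top, file.path(outdir, "top_tracts.csv"))
  message("stage disparity: done")

  manifest <- list(
    package_version = as.character(utils::packageVersion("hazardCoex")),
    config_hash = unname(tools::md5sum(cfgPath)),
    n_tracts = length(tracts),
    n_days = ncol(he),
    n_fire_points = length(bundle@firePoints),
    unassigned_fire_points = metadata(he)$unassigned_fire_points,
    warnings = warningsCount,
    rows = list(exposure_summary = nrow(summary),
                monthly = nrow(monthly), trends = nrow(trends),
                composition = nrow(comp)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(outdir, "manifest.json"))
  invisible(manifest)
}
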