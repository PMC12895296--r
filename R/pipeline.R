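#' Build a pipeline run configuration
#'
#' One configuration object drives the whole synthetic run: scene size, the
#' observation years (default 2007-2010 plus 2015-2024 — 14 years around the
#' 2011-2014 acquisition gap), the classifier settings (70/30 stratified
#' split, 500 trees, training on the 2019 scene), the HAND masking threshold
#' (20 m), the water-table reference percentiles (90th flooded / 10th
#' non-flooded) and class bounds, the GWP horizons, and every generator
#' parameter. The single \code{seed} fans out deterministically to per-stage
#' child seeds, so any stage can be rerun in isolation reproducibly.
#' Configurations round-trip losslessly through YAML via
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @param seed master integer seed.
#' @param years integer years of the annual series.
#' @param gridRows,gridCols synthetic scene dimensions.
#' @param pixelSizeM pixel size (m; default 25).
#' @param nChannels drainage channels in the synthetic terrain.
#' @param handThresholdM flood-potential HAND threshold (m; default 20).
#' @param trainFraction training fraction of ground-truth points (0.7).
#' @param nTrees random-forest trees (500).
#' @param trainYear year of the scene used for training (2019).
#' @param nPoints ground-truth points (1087).
#' @param depthPercentile flooded-HAND reference percentile (90).
#' @param wtlPercentile non-flooded-HAND reference percentile (10).
#' @param gapYear year whose mosaic has a quality gap to be donor-filled
#'   from the preceding year (2008; NA disables).
#' @param hhMeanFloodedDb,hhMeanDryDb,hvMeanFloodedDb,hvMeanDryDb,noiseSdDb,incidenceRefDeg
#'   scene backscatter parameters (see [sceneParams()]).
#' @param baseCutoffM,trendMPerYear,breakpointYear,postBreakTrendMPerYear,noiseFraction,spatialAnomalySdM
#'   flood dynamics (see [floodDynamics()]); defaults encode a mild drying
#'   trend turning into wetting at 2015, with 0.4 m of smooth spatial
#'   water-level heterogeneity.
#' @param eviTrendSwamp,eviTrendTerraFirme,eviNoiseSd,eviMissingFraction,eviBaselineSwamp,eviBaselineTerraFirme
#'   EVI generator parameters (see [generateEviStack()]).
#' @param eviAvailabilityThreshold availability filter (0.8).
#' @return a list of class \code{RunConfig}.
#' @export
runConfig <- function(seed = 1L,
                      years = c(2007:2010, 2015:2024),
                      gridRows = 96L, gridCols = 96L,
                      pixelSizeM = 25, nChannels = 3L,
                      handThresholdM = 20, trainFraction = 0.7,
                      nTrees = 500L, trainYear = 2019L, nPoints = 1087L,
                      depthPercentile = 90, wtlPercentile = 10,
                      gapYear = 2008L,
                      hhMeanFloodedDb = -6, hhMeanDryDb = -9,
                      hvMeanFloodedDb = -12, hvMeanDryDb = -13,
                      noiseSdDb = 1, incidenceRefDeg = 38.7,
                      baseCutoffM = 1.2, trendMPerYear = -0.03,
                      breakpointYear = 2015L,
                      postBreakTrendMPerYear = 0.08,
                      noiseFraction = 0.02,
                      spatialAnomalySdM = 0.4,
                      eviTrendSwamp = 6e-4, eviTrendTerraFirme = 9e-4,
                      eviNoiseSd = 0.01, eviMissingFraction = 0.1,
                      eviBaselineSwamp = 0.45, eviBaselineTerraFirme = 0.50,
                      eviAvailabilityThreshold = 0.8) {
  cfg <- list(
    seed = as.integer(seed), years = as.integer(years),
    gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
    pixelSizeM = pixelSizeM, nChannels = as.integer(nChannels),
    handThresholdM = handThresholdM, trainFraction = trainFraction,
    nTrees = as.integer(nTrees), trainYear = as.integer(trainYear),
    nPoints = as.integer(nPoints),
    depthPercentile = depthPercentile, wtlPercentile = wtlPercentile,
    wtlBreaks = wtlClassBreaks(),
    gwpHorizons = c("100yr", "20yr"),
    gapYear = as.integer(gapYear),
    hhMeanFloodedDb = hhMeanFloodedDb, hhMeanDryDb = hhMeanDryDb,
    hvMeanFloodedDb = hvMeanFloodedDb, hvMeanDryDb = hvMeanDryDb,
    noiseSdDb = noiseSdDb, incidenceRefDeg = incidenceRefDeg,
    baseCutoffM = baseCutoffM, trendMPerYear = trendMPerYear,
    breakpointYear = as.integer(breakpointYear),
    postBreakTrendMPerYear = postBreakTrendMPerYear,
    noiseFraction = noiseFraction,
    spatialAnomalySdM = spatialAnomalySdM,
    eviTrendSwamp = eviTrendSwamp, eviTrendTerraFirme = eviTrendTerraFirme,
    eviNoiseSd = eviNoiseSd, eviMissingFraction = eviMissingFraction,
    eviBaselineSwamp = eviBaselineSwamp,
    eviBaselineTerraFirme = eviBaselineTerraFirme,
    eviAvailabilityThreshold = eviAvailabilityThreshold
  )
  if (anyDuplicated(cfg$years)) .stopf("years must be distinct")
  if (!cfg$trainYear %in% cfg$years)
    .stopf("trainYear %d is not in the year list", cfg$trainYear)
  class(cfg) <- "RunConfig"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param config a \code{RunConfig} list from [runConfig()].
#' @param path YAML file path.
#' @return \code{readRunConfig} returns the \code{RunConfig};
#'   \code{writeRunConfig} returns \code{path} invisibly.
#' @export
writeRunConfig <- function(config, path) {
  x <- unclass(config)
  x$wtlBreaks <- NULL  # fixed by wtlClassBreaks(); -Inf does not round-trip
  x$gwpHorizons <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(runConfig, x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("stage '%s' failed: %s", name, conditionMessage(e))
  })
}

.writeCsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "year"
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> preprocess -> classify -> water table ->
#' emissions -> trends as one deterministic run: synthetic terrain and flood
#' truth, annual backscatter scenes (with a quality gap in the configured
#' gap year, donor-filled from the preceding year), preprocessing, 70/30
#' training and annual classification, extent series with error-adjusted
#' confidence intervals, OLS and one-breakpoint piecewise extent trends, a
#' loss/gain change map between the first four and last ten years,
#' water-table reconstruction and six-class areas, per-gas emissions with
#' CO2-equivalents at both horizons and their trends, and EVI stratum and
#' pixel-wise productivity trends with a paired test.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @param outDir optional output directory; when given, all tabular
#'   artifacts (CSV), grids (ESRI ASCII), the configuration (YAML) and a
#'   JSON manifest with per-artifact stage provenance are written there.
#' @return (invisibly) a list with the fitted objects and summary tables;
#'   see the \code{report} element for the headline trend numbers.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  years <- config$years
  seeds <- vapply(1:6, function(k) childSeed(config$seed, k), integer(1))

  terrain <- .stage("simulate-terrain",
    generateTerrain(config$gridRows, config$gridCols, config$pixelSizeM,
                    config$nChannels, seed = seeds[1]))
  dyn <- floodDynamics(years, config$baseCutoffM, config$trendMPerYear,
                       config$breakpointYear, config$postBreakTrendMPerYear,
                       config$noiseFraction, config$spatialAnomalySdM,
                       seed = seeds[2])
  truth <- .stage("simulate-flood-truth", generateFloodTruth(terrain, dyn))
  params <- sceneParams(config$hhMeanFloodedDb, config$hhMeanDryDb,
                        config$hvMeanFloodedDb, config$hvMeanDryDb,
                        config$noiseSdDb, config$incidenceRefDeg,
                        seed = seeds[3])

  nr <- config$gridRows; nc <- config$gridCols
  gapMask <- matrix(FALSE, nr, nc)
  gapMask[seq_len(max(nr %/% 4L, 1L)), seq_len(max(nc %/% 4L, 1L))] <- TRUE

  scenes <- .stage("simulate-backscatter", lapply(seq_along(years), function(i) {
    gm <- if (!is.na(config$gapYear) && years[i] == config$gapYear) gapMask
          else NULL
    generateBackscatter(terrain, truth[[i]], params, years[i], gapMask = gm)
  }))
  names(scenes) <- as.character(years)

  scenes <- .stage("preprocess", {
    pp <- lapply(scenes, preprocessScene,
                 referenceDeg = config$incidenceRefDeg)
    gi <- match(config$gapYear, years)
    if (!is.na(gi) && gi > 1L) pp[[gi]] <- fillGaps(pp[[gi]], pp[[gi - 1L]])
    pp
  })

  potential <- floodPotentialMask(terrain@forestMask, terrain@handM,
                                  config$handThresholdM)

  classifier <- .stage("train", {
    gt <- generateGroundTruth(truth[[as.character(config$trainYear)]],
                              config$nPoints, seed = seeds[4],
                              eligibleMask = potential)
    feats <- extractFeatures(scenes[[as.character(config$trainYear)]],
                             terrain@handM, gt)
    trainFloodClassifier(feats, config$trainFraction, config$nTrees,
                         seed = seeds[5])
  })

  maps <- .stage("classify", lapply(scenes, classifyYear,
    classifier = classifier, handM = terrain@handM,
    potentialMask = potential, pixelSizeM = config$pixelSizeM))

  extents <- extentSeries(maps)
  adjusted <- do.call(rbind, lapply(maps, errorAdjustedExtent,
                                    report = classifier@report))
  rownames(adjusted) <- NULL
  extentTrend <- olsTrend(extents$year, extents$areaKm2)
  extentPiecewise <- piecewiseTrend(extents$year, extents$areaKm2)

  early <- maps[years <= min(years) + 3L]
  late <- maps[years > min(years) + 3L]
  change <- changeMap(early, late)

  domain <- maxFloodExtent(maps)
  wtg <- .stage("wtl", lapply(maps, waterTable, handM = terrain@handM,
                              domain = domain,
                              depthPct = config$depthPercentile,
                              wtlPct = config$wtlPercentile))
  classAreas <- do.call(rbind, lapply(wtg, wtlClassAreas))
  rownames(classAreas) <- NULL

  flux <- defaultFluxTable()
  emis <- .stage("emissions", emissionsSeries(split(classAreas, classAreas$year), flux))
  emissionTrends <- lapply(split(emis, emis$quantity), function(d)
    olsTrend(d$year, d$total))

  eviStack <- .stage("simulate-evi", generateEviStack(
    terrain, truth,
    trendPerYear = c(swamp = config$eviTrendSwamp,
                     terra_firme = config$eviTrendTerraFirme),
    noiseSd = config$eviNoiseSd,
    missingFraction = config$eviMissingFraction, seed = seeds[6],
    baselineSwamp = config$eviBaselineSwamp,
    baselineTerraFirme = config$eviBaselineTerraFirme))

  # availability filter over the annual series (the AMJ compositing path
  # applies the same rule to monthly stacks)
  availability <- Reduce(`+`, lapply(eviStack$evi, function(m) !is.na(m) + 0L)) /
    length(eviStack$evi)
  kept <- availability >= config$eviAvailabilityThreshold &
    terrain@forestMask
  eviFiltered <- lapply(eviStack$evi, function(m) { m[!kept] <- NA_real_; m })

  strata <- stratumMeans(eviFiltered, years, eviStack$floodFrequency,
                         eviStack$nMaps)
  strataTrends <- list(
    all = olsTrend(strata$year, strata$all),
    swamp = olsTrend(strata$year, strata$swamp),
    terra_firme = olsTrend(strata$year, strata$terra_firme))
  paired <- pairedTTest(strata$swamp, strata$terra_firme)
  pixelTrends <- pixelwiseTrends(eviFiltered, years)

  report <- data.frame(
    quantity = c("extent_km2", "CO2_t", "CH4_t", "N2O_t",
                 "CO2eq_100yr_t", "CO2eq_20yr_t",
                 "EVI_all", "EVI_swamp", "EVI_terra_firme"),
    slopePerYear = c(extentTrend@slope,
                     emissionTrends[["CO2"]]@slope,
                     emissionTrends[["CH4"]]@slope,
                     emissionTrends[["N2O"]]@slope,
                     emissionTrends[["CO2eq_100yr"]]@slope,
                     emissionTrends[["CO2eq_20yr"]]@slope,
                     strataTrends$all@slope, strataTrends$swamp@slope,
                     strataTrends$terra_firme@slope),
    pValue = c(extentTrend@pValue,
               emissionTrends[["CO2"]]@pValue,
               emissionTrends[["CH4"]]@pValue,
               emissionTrends[["N2O"]]@pValue,
               emissionTrends[["CO2eq_100yr"]]@pValue,
               emissionTrends[["CO2eq_20yr"]]@pValue,
               strataTrends$all@pValue, strataTrends$swamp@pValue,
               strataTrends$terra_firme@pValue)
  )

  result <- list(
    config = config, terrain = terrain, truth = truth, scenes = scenes,
    classifier = classifier, maps = maps,
    extents = extents, adjustedExtents = adjusted,
    extentTrend = extentTrend, extentPiecewise = extentPiecewise,
    changeCounts = change$counts, changeClasses = change$classes,
    maxExtent = domain, waterTables = wtg, classAreas = classAreas,
    fluxTable = flux, emissions = emis, emissionTrends = emissionTrends,
    strata = strata, strataTrends = strataTrends, pairedTest = paired,
    pixelTrends = pixelTrends, report = report,
    yearGap = setdiff(seq(min(years), max(years)), years)
  )

  if (!is.null(outDir)) .writeRunArtifacts(result, outDir)
  invisible(result)
}

.writeRunArtifacts <- function(result, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  px <- result$config$pixelSizeM
  manifest <- list()
  add <- function(file, stage, description) {
    manifest[[length(manifest) + 1L]] <<-
      list(file = file, stage = stage, description = description)
  }

  writeRunConfig(result$config, file.path(outDir, "config.yaml"))
  add("config.yaml", "config", "run configuration (YAML)")

  writeAsciiGrid(result$terrain@handM, file.path(outDir, "hand.asc"), px)
  add("hand.asc", "simulate", "HAND grid (m)")
  writeAsciiGrid(result$terrain@forestMask, file.path(outDir, "forest_mask.asc"), px)
  add("forest_mask.asc", "simulate", "forest mask (0/1)")
  writeAsciiGrid(result$maxExtent, file.path(outDir, "max_flood_extent.asc"), px)
  add("max_flood_extent.asc", "wtl", "maximum flood extent (0/1)")

  for (m in result$maps) {
    f <- sprintf("flood_map_%d.asc", m@year)
    g <- m@flooded + 0
    g[!m@analysisMask] <- NA
    writeAsciiGrid(g, file.path(outDir, f), px)
    add(f, "classify", sprintf("flood map %d (1 flooded, 0 dry, nodata unclassified)", m@year))
  }
  for (w in result$waterTables) {
    f <- sprintf("wtl_%d.asc", w@year)
    writeAsciiGrid(w@wtlCm, file.path(outDir, f), px)
    add(f, "wtl", sprintf("water-table level %d (cm)", w@year))
  }

  .writeCsv(result$extents, file.path(outDir, "extents.csv"))
  add("extents.csv", "classify", "annual swamp extent (km2)")
  .writeCsv(result$adjustedExtents, file.path(outDir, "extents_adjusted.csv"))
  add("extents_adjusted.csv", "classify", "error-adjusted extents with 95% CI")
  cm <- as.data.frame(as.table(result$classifier@report@confusion))
  names(cm) <- c("mapped", "reference", "count")
  .writeCsv(cm, file.path(outDir, "confusion.csv"))
  add("confusion.csv", "train", "holdout confusion matrix")
  .writeCsv(result$classAreas, file.path(outDir, "wtl_class_areas.csv"))
  add("wtl_class_areas.csv", "wtl", "six-class WTL areas per year (km2)")
  writeFluxTable(result$fluxTable, file.path(outDir, "flux_table.csv"))
  add("flux_table.csv", "emissions", "flux densities used (t km-2 yr-1)")
  .writeCsv(result$emissions, file.path(outDir, "emissions.csv"))
  add("emissions.csv", "emissions", "annual totals per gas and CO2-eq (t yr-1)")
  .writeCsv(result$strata, file.path(outDir, "evi_strata.csv"))
  add("evi_strata.csv", "trends", "EVI stratum means per year")
  .writeCsv(result$report, file.path(outDir, "report.csv"))
  add("report.csv", "trends", "headline slopes and p values")

  chg <- data.frame(class = names(result$changeCounts),
                    pixels = as.integer(result$changeCounts))
  .writeCsv(chg, file.path(outDir, "change_map_counts.csv"))
  add("change_map_counts.csv", "classify", "loss/gain change-map class counts")

  jsonlite::write_json(
    list(seed = result$config$seed,
         years = result$config$years,
         yearGap = result$yearGap,
         artifacts = manifest),
    file.path(outDir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
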