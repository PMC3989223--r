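#' @include io.R
NULL

#' Assemble a pipeline configuration
#'
#' Bundles everything [runPipeline()] needs. `records` may be a data.frame
#' or a CSV path (read via [readRecords()]); `studyArea` a polygon matrix or
#' a GeoJSON path (read via [readStudyArea()]).
#'
#' @param records individual records (data.frame or CSV path).
#' @param studyArea capture-area polygon (matrix with columns x, y, or
#'   GeoJSON path) used for residency calls; default: a 5 km disc around the
#'   centroid of the benchmark locations.
#' @param benchmarkLocs `loc_id` values forming the focal (known-origin)
#'   study area whose returning ASY birds define the year benchmark.
#' @param benchmarkYear reference year for the delta-2H year correction.
#' @param extent named (xmin, xmax, ymin, ymax) in km; default: the record
#'   bounding box padded by `pad` km.
#' @param cell analysis cell size, km (default 2).
#' @param pad extent padding, km (default 20).
#' @param ageFactors delta-2H age correction factors applied to SY birds.
#' @param oddsRatios odds ratios for the binarization.
#' @param families candidate semivariogram families.
#' @param outputDir directory for CSV / raster / sidecar outputs, or `NULL`
#'   to keep everything in memory.
#' @param verbose log stage-level progress with record counts.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(records, benchmarkLocs, benchmarkYear,
                           studyArea = NULL, extent = NULL, cell = 2,
                           pad = 20, ageFactors = c(-6, -3, 0, 3, 6),
                           oddsRatios = c(2, 4),
                           families = VARIOGRAM_FAMILIES,
                           outputDir = NULL, verbose = TRUE) {
  if (is.character(records)) records <- readRecords(records)
  if (is.character(studyArea)) studyArea <- readStudyArea(studyArea)
  stopifnot(cell > 0, all(oddsRatios > 0), length(benchmarkLocs) >= 1)
  if (is.null(extent)) {
    extent <- c(xmin = min(records$x_km) - pad, xmax = max(records$x_km) + pad,
                ymin = min(records$y_km) - pad, ymax = max(records$y_km) + pad)
  }
  structure(list(records = records, studyArea = studyArea,
                 benchmarkLocs = as.character(benchmarkLocs),
                 benchmarkYear = as.integer(benchmarkYear),
                 extent = extent, cell = cell, ageFactors = ageFactors,
                 oddsRatios = oddsRatios, families = families,
                 outputDir = outputDir, verbose = isTRUE(verbose)),
            class = "PipelineConfig")
}

stageLog <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full assignment pipeline
#'
#' Orchestrates the analysis end to end: location summaries, year
#' calibration from benchmark returning-ASY birds, per-isotope semivariogram
#' selection and ordinary kriging, within-location covariance estimation
#' from the validation subset, per-SY-bird bivariate assignment at every
#' (age factor x odds ratio) combination, residency and dispersal-distance
#' calls, and minimum detectable distances at the benchmark locations. The
#' pipeline is deterministic: it consumes no randomness beyond what is
#' already frozen in its input records.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()].
#' @return list with elements `summaries`, `yearCorrection`, `isoscapes`
#'   (list of two [Isoscape-class]), `cov` ([CovStructure-class]), `calls`
#'   (per-individual residency data.frame over all combinations),
#'   `summedSurfaces` (per-combination count rasters), `minDetectable`
#'   (per-benchmark-location distances), `sulfurTest` (when two sulfur years
#'   are available) and `config`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  rec <- config$records
  v <- config$verbose
  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  grid <- gridSpec(config$extent[["xmin"]], config$extent[["xmax"]],
                   config$extent[["ymin"]], config$extent[["ymax"]],
                   cell = config$cell)
  stageLog(v, "grid", "%d x %d cells of %g km", grid@nx, grid@ny, grid@cell)

  asy <- rec[rec$age == "ASY", , drop = FALSE]
  sy <- rec[rec$age == "SY" & rec$loc_id %in% config$benchmarkLocs, ,
            drop = FALSE]
  stageLog(v, "input", "%d records in: %d ASY, %d focal SY",
           nrow(rec), nrow(asy), nrow(sy))

  # -- year calibration from benchmark returning ASY ----------------------
  bench <- asy[asy$loc_id %in% config$benchmarkLocs, , drop = FALSE]
  yc <- withStage("calibration", {
    if (length(unique(bench$year)) > 1) {
      yearOffsets(bench, benchmarkYear = config$benchmarkYear)
    } else {
      yearOffsets(means = stats::setNames(mean(bench$d2H),
                                          unique(bench$year)),
                  benchmarkYear = config$benchmarkYear)
    }
  })
  # extend coverage to years seen only outside the benchmark area
  missingYears <- setdiff(unique(as.character(asy$year)), names(yc$offsets))
  if (length(missingYears))
    stop("pipeline stage 'calibration' failed: no benchmark birds for ",
         "year(s) ", paste(missingYears, collapse = ", "))
  asyCal <- withStage("calibration", applyCorrections(asy, yc, ageFactor = 0))
  stageLog(v, "calibration", "offsets: %s",
           paste(sprintf("%s %+0.1f", names(yc$offsets), yc$offsets),
                 collapse = ", "))

  # -- optional sulfur year test over benchmark birds ---------------------
  sulfur <- NULL
  sYears <- sort(unique(bench$year[is.finite(bench$d34S)]))
  if (length(sYears) >= 2) {
    ga <- bench$d34S[bench$year == sYears[1] & is.finite(bench$d34S)]
    gb <- bench$d34S[bench$year == sYears[length(sYears)] &
                     is.finite(bench$d34S)]
    if (length(ga) >= 2 && length(gb) >= 2) {
      sulfur <- sulfurYearTest(ga, gb)
      stageLog(v, "calibration",
               "sulfur year test: t(%d) = %.2f, p = %.3f%s", sulfur$df,
               sulfur$t, sulfur$p,
               if (sulfur$negligible) " (negligible vs 2 per-mil assay error)"
               else "")
    }
  }

  # -- isoscapes ----------------------------------------------------------
  # benchmark-area ASY from non-benchmark years only serve the year
  # calibration; the isoscape uses outside birds plus benchmark-year birds
  isoRec <- asyCal[!(asyCal$loc_id %in% config$benchmarkLocs &
                     asyCal$year != config$benchmarkYear), , drop = FALSE]
  summaries <- withStage("summarize",
                         summarizeLocations(isoRec,
                                            isotopes = c("d2H", "d34S")))
  stageLog(v, "summarize", "%d locations", nrow(summaries))
  isoH <- withStage("isoscape", buildIsoscape(
    summaries[summaries$n_d2H > 0, ], "d2H", grid, families = config$families))
  isoS <- withStage("isoscape", buildIsoscape(
    summaries[summaries$n_d34S > 0, ], "d34S", grid,
    families = config$families))
  stageLog(v, "isoscape", "d2H: %s (RMSE %.3g); d34S: %s (RMSE %.3g)",
           isoH@model@family, isoH@rmse, isoS@model@family, isoS@rmse)

  # -- covariance structure from the validation subset --------------------
  valid <- asyCal[!asyCal$loc_id %in% config$benchmarkLocs &
                  is.finite(asyCal$d34S), , drop = FALSE]
  cov <- withStage("covariance", estimateCovStructure(valid))
  stageLog(v, "covariance",
           "sigma_H %.2f, sigma_S %.2f, omega %.2f (df %d, %d birds)",
           cov@sigmaH, cov@sigmaS, cov@omega, cov@n, nrow(valid))

  # -- capture area -------------------------------------------------------
  area <- config$studyArea
  if (is.null(area)) {
    bl <- summaries[summaries$loc_id %in% config$benchmarkLocs, ]
    area <- discPolygon(mean(bl$x), mean(bl$y), radius = 5)
  }
  breedingPoint <- colMeans(area)

  # -- per-individual assignment over the sensitivity design --------------
  syUse <- sy[is.finite(sy$d2H) & is.finite(sy$d34S), , drop = FALSE]
  if (nrow(syUse) < nrow(sy))
    stageLog(v, "assign", "skipping %d SY bird(s) missing an isotope",
             nrow(sy) - nrow(syUse))
  calls <- list()
  summed <- list()
  for (af in config$ageFactors) {
    syCal <- applyCorrections(syUse, yc, ageFactor = af)
    for (odds in config$oddsRatios) {
      surfaces <- lapply(seq_len(nrow(syCal)), function(i)
        oddsBinarize(likelihoodSurface(syCal[i, ], isoH, isoS, cov), odds))
      block <- residencySummary(surfaces, area, breedingPoint)
      block$age_correction <- af
      calls[[length(calls) + 1L]] <- block
      key <- sprintf("age%+g_odds%g", af, odds)
      if (length(surfaces)) summed[[key]] <- sumBinarySurfaces(surfaces)
      stageLog(v, "assign", "age %+g, %g:1 -> %d/%d residents", af, odds,
               sum(block$resident), nrow(block))
    }
  }
  calls <- do.call(rbind, calls)

  # -- minimum detectable distance at the benchmark locations -------------
  bl <- summaries[summaries$loc_id %in% config$benchmarkLocs, , drop = FALSE]
  minDet <- vapply(seq_len(nrow(bl)), function(i)
    minDetectableDistance(isoH, isoS, cov, c(bl$x[i], bl$y[i]),
                          odds = config$oddsRatios[1]), numeric(1))
  names(minDet) <- bl$loc_id
  stageLog(v, "detectability", "mean %.0f km (SD %.0f) over %d locations",
           mean(minDet[is.finite(minDet)]), stats::sd(minDet[is.finite(minDet)]),
           length(minDet))

  out <- list(summaries = summaries, yearCorrection = yc,
              isoscapes = list(d2H = isoH, d34S = isoS), cov = cov,
              calls = calls, summedSurfaces = summed,
              minDetectable = minDet, sulfurTest = sulfur, config = config)
  if (!is.null(config$outputDir)) writePipelineOutputs(out)
  out
}

# write the report bundle: summary CSVs, isoscape rasters, model sidecars,
# summed per-combination rasters, calibration audit
writePipelineOutputs <- function(result) {
  dir <- result$config$outputDir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$summaries, file.path(dir, "location_summaries.csv"),
                   row.names = FALSE)
  calls <- result$calls
  calls$min_dispersal_km <- round(calls$min_dispersal_km, 3)
  utils::write.csv(calls, file.path(dir, "residency_calls.csv"),
                   row.names = FALSE)
  for (iso in names(result$isoscapes)) {
    s <- result$isoscapes[[iso]]
    writeAsciiGrid(s@mean, s@grid, file.path(dir, paste0("isoscape_", iso, ".asc")))
    writeAsciiGrid(s@variance, s@grid,
                   file.path(dir, paste0("krigvar_", iso, ".asc")))
    writeVariogramModel(s@model, file.path(dir, paste0("variogram_", iso, ".yml")),
                        rmse = s@rmse)
  }
  for (key in names(result$summedSurfaces)) {
    s <- result$summedSurfaces[[key]]
    writeAsciiGrid(s$counts, s$grid, file.path(dir, paste0("summed_", key, ".asc")))
  }
  md <- data.frame(loc_id = names(result$minDetectable),
                   min_detectable_km = round(unname(result$minDetectable), 3))
  utils::write.csv(md, file.path(dir, "min_detectable.csv"), row.names = FALSE)
  invisible(dir)
}
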