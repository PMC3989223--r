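#' @include dispersal.R
NULL

#' Read individual records from CSV
#'
#' Validates the tabular input format: required columns `id`, `loc_id`,
#' `x_km`, `y_km`, `year`, `age` plus the isotope columns `d2H` (required)
#' and `d34S` (optional — the sulfur assay was run on subsets only). Rows
#' with a non-numeric required isotope value are rejected with a logged line
#' number; blank / missing `d34S` is kept and flagged.
#'
#' @param path CSV file path.
#' @return record data.frame; rejected row numbers (if any) in attribute
#'   `"rejected"`, and a logical `sulfur_missing` column.
#' @export
readRecords <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "loc_id", "x_km", "y_km", "year", "age", "d2H")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"d34S" %in% names(df)) df$d34S <- NA_real_
  for (col in c("x_km", "y_km", "d2H", "d34S"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  df$year <- suppressWarnings(as.integer(df$year))
  bad <- which(!is.finite(df$d2H) | !is.finite(df$x_km) |
               !is.finite(df$y_km) | is.na(df$year) |
               !df$age %in% c("SY", "ASY"))
  if (length(bad)) {
    message("rejecting ", length(bad), " malformed row(s): lines ",
            paste(bad + 1L, collapse = ", "))
    df <- df[-bad, , drop = FALSE]
  }
  df$sulfur_missing <- !is.finite(df$d34S)
  rownames(df) <- NULL
  attr(df, "rejected") <- bad
  df
}

#' Write / read a raster as plain-text ESRI ASCII grid
#'
#' Single-band text raster with full grid metadata (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`), the package's
#' raster interchange format.
#'
#' @param values matrix (`ny` x `nx`, row 1 = southernmost row).
#' @param grid a [GridSpec-class].
#' @param path output / input file path.
#' @return `writeAsciiGrid()` the path invisibly; `readAsciiGrid()` a list
#'   with `grid` and `values`.
#' @export
writeAsciiGrid <- function(values, grid, path) {
  stopifnot(identical(dim(values), as.integer(c(grid@ny, grid@nx))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", grid@nx), paste("nrows", grid@ny),
               paste("xllcorner", grid@xmin), paste("yllcorner", grid@ymin),
               paste("cellsize", grid@cell), "NODATA_value -9999"), con)
  # ASCII grids are written top row first
  for (r in rev(seq_len(grid@ny)))
    writeLines(paste(format(values[r, ], trim = TRUE, digits = 15),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  grid <- new("GridSpec", xmin = vals[["xllcorner"]],
              ymin = vals[["yllcorner"]], cell = vals[["cellsize"]],
              nx = as.integer(vals[["ncols"]]), ny = as.integer(vals[["nrows"]]))
  body <- lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)
  m[m == vals[["nodata_value"]]] <- NA
  list(grid = grid, values = m[rev(seq_len(grid@ny)), , drop = FALSE])
}

#' Serialize / restore a variogram model as a key/value sidecar
#'
#' @param model a [VariogramModel-class].
#' @param path YAML file path.
#' @param rmse optional LOOCV RMSE recorded alongside.
#' @return `writeVariogramModel()` the path invisibly;
#'   `readVariogramModel()` the model (with `rmse` attribute when present).
#' @export
writeVariogramModel <- function(model, path, rmse = attr(model, "rmse")) {
  x <- list(family = model@family, nugget = model@nugget,
            partial_sill = model@psill,
            total_sill = model@nugget + model@psill, range_km = model@range)
  if (!is.null(rmse) && is.finite(rmse)) x$loocv_rmse <- rmse
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeVariogramModel
#' @export
readVariogramModel <- function(path) {
  x <- yaml::read_yaml(path)
  m <- variogramModel(x$family, x$nugget, x$partial_sill, x$range_km)
  if (!is.null(x$loocv_rmse)) attr(m, "rmse") <- x$loocv_rmse
  m
}

#' Read a study-area polygon from GeoJSON
#'
#' Accepts a `Polygon` (or single-polygon `MultiPolygon` / `Feature` /
#' `FeatureCollection`) and returns its outer ring in the projected km frame
#' the rest of the package uses.
#'
#' @param path GeoJSON file path.
#' @return matrix with columns `x`, `y` (closing vertex dropped).
#' @export
readStudyArea <- function(path) {
  g <- jsonlite::read_json(path)
  geom <- g
  if (identical(g$type, "FeatureCollection")) geom <- g$features[[1]]$geometry
  if (identical(geom$type, "Feature")) geom <- geom$geometry
  ring <- switch(geom$type,
    Polygon = geom$coordinates[[1]],
    MultiPolygon = geom$coordinates[[1]][[1]],
    stop("unsupported GeoJSON geometry: ", geom$type))
  m <- do.call(rbind, lapply(ring, function(p) c(x = p[[1]], y = p[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ]))
    m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Write a simulation / pipeline configuration as YAML
#'
#' @param config a [SimConfig-class].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  yaml::write_yaml(list(
    extent = as.list(config@extent), n_locations = config@nLocations,
    birds_per_location = config@birdsPerLocation,
    grid_cell = config@gridCell, field_cell = config@fieldCell,
    intercept_H = config@interceptH, intercept_S = config@interceptS,
    gradient_H = config@gradientH, gradient_S = config@gradientS,
    spatial_range = config@spatialRange, spatial_sill = config@spatialSill,
    nugget = config@nugget, sigma_H = config@sigmaH, sigma_S = config@sigmaS,
    omega = config@omega, year_offsets = as.list(config@yearOffsets),
    age_offset = config@ageOffset, min_separation = config@minSeparation,
    seed = config@seed), path)
  invisible(path)
}
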