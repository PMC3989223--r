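#' @include kriging.R
NULL

#' Summarize individual records into per-location means
#'
#' Collapses individual isotope measurements into one summary per (pooled)
#' sampling location: arithmetic mean, SD and count per isotope, plus the
#' location centroid as the unweighted mean of the member sites' coordinates.
#' Sites may be pooled into coarser locations via `pooling` (the paper-style
#' design pools the 12 focal study sites into 4 locations); the default
#' identity pooling keeps every site as its own location.
#'
#' @param records data.frame of individual records with columns `loc_id`,
#'   `x_km`, `y_km` and the isotope columns.
#' @param pooling named character vector mapping site ids to pooled location
#'   ids; sites absent from the map are an error. `NULL` for identity.
#' @param isotopes isotope columns to summarize.
#' @return data.frame with one row per location: `loc_id`, `x`, `y`, then
#'   `mean_<iso>`, `sd_<iso>`, `n_<iso>` per isotope. Locations with no
#'   finite value for any requested isotope are dropped with a warning.
#' @export
summarizeLocations <- function(records, pooling = NULL,
                               isotopes = c("d2H", "d34S")) {
  stopifnot(all(c("loc_id", "x_km", "y_km") %in% names(records)),
            all(isotopes %in% names(records)))
  site <- as.character(records$loc_id)
  if (is.null(pooling)) {
    loc <- site
  } else {
    missing <- setdiff(unique(site), names(pooling))
    if (length(missing))
      stop("sites absent from the pooling map: ",
           paste(missing, collapse = ", "))
    loc <- unname(pooling[site])
  }
  # centroid = unweighted mean over member sites' (unique) coordinates
  sites <- unique(data.frame(site = site, loc = loc,
                             x = records$x_km, y = records$y_km,
                             stringsAsFactors = FALSE))
  cx <- tapply(sites$x, sites$loc, mean)
  cy <- tapply(sites$y, sites$loc, mean)
  locs <- sort(unique(loc))
  out <- data.frame(loc_id = locs,
                    x = as.numeric(cx[locs]), y = as.numeric(cy[locs]),
                    stringsAsFactors = FALSE)
  for (iso in isotopes) {
    v <- records[[iso]]
    ok <- is.finite(v)
    n <- tapply(ok, loc, sum)
    mean_ <- tapply(ifelse(ok, v, NA), loc, mean, na.rm = TRUE)
    sd_ <- tapply(ifelse(ok, v, NA), loc, stats::sd, na.rm = TRUE)
    out[[paste0("mean_", iso)]] <- as.numeric(mean_[locs])
    out[[paste0("sd_", iso)]] <- as.numeric(sd_[locs])
    out[[paste0("n_", iso)]] <- as.integer(n[locs])
  }
  nIso <- as.matrix(out[, paste0("n_", isotopes), drop = FALSE])
  empty <- rowSums(nIso) == 0
  if (any(empty)) {
    warning("dropping location(s) with no isotope values: ",
            paste(out$loc_id[empty], collapse = ", "))
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Build one isoscape end to end
#'
#' Convenience wrapper chaining [selectModel()] (semivariogram family choice
#' by minimum leave-one-out RMSE) and [krige()] for a single isotope.
#'
#' @param summaries output of [summarizeLocations()].
#' @param isotope isotope column label, e.g. `"d2H"`.
#' @param grid target [GridSpec-class].
#' @param families candidate semivariogram families.
#' @param ... passed to [empiricalVariogram()] via [selectModel()].
#' @return an [Isoscape-class] carrying the winning model and its RMSE.
#' @export
buildIsoscape <- function(summaries, isotope, grid,
                          families = VARIOGRAM_FAMILIES, ...) {
  value <- paste0("mean_", isotope)
  if (!value %in% names(summaries)) value <- isotope
  stopifnot(value %in% names(summaries))
  use <- summaries[is.finite(summaries[[value]]), , drop = FALSE]
  model <- selectModel(use, families = families, value = value, ...)
  krige(use, model, grid, value = value, isotope = isotope,
        rmse = attr(model, "rmse"))
}
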