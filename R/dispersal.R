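#' @include assignment.R
NULL

#' Capture-area polygon from a point
#'
#' Converts a capture point to a disc polygon of the given radius, the
#' default residency footprint when no explicit study-area polygon is
#' supplied (birds at a sampling location were captured within ca. 5 km of
#' it).
#'
#' @param x,y capture point, km.
#' @param radius disc radius in km (default 5).
#' @param n number of polygon vertices.
#' @return matrix with columns `x`, `y` (open ring).
#' @export
discPolygon <- function(x, y, radius = 5, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = x + radius * cos(th), y = y + radius * sin(th))
}

#' Classify an individual as resident or immigrant
#'
#' A bird is a resident when at least one included cell center of its binary
#' origin surface falls inside the capture-area polygon, and an immigrant
#' otherwise. Immigrants additionally get the minimum dispersal distance to
#' the assigned region; residents get 0. `edge_contact` flags assigned
#' regions touching the outermost grid ring (where the true extent of the
#' origin area is censored by the isoscape edge, so maximum dispersal
#' distance cannot be estimated).
#'
#' @param bs a [BinarySurface-class].
#' @param captureArea polygon matrix (columns `x`, `y`) — see
#'   [discPolygon()] for the point-capture default.
#' @param breedingPoint optional (x, y) used for the distance; defaults to
#'   the polygon centroid.
#' @return data.frame row: `id`, `odds`, `resident`, `min_dispersal_km`,
#'   `edge_contact`.
#' @export
classifyResidency <- function(bs, captureArea, breedingPoint = NULL) {
  stopifnot(is(bs, "BinarySurface"))
  inc <- gridVec(bs@included) == 1L
  if (!any(inc)) stop("empty binary surface: cannot classify '", bs@id, "'")
  xy <- cellXY(bs@grid, which(inc))
  inside <- sp::point.in.polygon(xy[, "x"], xy[, "y"],
                                 captureArea[, 1], captureArea[, 2]) > 0
  resident <- any(inside)
  if (is.null(breedingPoint))
    breedingPoint <- colMeans(captureArea)
  minKm <- if (resident) 0
    else minDispersalDistance(bs, breedingPoint)
  edge <- any(gridVec(edgeMask(bs@grid))[inc])
  data.frame(id = bs@id, odds = bs@odds, resident = resident,
             min_dispersal_km = minKm, edge_contact = edge,
             stringsAsFactors = FALSE)
}

#' Minimum dispersal distance to the assigned origin region
#'
#' Minimum Euclidean distance from the breeding point to the nearest
#' included cell center; 0 when the breeding point lies inside an included
#' cell.
#'
#' @param bs a [BinarySurface-class] with at least one included cell.
#' @param breedingPoint numeric (x, y), km.
#' @return distance in km.
#' @export
minDispersalDistance <- function(bs, breedingPoint) {
  inc <- gridVec(bs@included) == 1L
  if (!any(inc)) stop("empty binary surface for '", bs@id, "'")
  if (inc[cellAt(bs@grid, breedingPoint[1], breedingPoint[2])])
    return(0)
  xy <- cellXY(bs@grid, which(inc))
  min(sqrt((xy[, "x"] - breedingPoint[1])^2 +
           (xy[, "y"] - breedingPoint[2])^2))
}

#' Minimum detectable dispersal distance at a location
#'
#' The method's short-distance blind spot at a site: a fictional individual
#' is given exactly the isotope values the isoscapes predict at the location
#' (origin "unknown"), assigned, and the distance from the location to the
#' nearest cell classified as *unlikely* origin is returned. A bird
#' dispersing less than this distance cannot be told apart from a resident.
#'
#' @param isoH,isoS the two [Isoscape-class] objects.
#' @param cov a [CovStructure-class].
#' @param location numeric (x, y), km.
#' @param odds odds ratio for the binarization (default 2).
#' @return distance in km, or `Inf` (with a warning) when the whole grid is
#'   classified as likely origin — not detectable within the extent.
#' @export
minDetectableDistance <- function(isoH, isoS, cov, location, odds = 2) {
  g <- isoH@grid
  cell <- cellAt(g, location[1], location[2])
  fict <- list(id = sprintf("fictional_%.0f_%.0f", location[1], location[2]),
               d2H = gridVec(isoH@mean)[cell], d34S = gridVec(isoS@mean)[cell])
  bs <- oddsBinarize(likelihoodSurface(fict, isoH, isoS, cov), odds)
  exc <- gridVec(bs@included) == 0L
  if (!any(exc)) {
    warning("likely origin covers the whole grid at (", location[1], ", ",
            location[2], "): not detectable within extent")
    return(Inf)
  }
  xy <- cellXY(g, which(exc))
  min(sqrt((xy[, "x"] - location[1])^2 + (xy[, "y"] - location[2])^2))
}

#' Classification accuracy for known-origin birds
#'
#' Percentage of birds whose assigned (likely-origin) region overlaps their
#' known origin area.
#'
#' @param overlaps logical vector, one per bird: does the assigned region
#'   overlap the known origin?
#' @return percentage in `[0, 100]`, full precision.
#' @export
classificationAccuracy <- function(overlaps) {
  if (length(overlaps) == 0) stop("no known-origin birds to score")
  100 * sum(overlaps) / length(overlaps)
}

#' Residency / dispersal summary over a cohort
#'
#' Applies [classifyResidency()] to every surface of a cohort and appends
#' cohort-level counts: number and percentage of residents, and the range of
#' immigrant minimum dispersal distances.
#'
#' @param surfaces list of [BinarySurface-class] objects.
#' @param captureArea polygon matrix (columns `x`, `y`).
#' @param breedingPoint optional shared breeding point.
#' @return data.frame of per-individual calls with attribute `"summary"`.
#' @export
residencySummary <- function(surfaces, captureArea, breedingPoint = NULL) {
  calls <- do.call(rbind, lapply(surfaces, classifyResidency,
                                 captureArea = captureArea,
                                 breedingPoint = breedingPoint))
  imm <- calls$min_dispersal_km[!calls$resident]
  attr(calls, "summary") <- list(
    n = nrow(calls), nResident = sum(calls$resident),
    pctResident = 100 * mean(calls$resident),
    immigrantRange = if (length(imm)) range(imm) else c(NA_real_, NA_real_),
    nEdge = sum(calls$edge_contact))
  calls
}
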