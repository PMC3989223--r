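#' @include AllGenerics.R
NULL

#' Construct a regular analysis grid
#'
#' Builds a [GridSpec-class] covering the requested extent with square cells.
#' The upper edge is expanded (never shrunk) so the grid covers the whole
#' extent with an integer number of cells.
#'
#' @param xmin,xmax,ymin,ymax extent in projected km.
#' @param cell cell size in km (default 2, the analysis resolution).
#' @return a [GridSpec-class].
#' @examples
#' g <- gridSpec(0, 340, 0, 530, cell = 2)
#' nCells(g)
#' @export
gridSpec <- function(xmin, xmax, ymin, ymax, cell = 2) {
  if (xmax <= xmin || ymax <= ymin)
    stop("extent must be strictly positive in both dimensions")
  new("GridSpec", xmin = as.numeric(xmin), ymin = as.numeric(ymin),
      cell = as.numeric(cell),
      nx = as.integer(ceiling((xmax - xmin) / cell)),
      ny = as.integer(ceiling((ymax - ymin) / cell)))
}

#' @rdname gridOf
#' @export
setMethod("nCells", "GridSpec", function(x) as.integer(x@nx) * as.integer(x@ny))

#' @rdname gridOf
#' @export
setMethod("cellCenters", "GridSpec", function(x) {
  cx <- x@xmin + (seq_len(x@nx) - 0.5) * x@cell
  cy <- x@ymin + (seq_len(x@ny) - 0.5) * x@cell
  data.frame(cell = seq_len(nCells(x)),
             x = rep(cx, times = x@ny),
             y = rep(cy, each = x@nx))
})

# Cell indices are row-major from the lower-left origin (x fastest):
# cell = (row - 1) * nx + col with row 1 the southernmost row. Value
# matrices are stored [row = y, col = x]; gridVec()/gridMat() convert
# between the matrix layout and the row-major cell vector.
gridVec <- function(m) as.vector(t(m))

gridMat <- function(v, grid) matrix(v, grid@ny, grid@nx, byrow = TRUE)

cellXY <- function(grid, cells) {
  row <- (cells - 1L) %/% grid@nx + 1L
  col <- (cells - 1L) %% grid@nx + 1L
  cbind(x = grid@xmin + (col - 0.5) * grid@cell,
        y = grid@ymin + (row - 0.5) * grid@cell)
}

# cell index containing a point (clamped to the grid edge)
cellAt <- function(grid, x, y) {
  col <- pmin(pmax(floor((x - grid@xmin) / grid@cell) + 1, 1), grid@nx)
  row <- pmin(pmax(floor((y - grid@ymin) / grid@cell) + 1, 1), grid@ny)
  as.integer((row - 1) * grid@nx + col)
}

sameGrid <- function(a, b) {
  isTRUE(all.equal(a@xmin, b@xmin)) && isTRUE(all.equal(a@ymin, b@ymin)) &&
    isTRUE(all.equal(a@cell, b@cell)) && a@nx == b@nx && a@ny == b@ny
}

# logical matrix flagging the outermost ring of cells
edgeMask <- function(grid) {
  m <- matrix(FALSE, grid@ny, grid@nx)
  m[1, ] <- TRUE; m[grid@ny, ] <- TRUE
  m[, 1] <- TRUE; m[, grid@nx] <- TRUE
  m
}

#' Bilinear interpolation of a gridded surface
#'
#' Interpolates a cell-registered surface at arbitrary points. Points beyond
#' the outermost cell centers are clamped to the border value (constant
#' extrapolation).
#'
#' @param grid a [GridSpec-class].
#' @param values matrix (`ny` x `nx`) of cell-center values.
#' @param x,y query coordinates, km.
#' @return numeric vector of interpolated values.
#' @export
bilinearInterp <- function(grid, values, x, y) {
  fx <- (x - grid@xmin) / grid@cell - 0.5
  fy <- (y - grid@ymin) / grid@cell - 0.5
  c0 <- pmin(pmax(floor(fx), 0), grid@nx - 1)
  r0 <- pmin(pmax(floor(fy), 0), grid@ny - 1)
  c1 <- pmin(c0 + 1, grid@nx - 1)
  r1 <- pmin(r0 + 1, grid@ny - 1)
  tx <- pmin(pmax(fx - c0, 0), 1)
  ty <- pmin(pmax(fy - r0, 0), 1)
  idx <- function(r, c) values[cbind(r + 1, c + 1)]
  (1 - tx) * (1 - ty) * idx(r0, c0) + tx * (1 - ty) * idx(r0, c1) +
    (1 - tx) * ty * idx(r1, c0) + tx * ty * idx(r1, c1)
}
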