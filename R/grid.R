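#' Regular raster grid
#'
#' Light-weight container for a regular, square-celled raster. All grids in a
#' run share one planar frame: cell `(r, c)` (1-based, row 1 at the top) has
#' its center at `x = (c - 0.5) * cell_size_km`, `y = (r - 0.5) * cell_size_km`
#' with `y` increasing downward. `NA` cells are barriers (non-traversable).
#'
#' @param values numeric matrix of cell values; `NA` marks barrier cells.
#' @param cell_size_km positive cell edge length in km.
#' @return an object of class `corridor_grid`.
#' @export
corridor_grid <- function(values, cell_size_km = 1) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      is.na(cell_size_km) || cell_size_km <= 0)
    stop("`cell_size_km` must be a positive number")
  structure(list(values = values, cell_size_km = cell_size_km),
            class = "corridor_grid")
}

#' Binary anthropogenic land-conversion grid
#'
#' A raster in which each cell is 0 (natural land cover) or 1 (converted to
#' human land cover: cropland, settlement, built-up). This is the sole
#' landscape input the corridor models consume.
#'
#' @inheritParams corridor_grid
#' @return an object of class `conversion_grid` (also a `corridor_grid`).
#' @export
conversion_grid <- function(values, cell_size_km = 1) {
  g <- corridor_grid(values, cell_size_km)
  v <- g$values[!is.na(g$values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("conversion grid must be strictly binary (0 = natural, 1 = converted)")
  class(g) <- c("conversion_grid", class(g))
  g
}

#' @export
print.corridor_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %d x %d cells, %.3g km cells", class(x)[1],
              nrow(v), ncol(v), x$cell_size_km))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf(", range [%.4g, %.4g]", min(fin), max(fin)))
  cat(sprintf(", %d barrier cells\n", sum(is.na(v))))
  invisible(x)
}

#' @export
dim.corridor_grid <- function(x) dim(x$values)

grid_shape_check <- function(a, b, what_a = "grid", what_b = "grid") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("shape mismatch: %s is %dx%d but %s is %dx%d",
                 what_a, nrow(a$values), ncol(a$values),
                 what_b, nrow(b$values), ncol(b$values)))
  if (!isTRUE(all.equal(a$cell_size_km, b$cell_size_km)))
    stop(sprintf("cell size mismatch between %s and %s", what_a, what_b))
  invisible(TRUE)
}

#' Cell centers of a grid
#'
#' @param grid a `corridor_grid`.
#' @return a two-column matrix (x, y) of all cell centers in column-major
#'   (R linear index) order.
#' @keywords internal
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size_km
  r <- rep(seq_len(nr), times = nc)
  c <- rep(seq_len(nc), each = nr)
  cbind(x = (c - 0.5) * cs, y = (r - 0.5) * cs)
}
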