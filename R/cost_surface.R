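#' Cost (resistance) surface
#'
#' Per-cell traversal cost for wildlife movement. Natural cells cost 1 to
#' cross; cells influenced by anthropogenic conversion cost up to
#' `base_cost`. `NA` cells are hard barriers (large water bodies) excluded
#' from all traversal and from focal-mean windows.
#'
#' @param values numeric matrix in `[1, base_cost]`, `NA` = barrier.
#' @param base_cost cost assigned to a fully converted cell: 10, 100 or 1000.
#' @param neighborhood focal-mean window edge applied to this surface:
#'   1 (unsmoothed), 3, 5, 7 or 9.
#' @param cell_size_km positive cell size in km.
#' @param water_mask_applied whether a water mask has been applied.
#' @return an object of class `cost_surface` (also a `corridor_grid`).
#' @export
cost_surface <- function(values, base_cost, neighborhood = 1,
                         cell_size_km = 1, water_mask_applied = FALSE) {
  g <- corridor_grid(values, cell_size_km)
  fin <- values[!is.na(values)]
  if (length(fin) && (min(fin) < 1 - 1e-9 || max(fin) > base_cost + 1e-9))
    stop("cost surface values must lie in [1, base_cost]")
  g$base_cost <- base_cost
  g$neighborhood <- neighborhood
  g$water_mask_applied <- water_mask_applied
  class(g) <- c("cost_surface", class(g))
  g
}

#' Assign base traversal costs to a conversion grid
#'
#' Natural cells (0) receive cost 1; converted cells (1) receive
#' `base_cost`. The three base costs encode alternative assumptions about
#' how strongly converted land resists large-mammal movement.
#'
#' @param conv a [conversion_grid()].
#' @param base_cost 10, 100 or 1000.
#' @return an unsmoothed [cost_surface()] (`neighborhood = 1`).
#' @export
assign_base_costs <- function(conv, base_cost) {
  if (!inherits(conv, "conversion_grid"))
    conv <- conversion_grid(conv$values, conv$cell_size_km)  # re-validate
  if (!base_cost %in% c(10, 100, 1000))
    stop("`base_cost` must be one of 10, 100, 1000")
  v <- conv$values
  out <- ifelse(v == 1, base_cost, 1)
  out[is.na(v)] <- NA
  cost_surface(out, base_cost = base_cost, neighborhood = 1,
               cell_size_km = conv$cell_size_km)
}

# Accumulate k x k window sums by offset shifting; NA cells contribute
# neither value nor count. Returns list(sum, count).
window_sums <- function(v, k) {
  h <- (k - 1) / 2
  nr <- nrow(v); nc <- ncol(v)
  val <- ifelse(is.na(v), 0, v)
  cnt0 <- !is.na(v)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (dr in -h:h) {
    tr <- max(1, 1 - dr):min(nr, nr - dr)   # target rows
    sr <- tr + dr                            # source rows
    for (dc in -h:h) {
      tc <- max(1, 1 - dc):min(nc, nc - dc)
      sc <- tc + dc
      acc[tr, tc] <- acc[tr, tc] + val[sr, sc]
      cnt[tr, tc] <- cnt[tr, tc] + cnt0[sr, sc]
    }
  }
  list(sum = acc, count = cnt)
}

#' Focal mean of a cost surface
#'
#' Replaces each cell by the arithmetic mean of its `k` x `k` neighborhood,
#' spreading the cost of converted cells into the natural cells around them.
#' At grid edges the mean is taken over in-bounds cells only, and barrier
#' cells are excluded from windows entirely (they receive no value and
#' contribute none), so the output range stays within `[1, base_cost]`.
#'
#' @param surface an unsmoothed [cost_surface()].
#' @param k odd window edge length: 3, 5, 7 or 9.
#' @return a [cost_surface()] with `neighborhood = k`.
#' @export
focal_mean <- function(surface, k) {
  if (!inherits(surface, "cost_surface")) stop("`surface` must be a cost_surface")
  if (length(k) != 1 || is.na(k) || k < 3 || k %% 2 == 0)
    stop("`k` must be an odd integer >= 3")
  if (surface$neighborhood != 1)
    stop("focal_mean expects an unsmoothed (neighborhood = 1) surface")
  v <- surface$values
  ws <- window_sums(v, k)
  out <- ws$sum / ws$count
  out[is.na(v)] <- NA
  cost_surface(out, base_cost = surface$base_cost, neighborhood = k,
               cell_size_km = surface$cell_size_km,
               water_mask_applied = surface$water_mask_applied)
}

#' Build the factorial cost-surface set
#'
#' The full design crosses base costs \{10, 100, 1000\} with neighborhoods
#' \{1 (none), 3, 5, 7, 9\}: 3 unsmoothed surfaces plus 12 focal-mean
#' surfaces, 15 in all, spanning the uncertainty about both the magnitude
#' and the spatial scale of the impact of conversion on movement.
#'
#' @param conv a [conversion_grid()].
#' @param base_costs base costs to include.
#' @param neighborhoods focal window edges to include (1 = unsmoothed).
#' @param water_mask optional binary [corridor_grid()]; masked cells become
#'   barriers on every surface (see [apply_water_mask()]).
#' @return a list of [cost_surface()] objects named `"b<base>_k<nbhd>"`.
#' @export
build_cost_surface_set <- function(conv, base_costs = c(10, 100, 1000),
                                   neighborhoods = c(1, 3, 5, 7, 9),
                                   water_mask = NULL) {
  out <- list()
  for (b in base_costs) {
    base <- assign_base_costs(conv, b)
    for (k in neighborhoods) {
      s <- if (k == 1) base else focal_mean(base, k)
      if (!is.null(water_mask)) s <- apply_water_mask(s, water_mask)
      out[[sprintf("b%d_k%d", b, k)]] <- s
    }
  }
  out
}

#' The factorial corridor-model grid
#'
#' One row per candidate corridor model: a cost surface (base cost x
#' neighborhood) mapped at one corridor width. The default design yields
#' 15 surfaces x 4 widths = 60 models.
#'
#' @inheritParams build_cost_surface_set
#' @param widths corridor widths as "lowest percent of cost cells".
#' @return a data.frame with columns `base_cost`, `neighborhood`,
#'   `width_percent`, `surface` (the surface-set name).
#' @export
model_param_grid <- function(base_costs = c(10, 100, 1000),
                             neighborhoods = c(1, 3, 5, 7, 9),
                             widths = c(5, 10, 15, 20)) {
  g <- expand.grid(width_percent = widths, neighborhood = neighborhoods,
                   base_cost = base_costs)
  g <- g[c("base_cost", "neighborhood", "width_percent")]
  g$surface <- sprintf("b%d_k%d", g$base_cost, g$neighborhood)
  g
}

#' Mask water bodies out of a cost surface
#'
#' Large inland water bodies are barriers to large-mammal movement, not
#' resistances: masked cells become `NA` (non-traversable) rather than
#' high-cost, and take precedence over any conversion cost.
#'
#' @param surface a [cost_surface()].
#' @param water_mask binary [corridor_grid()] of the same shape
#'   (1 = water).
#' @return the masked [cost_surface()].
#' @export
apply_water_mask <- function(surface, water_mask) {
  grid_shape_check(surface, water_mask, "cost surface", "water mask")
  w <- water_mask$values
  if (!all(w[!is.na(w)] %in% c(0, 1))) stop("water mask must be binary")
  v <- surface$values
  v[!is.na(w) & w == 1] <- NA
  cost_surface(v, base_cost = surface$base_cost,
               neighborhood = surface$neighborhood,
               cell_size_km = surface$cell_size_km,
               water_mask_applied = TRUE)
}

#' Project near-future land conversion
#'
#' Applies a focal maximum over a 3 x 3 neighborhood: every natural cell
#' adjacent (including diagonally) to a converted cell is reclassified as
#' converted, the precautionary assumption that land nearest existing
#' conversion is the most likely to be converted next.
#'
#' @param conv a [conversion_grid()].
#' @return a [conversion_grid()] whose converted set is a superset of the
#'   input's.
#' @export
project_future_conversion <- function(conv) {
  if (!inherits(conv, "conversion_grid"))
    conv <- conversion_grid(conv$values, conv$cell_size_km)
  v <- conv$values
  nr <- nrow(v); nc <- ncol(v)
  vz <- ifelse(is.na(v), 0, v)
  out <- matrix(0, nr, nc)
  for (dr in -1:1) {
    tr <- max(1, 1 - dr):min(nr, nr - dr); sr <- tr + dr
    for (dc in -1:1) {
      tc <- max(1, 1 - dc):min(nc, nc - dc); sc <- tc + dc
      out[tr, tc] <- pmax(out[tr, tc], vz[sr, sc])
    }
  }
  out[is.na(v)] <- NA
  conversion_grid(out, cell_size_km = conv$cell_size_km)
}
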