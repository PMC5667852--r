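#' Rasterize a protected-area polygon to source cells
#'
#' A cell belongs to the source set when its center falls inside the
#' polygon.
#'
#' @param poly polygon vertex matrix (x, y in km) or a single-row
#'   [pa_table()] subset.
#' @param grid any [corridor_grid()] defining the frame.
#' @return integer vector of 1-based column-major cell indices.
#' @export
rasterize_sources <- function(poly, grid) {
  if (inherits(poly, "pa_table")) {
    if (nrow(poly) != 1) stop("pass a single protected area")
    poly <- poly$geometry[[1]]
  }
  ctr <- cell_centers(grid)
  inside <- mgcv::in.out(poly, ctr)
  cells <- which(inside)
  if (!length(cells))
    stop("polygon covers no cell center on this grid")
  cells
}

#' Cost-weighted distance field
#'
#' Multi-source shortest-path (Dijkstra) distance on the 8-connected grid
#' graph. The link cost between adjacent cells i and j is
#' `((v_i + v_j) / 2) * d_ij` with `d_ij` equal to the cell size for rook
#' moves and `sqrt(2)` times it for diagonal moves, so accumulated values
#' are in weighted km. Source cells have distance 0; cells cut off by
#' barriers are `Inf`. Diagonal moves may not slip between two barrier
#' cells that share only a corner.
#'
#' @param surface a [cost_surface()].
#' @param sources integer cell indices (1-based, column-major) or a logical
#'   matrix mask.
#' @return an object of class `cwd_field`: list with `dist` (matrix, weighted
#'   km), `pred` (predecessor linear index matrix, `NA` at sources and
#'   unreachable cells), `sources`, `cell_size_km`.
#' @export
cost_distance <- function(surface, sources) {
  if (!inherits(surface, "cost_surface")) stop("`surface` must be a cost_surface")
  if (is.matrix(sources) && is.logical(sources)) sources <- which(sources)
  sources <- as.integer(sources)
  n <- length(surface$values)
  if (!length(sources)) stop("empty source set")
  if (any(sources < 1 | sources > n)) stop("source index out of range")
  if (all(is.na(surface$values[sources])))
    stop("all source cells lie on barriers")
  res <- grid_cost_distance(surface$values, sources - 1L, surface$cell_size_km)
  pred <- res$pred
  pred[pred < 0] <- NA_integer_
  pred[pred >= 0 & !is.na(pred)] <- pred[pred >= 0 & !is.na(pred)] + 1L
  structure(list(dist = res$dist, pred = pred, sources = sources,
                 cell_size_km = surface$cell_size_km),
            class = "cwd_field")
}

#' Least-cost path by predecessor backtracking
#'
#' Traces the single cell-wide least-cost path from a destination cell set
#' back to the source set of a cost-weighted distance field. The
#' destination cell chosen is the one with the smallest accumulated
#' distance, so the path cost equals `min(cwd$dist[destination])`.
#'
#' @param cwd a [cost_distance()] field.
#' @param destination integer cell indices or logical mask.
#' @return a list: `cells` (linear indices, source end first), `lcp_km`
#'   (geometric path length in km), `cost` (accumulated weighted km),
#'   `connected` (FALSE when the destination is unreachable; `cells` is then
#'   empty and `cost` is `Inf`).
#' @export
least_cost_path <- function(cwd, destination) {
  if (is.matrix(destination) && is.logical(destination))
    destination <- which(destination)
  destination <- as.integer(destination)
  if (!length(destination)) stop("empty destination set")
  d <- cwd$dist[destination]
  if (all(!is.finite(d)))
    return(list(cells = integer(0), lcp_km = Inf, cost = Inf,
                connected = FALSE))
  dest <- destination[which.min(d)]
  nr <- nrow(cwd$dist)
  cells <- integer(0)
  cur <- dest
  repeat {
    cells <- c(cells, cur)
    nxt <- cwd$pred[cur]
    if (is.na(nxt)) break
    cur <- nxt
  }
  cells <- rev(cells)  # source end first
  if (length(cells) > 1) {
    r <- (cells - 1L) %% nr; c <- (cells - 1L) %/% nr
    step <- sqrt(diff(r)^2 + diff(c)^2) * cwd$cell_size_km
    lcp <- sum(step)
  } else lcp <- 0
  list(cells = cells, lcp_km = lcp, cost = cwd$dist[dest], connected = TRUE)
}

#' Normalized corridor raster for a pair of source sets
#'
#' Per cell, the sum of the cost-weighted distances to both protected areas
#' minus the least-cost-path cost, i.e. the extra weighted km incurred by
#' routing through that cell. Cells on a least-cost path score exactly 0.
#'
#' @param cwd_a,cwd_b [cost_distance()] fields over the same surface.
#' @return a [corridor_grid()]; all-`Inf` when the pair is disconnected.
#' @export
corridor_raster <- function(cwd_a, cwd_b) {
  if (!identical(dim(cwd_a$dist), dim(cwd_b$dist)))
    stop("cost-distance fields have mismatched shapes")
  tot <- cwd_a$dist + cwd_b$dist
  fin <- tot[is.finite(tot)]
  if (length(fin)) tot <- tot - min(fin)
  corridor_grid(tot, cell_size_km = cwd_a$cell_size_km)
}

#' Slice the lowest-cost cells of a corridor raster
#'
#' Selects the lowest `width_percent` of corridor cells. Under the default
#' `"cellcount"` rule the cutoff is the `width_percent` cell-count quantile
#' of the finite corridor values (ties at the cutoff included), so for 100
#' finite cells at width 10 exactly the 10 cheapest cells (plus ties) are
#' kept. The alternative `"cwd_cutoff"` rule keeps cells whose detour is
#' within `width_percent` percent of the least-cost-path cost.
#' Least-cost-path cells (value 0) are always included.
#'
#' @param corridor a [corridor_raster()] output.
#' @param width_percent one of 5, 10, 15, 20 (other positive values allowed).
#' @param method `"cellcount"` (default) or `"cwd_cutoff"`.
#' @param lcp_cost least-cost-path cost in weighted km; required for
#'   `"cwd_cutoff"`.
#' @return a logical matrix mask of selected cells (empty when the corridor
#'   is entirely infinite).
#' @export
slice_corridor <- function(corridor, width_percent,
                           method = c("cellcount", "cwd_cutoff"),
                           lcp_cost = NULL) {
  method <- match.arg(method)
  if (width_percent <= 0) stop("`width_percent` must be positive")
  v <- corridor$values
  fin <- is.finite(v)
  if (!any(fin)) return(fin)  # all-FALSE mask
  if (method == "cellcount") {
    vals <- sort(v[fin])
    k <- ceiling(width_percent / 100 * length(vals))
    cutoff <- vals[k]
  } else {
    if (is.null(lcp_cost)) stop("`lcp_cost` required for method = 'cwd_cutoff'")
    cutoff <- width_percent / 100 * lcp_cost
  }
  fin & v <= cutoff
}

result_fields <- c("pa_a", "pa_b", "cwd_weighted_km", "euclidean_km",
                   "lcp_km", "cwd_to_eud_ratio", "cwd_to_lcp_ratio",
                   "crosses_converted", "crosses_future_converted",
                   "intersects_third_pa", "natural_barrier", "status")

#' Corridor metrics for one protected-area pair
#'
#' Runs the full per-pair corridor computation on one cost surface:
#' cost-weighted distance (CWD, the minimum over cells of the sum of the
#' two distance fields), edge-to-edge Euclidean distance, least-cost-path
#' length, their ratios, percentile-sliced corridors at each width, and the
#' crossing flags used downstream. Contiguous pairs (positive shared
#' border) cannot be modeled and are returned with status `"contiguous"`
#' and `NA` metrics.
#'
#' @param pa_a,pa_b protected-area ids.
#' @param pas a [pa_table()].
#' @param surface the [cost_surface()] to model on.
#' @param conv the current [conversion_grid()] (for the converted-crossing
#'   flag); `NULL` skips the flag.
#' @param future_conv projected conversion grid from
#'   [project_future_conversion()]; `NULL` skips the flag.
#' @param widths corridor widths (percent) at which to slice.
#' @param width_percent the working width whose slice drives the third-PA
#'   intersection flag.
#' @param crossing whether "crossing converted land" is judged on the
#'   single-cell least-cost path (`"lcp"`, default) or on any cell of the
#'   working-width corridor slice (`"corridor"`).
#' @param slice_method passed to [slice_corridor()].
#' @return an object of class `corridor_result`: named list of scalar
#'   metrics plus `sliced` (named list of logical masks per width), `path`
#'   (least-cost-path cells) and `corridor` (the normalized corridor grid).
#' @export
pair_metrics <- function(pa_a, pa_b, pas, surface, conv = NULL,
                         future_conv = NULL, widths = c(5, 10, 15, 20),
                         width_percent = 10,
                         crossing = c("lcp", "corridor"),
                         slice_method = "cellcount") {
  crossing <- match.arg(crossing)
  if (identical(pa_a, pa_b)) stop("`pa_a` and `pa_b` must differ")
  ia <- match(pa_a, pas$id); ib <- match(pa_b, pas$id)
  if (is.na(ia) || is.na(ib)) stop("unknown protected-area id")
  ga <- pas$geometry[[ia]]; gb <- pas$geometry[[ib]]

  res <- list(pa_a = pa_a, pa_b = pa_b, cwd_weighted_km = NA_real_,
              euclidean_km = polygon_distance(ga, gb), lcp_km = NA_real_,
              cwd_to_eud_ratio = NA_real_, cwd_to_lcp_ratio = NA_real_,
              crosses_converted = NA, crosses_future_converted = NA,
              intersects_third_pa = NA, natural_barrier = NA,
              status = NA_character_, width_percent = width_percent,
              sliced = NULL, path = integer(0), corridor = NULL)
  class(res) <- "corridor_result"

  if (shared_border_length(ga, gb) > 0) {
    res$status <- "contiguous"
    return(res)
  }

  src_a <- rasterize_sources(ga, surface)
  src_b <- rasterize_sources(gb, surface)
  cwd_a <- cost_distance(surface, src_a)
  cwd_b <- cost_distance(surface, src_b)
  lcp <- least_cost_path(cwd_a, src_b)
  corr <- corridor_raster(cwd_a, cwd_b)

  res$cwd_weighted_km <- lcp$cost
  res$lcp_km <- lcp$lcp_km
  res$path <- lcp$cells
  res$corridor <- corr
  if (!lcp$connected) {
    res$status <- "unclassified"
    res$sliced <- stats::setNames(
      lapply(widths, function(w) slice_corridor(corr, w, slice_method)),
      paste0("w", widths))
    return(res)
  }
  res$cwd_to_eud_ratio <- if (res$euclidean_km > 0)
    res$cwd_weighted_km / res$euclidean_km else NA_real_
  res$cwd_to_lcp_ratio <- if (res$lcp_km > 0)
    res$cwd_weighted_km / res$lcp_km else NA_real_

  res$sliced <- stats::setNames(
    lapply(widths, function(w)
      slice_corridor(corr, w, slice_method, lcp_cost = lcp$cost)),
    paste0("w", widths))
  working <- res$sliced[[paste0("w", width_percent)]]
  if (is.null(working))
    working <- slice_corridor(corr, width_percent, slice_method,
                              lcp_cost = lcp$cost)

  crossing_cells <- if (crossing == "lcp") lcp$cells else which(working)
  if (!is.null(conv)) {
    cv <- conv$values[crossing_cells]
    res$crosses_converted <- any(cv == 1, na.rm = TRUE)
  }
  if (!is.null(future_conv)) {
    fv <- future_conv$values[crossing_cells]
    res$crosses_future_converted <- any(fv == 1, na.rm = TRUE)
  }

  # third-PA test: the working-width corridor against every other area
  others <- setdiff(seq_len(nrow(pas)), c(ia, ib))
  hit <- FALSE
  for (j in others) {
    cells_j <- tryCatch(rasterize_sources(pas$geometry[[j]], surface),
                        error = function(e) integer(0))
    if (length(cells_j) && any(working[cells_j])) { hit <- TRUE; break }
  }
  res$intersects_third_pa <- hit
  res$status <- "unclassified"
  res
}

#' @export
print.corridor_result <- function(x, ...) {
  cat(sprintf("<corridor_result> %s -- %s: status %s\n", x$pa_a, x$pa_b,
              x$status))
  if (is.finite(x$cwd_weighted_km %||% NA))
    cat(sprintf("  CWD %.1f weighted km | EuD %.1f km | LCP %.1f km\n",
                x$cwd_weighted_km, x$euclidean_km, x$lcp_km))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten corridor results to a table
#'
#' @param results list of [pair_metrics()] results.
#' @return a data.frame mirroring the corridor summary table: one row per
#'   pair with CWD, EuD, LCP, ratios, flags and status.
#' @export
corridor_table <- function(results) {
  rows <- lapply(results, function(r) {
    out <- r[setdiff(result_fields, character(0))]
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
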