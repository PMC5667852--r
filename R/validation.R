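#' Score a corridor cell set against labeled validation locations
#'
#' A location is *captured* when any selected corridor cell center lies
#' within `buffer_radius_km` of its point (the circle-point test; at 5 km
#' buffers over ~1 km cells this is equivalent, to sub-cell precision, to
#' intersecting the buffer circle with the corridor footprint). Captured
#' movement locations are true positives, uncaptured ones false negatives;
#' captured no-movement locations are false positives, uncaptured ones
#' true negatives.
#'
#' @param cells logical corridor mask (as from [slice_corridor()]) or
#'   integer cell indices.
#' @param locations data.frame with `x`, `y` (km) and
#'   `label` in `{"movement", "none"}`.
#' @param grid a [corridor_grid()] defining the frame.
#' @param buffer_radius_km capture radius in km.
#' @return a one-row data.frame `tp`, `fp`, `fn`, `tn`, `n` (class
#'   `confusion_matrix`).
#' @export
score_locations <- function(cells, locations, grid, buffer_radius_km = 5) {
  if (!nrow(locations)) stop("no validation locations supplied")
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size_km
  if (any(locations$x < 0 | locations$x > nc * cs |
          locations$y < 0 | locations$y > nr * cs))
    stop("validation location outside the grid extent")
  mask <- if (is.matrix(cells) && is.logical(cells)) cells else {
    m <- matrix(FALSE, nr, nc); m[as.integer(cells)] <- TRUE; m
  }
  captured <- vapply(seq_len(nrow(locations)), function(i) {
    x <- locations$x[i]; y <- locations$y[i]
    # candidate cells: the bounding box of the buffer disc
    r1 <- max(1, floor((y - buffer_radius_km) / cs + 0.5))
    r2 <- min(nr, ceiling((y + buffer_radius_km) / cs + 0.5))
    c1 <- max(1, floor((x - buffer_radius_km) / cs + 0.5))
    c2 <- min(nc, ceiling((x + buffer_radius_km) / cs + 0.5))
    if (r1 > r2 || c1 > c2) return(FALSE)
    sub <- mask[r1:r2, c1:c2, drop = FALSE]
    if (!any(sub)) return(FALSE)
    hit <- which(sub, arr.ind = TRUE)
    cx <- (c1 + hit[, 2] - 1.5) * cs
    cy <- (r1 + hit[, 1] - 1.5) * cs
    any((cx - x)^2 + (cy - y)^2 <= buffer_radius_km^2)
  }, logical(1))
  mv <- locations$label == "movement"
  out <- data.frame(tp = sum(captured & mv), fp = sum(captured & !mv),
                    fn = sum(!captured & mv), tn = sum(!captured & !mv))
  out$n <- out$tp + out$fp + out$fn + out$tn
  class(out) <- c("confusion_matrix", "data.frame")
  out
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement between model-predicted corridor presence
#' and reported wildlife movement:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (tp + tn) / n` and chance agreement
#' `p_e = ((tp + fp)(tp + fn) + (fn + tn)(fp + tn)) / n^2`.
#' The degenerate all-one-class case (`p_e = 1`, `p_o = 1`) returns 0.
#'
#' @param tp,fp,fn,tn cell counts, or a `confusion_matrix` as first
#'   argument.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (inherits(tp, "confusion_matrix") ||
      (is.data.frame(tp) && all(c("tp", "fp", "fn", "tn") %in% names(tp)))) {
    m <- tp; tp <- m$tp; fp <- m$fp; fn <- m$fn; tn <- m$tn
  }
  n <- tp + fp + fn + tn
  if (n == 0) stop("empty confusion matrix")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Score the factorial corridor models against validation locations
#'
#' For each model (cost surface x corridor width), takes the union of the
#' sliced corridor cells across all scored pairs, scores it against the
#' locations and computes Cohen's kappa and the corridor footprint size.
#'
#' @param results_by_surface named list (one entry per surface name) of
#'   lists of [pair_metrics()] results.
#' @param params a [model_param_grid()] data.frame.
#' @param locations validation locations (see [score_locations()]).
#' @param grid frame-defining [corridor_grid()].
#' @param buffer_radius_km capture radius.
#' @return `params` with appended columns `tp`, `fp`, `fn`, `tn`, `kappa`,
#'   `cells`.
#' @export
score_models <- function(results_by_surface, params, locations, grid,
                         buffer_radius_km = 5) {
  scores <- params
  scores$tp <- scores$fp <- scores$fn <- scores$tn <- NA_integer_
  scores$kappa <- NA_real_
  scores$cells <- NA_integer_
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  for (i in seq_len(nrow(params))) {
    sname <- params$surface[i]
    w <- params$width_percent[i]
    res_list <- results_by_surface[[sname]]
    if (is.null(res_list)) stop("no corridor results for surface ", sname)
    mask <- matrix(FALSE, nr, nc)
    for (r in res_list) {
      s <- r$sliced[[paste0("w", w)]]
      if (!is.null(s)) mask <- mask | s
    }
    cm <- score_locations(mask, locations, grid, buffer_radius_km)
    scores$tp[i] <- cm$tp; scores$fp[i] <- cm$fp
    scores$fn[i] <- cm$fn; scores$tn[i] <- cm$tn
    scores$kappa[i] <- cohen_kappa(cm)
    scores$cells[i] <- sum(mask)
  }
  scores
}

#' Select the best corridor model: highest kappa, fewest cells
#'
#' Among models whose kappa is within `kappa_tolerance` of the maximum,
#' returns the one with the smallest corridor footprint — the
#' kappa-and-parsimony rule under which a model with a slightly lower
#' kappa but a one-third smaller footprint beats the top-kappa model.
#' Remaining ties break by higher kappa, then smaller neighborhood, then
#' lower base cost, then smaller width.
#'
#' @param scores a [score_models()] data.frame (needs `kappa` and `cells`).
#' @param kappa_tolerance admissible drop below the maximum kappa.
#' @return the selected row of `scores`.
#' @export
select_best_model <- function(scores, kappa_tolerance = 0.05) {
  if (!nrow(scores)) stop("no model scores supplied")
  ok <- scores[scores$kappa >= max(scores$kappa) - kappa_tolerance, ,
               drop = FALSE]
  ord <- order(ok$cells, -ok$kappa, ok$neighborhood, ok$base_cost,
               ok$width_percent)
  ok[ord[1], , drop = FALSE]
}
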