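third_pa_flag <- function(sliced, pas, ia, ib, grid) {
  others <- setdiff(seq_len(nrow(pas)), c(ia, ib))
  for (j in others) {
    cells_j <- tryCatch(rasterize_sources(pas$geometry[[j]], grid),
                        error = function(e) integer(0))
    if (length(cells_j) && any(sliced[cells_j])) return(TRUE)
  }
  FALSE
}

#' Run the full structural-connectivity pipeline
#'
#' Executes the whole assessment on one landscape: build the factorial
#' cost-surface set, model least-cost corridors between protected-area
#' pairs on every surface, score all corridor models against the
#' validation locations, pick the best model by the kappa-and-parsimony
#' rule, derive the open/severed threshold from the reference pair,
#' classify every corridor (with converted-crossing, future-conversion,
#' third-area and natural-barrier flags), and assemble the corridor
#' network with complexes, isolated reserves and stepping-stones.
#'
#' @param config a named list (see [read_run_config()] for the YAML form):
#' \describe{
#'   \item{bundle / spec / paths}{the landscape: either a
#'     [generate_landscape()] bundle (`bundle`), a [landscape_spec()]
#'     (`spec`), or file paths `conversion`, `pas`, `points` and optional
#'     `water`, `dem`, `wetland`.}
#'   \item{base_costs, neighborhoods, widths}{the factorial design;
#'     defaults \{10, 100, 1000\} x \{1, 3, 5, 7, 9\} x \{5, 10, 15, 20\}
#'     give the 60-model grid.}
#'   \item{buffer_radius_km}{validation capture radius, default 5.}
#'   \item{kappa_tolerance}{model-selection tolerance, default 0.05.}
#'   \item{slope_threshold_deg}{natural-barrier slope threshold, default 10.}
#'   \item{reference_pair}{ids `c(a, b)` of the severed reference corridor
#'     whose CWD/EuD calibrate the classification rule.}
#'   \item{pairs}{optional list of id pairs to model; default: all
#'     unordered protected-area pairs.}
#'   \item{crossing, slice_method}{see [pair_metrics()] and
#'     [slice_corridor()].}
#'   \item{out_dir}{optional directory; when set, all tables are written
#'     as CSV alongside a plain-text run log.}
#'   \item{seed}{RNG seed used when `spec` is generated here.}
#' }
#' @return a list: `bundle`, `scores` (60-model table), `best` (selected
#'   model row), `rule`, `table` (classified corridor table), `complexes`,
#'   `network`, `isolated`, `stepping_stones`, `future_conversion`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  base_costs <- cfg$base_costs %||% c(10, 100, 1000)
  neighborhoods <- cfg$neighborhoods %||% c(1, 3, 5, 7, 9)
  widths <- cfg$widths %||% c(5, 10, 15, 20)
  buffer <- cfg$buffer_radius_km %||% 5
  tol <- cfg$kappa_tolerance %||% 0.05
  slope_thr <- cfg$slope_threshold_deg %||% 10
  crossing <- cfg$crossing %||% "lcp"
  slice_method <- cfg$slice_method %||% "cellcount"

  # --- stage: inputs -------------------------------------------------------
  bundle <- cfg$bundle
  if (is.null(bundle) && !is.null(cfg$spec))
    bundle <- generate_landscape(cfg$spec)
  if (is.null(bundle)) {
    if (is.null(cfg$conversion) || is.null(cfg$pas) || is.null(cfg$points))
      stop("stage inputs: need `bundle`, `spec`, or paths ",
           "`conversion` + `pas` + `points`")
    conv <- read_ascii_grid(cfg$conversion)
    bundle <- list(
      conversion = conversion_grid(conv$values, conv$cell_size_km),
      pas = read_pas_geojson(cfg$pas),
      points = read_validation_points(cfg$points),
      water_mask = if (!is.null(cfg$water)) read_ascii_grid(cfg$water),
      dem = if (!is.null(cfg$dem)) read_ascii_grid(cfg$dem),
      wetland_mask = if (!is.null(cfg$wetland)) read_ascii_grid(cfg$wetland))
  }
  conv <- bundle$conversion
  pas <- bundle$pas
  if (nrow(pas) < 2) stop("stage inputs: need at least two protected areas")
  future <- project_future_conversion(conv)
  slope <- if (!is.null(bundle$dem)) slope_from_dem(bundle$dem)

  pairs <- cfg$pairs
  if (is.null(pairs)) {
    cmb <- utils::combn(pas$id, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }

  # --- stage: cost surfaces ------------------------------------------------
  surfaces <- build_cost_surface_set(conv, base_costs, neighborhoods,
                                     water_mask = bundle$water_mask)

  # --- stage: corridors ----------------------------------------------------
  results_by_surface <- lapply(surfaces, function(s) {
    lapply(pairs, function(p)
      pair_metrics(p[1], p[2], pas, s, conv = conv, future_conv = future,
                   widths = widths, width_percent = widths[1],
                   crossing = crossing, slice_method = slice_method))
  })

  # --- stage: validation / model selection ---------------------------------
  params <- model_param_grid(base_costs, neighborhoods, widths)
  scores <- score_models(results_by_surface, params, bundle$points, conv,
                         buffer_radius_km = buffer)
  best <- select_best_model(scores, kappa_tolerance = tol)
  best_results <- results_by_surface[[best$surface]]
  best_w <- paste0("w", best$width_percent)

  # flags at the selected model's width
  for (i in seq_along(best_results)) {
    r <- best_results[[i]]
    if (!identical(r$status, "contiguous") && !is.null(r$sliced[[best_w]])) {
      sl <- r$sliced[[best_w]]
      ia <- match(r$pa_a, pas$id); ib <- match(r$pa_b, pas$id)
      r$intersects_third_pa <- third_pa_flag(sl, pas, ia, ib, conv)
      r$natural_barrier <- flag_natural_barriers(sl, slope,
                                                 bundle$wetland_mask,
                                                 slope_thr)
      r$width_percent <- best$width_percent
      if (crossing == "corridor") {
        r$crosses_converted <- any(conv$values[which(sl)] == 1, na.rm = TRUE)
        r$crosses_future_converted <-
          any(future$values[which(sl)] == 1, na.rm = TRUE)
      }
      best_results[[i]] <- r
    }
  }

  # --- stage: classification -----------------------------------------------
  ref_ids <- cfg$reference_pair
  if (is.null(ref_ids)) stop("stage classification: `reference_pair` not set")
  ref <- NULL
  for (r in best_results)
    if (setequal(c(r$pa_a, r$pa_b), ref_ids)) ref <- r
  if (is.null(ref))
    stop("stage classification: reference pair not among modeled pairs")
  rule <- derive_rule(ref)

  tab <- corridor_table(best_results)
  classifiable <- tab$status == "unclassified" & is.finite(tab$cwd_weighted_km)
  tab$status[classifiable] <- classify_status(
    tab$cwd_weighted_km[classifiable], tab$euclidean_km[classifiable],
    tab$crosses_converted[classifiable], rule)
  # barrier-disconnected pairs exceed any finite threshold
  tab$status[tab$status == "unclassified"] <- "severed"
  tab$status <- drop_if_third_pa(tab$status, tab$intersects_third_pa)

  # --- stage: network ------------------------------------------------------
  complexes <- build_complexes(pas)
  net <- build_network(complexes, tab, pas)
  corridor_cells <- list()
  for (r in best_results)
    if (!is.null(r$sliced[[best_w]]))
      corridor_cells[[paste(r$pa_a, r$pa_b, sep = "|")]] <- r$sliced[[best_w]]
  stones <- stepping_stones(net, pas, corridor_cells, conv)
  isolated <- isolated_nodes(net)

  out <- list(bundle = bundle, scores = scores, best = best, rule = rule,
              table = tab, complexes = complexes, network = net,
              isolated = isolated, stepping_stones = stones,
              future_conversion = future)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(cfg$out_dir, "model_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(tab, file.path(cfg$out_dir, "corridors_classified.csv"),
                     row.names = FALSE)
    utils::write.csv(net$nodes, file.path(cfg$out_dir, "network_nodes.csv"),
                     row.names = FALSE)
    utils::write.csv(net$edges, file.path(cfg$out_dir, "network_edges.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(cwd_threshold_weighted_km =
                            rule$cwd_threshold_weighted_km,
                          eud_threshold_km = rule$eud_threshold_km,
                          reference_pair = rule$reference_pair),
                     file.path(cfg$out_dir, "rule.yaml"))
    log_lines <- c(
      sprintf("corridornet %s", as.character(utils::packageVersion("corridornet"))),
      sprintf("seed: %s", cfg$seed %||% cfg$spec$seed %||% "NA"),
      sprintf("base_costs: %s", paste(base_costs, collapse = ",")),
      sprintf("neighborhoods: %s", paste(neighborhoods, collapse = ",")),
      sprintf("widths: %s", paste(widths, collapse = ",")),
      sprintf("buffer_radius_km: %g | kappa_tolerance: %g | slope_threshold_deg: %g",
              buffer, tol, slope_thr),
      sprintf("best model: base %d, neighborhood %d, width %d%% (kappa %.3f, %d cells)",
              best$base_cost, best$neighborhood, best$width_percent,
              best$kappa, best$cells),
      sprintf("rule: CWD < %.3f weighted km | EuD > %.3f km exception",
              rule$cwd_threshold_weighted_km, rule$eud_threshold_km))
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  }
  out
}
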