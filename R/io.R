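#' Read a grid from an ESRI ASCII raster file
#'
#' Grids are stored as ESRI ASCII grid (`.asc`), a plain-text raster
#' interchange format readable by every desktop GIS. `NODATA` cells become
#' `NA` (barrier) cells. The `cellsize` header is interpreted in km.
#'
#' @param path path to a `.asc` file.
#' @return a [corridor_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[key]])) stop("missing ASCII grid header field: ", key)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d cell values, found %d", nr * nc, length(vals)))
  if (!is.null(hdr$nodata_value))
    vals[vals == hdr$nodata_value] <- NA
  # .asc streams rows top to bottom
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  corridor_grid(m, cell_size_km = hdr$cellsize)
}

#' Write a grid to an ESRI ASCII raster file
#'
#' @param grid a [corridor_grid()].
#' @param path output path.
#' @param nodata value used to encode `NA` (barrier) cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           "xllcorner 0", sprintf("yllcorner %s",
                                  format(-nr * grid$cell_size_km, digits = 15)),
           sprintf("cellsize %s", format(grid$cell_size_km, digits = 15)),
           sprintf("NODATA_value %s", format(nodata, digits = 15)))
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(x) paste(format(x, digits = 15, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Protection levels recognised for protected areas
#'
#' The first three levels (national parks, nature reserves, game reserves)
#' count as "high protection": only these are merged into complexes and used
#' as corridor-network anchor nodes.
#' @export
protection_levels <- c("national_park", "nature_reserve", "game_reserve",
                       "forest_reserve", "wildlife_management_area",
                       "game_controlled_area", "other")

#' High-protection predicate
#'
#' @param level character vector of protection levels.
#' @return logical: `TRUE` for national parks, nature reserves and game
#'   reserves.
#' @export
is_high_protection <- function(level) {
  level %in% c("national_park", "nature_reserve", "game_reserve")
}

#' Build a protected-area table
#'
#' @param id character vector of unique ids.
#' @param name character vector of display names.
#' @param protection_level character vector drawn from [protection_levels].
#' @param geometry list of two-column (x, y) polygon vertex matrices in km,
#'   in the shared grid frame; rings need not be closed.
#' @return a data.frame with a `geometry` list-column, class `pa_table`.
#' @export
pa_table <- function(id, name, protection_level, geometry) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("protected-area ids must be unique")
  bad <- setdiff(protection_level, protection_levels)
  if (length(bad))
    stop("unknown protection level(s): ", paste(bad, collapse = ", "),
         "; accepted values: ", paste(protection_levels, collapse = ", "))
  if (!is.list(geometry) || length(geometry) != length(id))
    stop("`geometry` must be a list of polygon matrices, one per area")
  for (g in geometry) {
    if (!is.matrix(g) || ncol(g) != 2 || nrow(g) < 3 || anyNA(g))
      stop("each geometry must be a finite two-column matrix with >= 3 vertices")
  }
  out <- data.frame(id = id, name = as.character(name),
                    protection_level = protection_level,
                    stringsAsFactors = FALSE)
  out$geometry <- geometry
  class(out) <- c("pa_table", "data.frame")
  out
}

#' Read protected areas from GeoJSON
#'
#' Expects a FeatureCollection of single-ring Polygon features carrying
#' `id`, `name` and `protection_level` properties.
#'
#' @param path path to a GeoJSON file.
#' @return a [pa_table()].
#' @export
read_pas_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- fc$features
  get_prop <- function(f, key) {
    v <- f$properties[[key]]
    if (is.null(v)) stop("feature missing required property: ", key)
    as.character(v)
  }
  geom <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("x", "y")
    # drop closing vertex if present
    if (nrow(m) > 3 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  })
  pa_table(id = vapply(feats, get_prop, "", key = "id"),
           name = vapply(feats, get_prop, "", key = "name"),
           protection_level = vapply(feats, get_prop, "", key = "protection_level"),
           geometry = geom)
}

#' Write protected areas to GeoJSON
#'
#' @param pas a [pa_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pas_geojson <- function(pas, path) {
  feats <- lapply(seq_len(nrow(pas)), function(i) {
    g <- pas$geometry[[i]]
    ring <- lapply(seq_len(nrow(g)), function(j) c(g[j, 1], g[j, 2]))
    ring[[length(ring) + 1]] <- ring[[1]]  # close the ring
    list(type = "Feature",
         properties = list(id = pas$id[i], name = pas$name[i],
                           protection_level = pas$protection_level[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write validation points
#'
#' Validation points are the movement records used to score corridor models:
#' `x`, `y` in km in the grid frame, `label` either `"movement"` (wildlife
#' reported crossing here) or `"none"` (no known movement).
#'
#' @param path CSV path.
#' @return a data.frame with columns `x`, `y`, `label`.
#' @export
read_validation_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "label")
  if (!all(need %in% names(df)))
    stop("validation point file must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$label), c("movement", "none"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  df[need]
}

#' @rdname read_validation_points
#' @param points a data.frame with columns `x`, `y`, `label`.
#' @export
write_validation_points <- function(points, path) {
  utils::write.csv(points[c("x", "y", "label")], path, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected so that typos fail loudly. See [run_pipeline()]
#' for the meaning and defaults of each field.
#'
#' @param path YAML file path.
#' @return a named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("conversion", "pas", "points", "water", "dem", "wetland",
             "base_costs", "neighborhoods", "widths", "buffer_radius_km",
             "kappa_tolerance", "slope_threshold_deg", "reference_pair",
             "pairs", "crossing", "slice_method", "width_percent",
             "cell_size_km", "seed", "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
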