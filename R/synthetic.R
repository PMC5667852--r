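#' Rectangular protected area for a landscape specification
#'
#' @param id,name,protection_level identity fields; `protection_level` must
#'   be one of [protection_levels].
#' @param rows,cols inclusive 1-based cell ranges `c(first, last)` the
#'   reserve occupies.
#' @return a list describing the reserve, for [landscape_spec()].
#' @export
pa_rect <- function(id, name, protection_level, rows, cols) {
  if (!protection_level %in% protection_levels)
    stop("unknown protection level: ", protection_level)
  if (length(rows) != 2 || length(cols) != 2 || rows[1] > rows[2] ||
      cols[1] > cols[2] || rows[1] < 1 || cols[1] < 1)
    stop("`rows` and `cols` must be increasing positive ranges")
  list(id = as.character(id), name = name,
       protection_level = protection_level,
       rows = as.integer(rows), cols = as.integer(cols))
}

#' Planted link between two protected areas
#'
#' An `open_corridor` link carves an all-natural strip between the pair; a
#' `blocked` link carves the same strip and then lays a converted band
#' across the full grid between the pair, so that every natural route
#' between them is interrupted.
#'
#' @param pa_a,pa_b reserve ids.
#' @param kind `"open_corridor"` or `"blocked"`.
#' @param corridor_width_cells width of the carved natural strip.
#' @param blockage_width_cells thickness of the converted band
#'   (`blocked` links only).
#' @param band_extent optional `c(lo, hi)` range, in cells, limiting how far
#'   the blockage band extends across the landscape (columns for a
#'   vertically separated pair, rows for a horizontal one). By default the
#'   band spans the whole grid; when water barriers already compartmentalize
#'   the landscape the band only needs to reach them.
#' @return a list describing the link, for [landscape_spec()].
#' @export
planted_link <- function(pa_a, pa_b, kind = c("open_corridor", "blocked"),
                         corridor_width_cells = 5, blockage_width_cells = 3,
                         band_extent = NULL) {
  kind <- match.arg(kind)
  list(pa_a = as.character(pa_a), pa_b = as.character(pa_b), kind = kind,
       corridor_width_cells = as.integer(corridor_width_cells),
       blockage_width_cells = as.integer(blockage_width_cells),
       band_extent = if (!is.null(band_extent)) as.integer(band_extent))
}

#' Synthetic landscape specification
#'
#' Describes a seeded synthetic study region: a mostly natural grid with
#' spatially clumped converted patches, rectangular reserves, planted
#' natural corridors and planted converted blockages between reserve
#' pairs, and labeled wildlife-movement points on (positives) and far from
#' (negatives) the planted corridors.
#'
#' @param grid_rows,grid_cols grid dimensions (cells).
#' @param cell_size_km cell size in km.
#' @param conversion_fraction target fraction of *background* cells
#'   (outside reserves and planted structures) that are converted.
#' @param protected_areas list of [pa_rect()] entries.
#' @param planted_links list of [planted_link()] entries.
#' @param n_positive_points,n_negative_points counts of labeled points.
#' @param buffer_radius_km validation buffer radius (km).
#' @param village_spacing_km spacing of the village pairs whose midpoints
#'   define positive points.
#' @param relief optional ridge/wetland description: a list with
#'   `height_km`, `rise` (km of elevation per km of horizontal distance on
#'   the ridge flank), `crest_col`, and optionally `wetland = list(rows,
#'   cols)` for a permanent-wetland rectangle.
#' @param water optional list of open-water rectangles, each a
#'   `list(rows, cols)`, combined into the barrier water mask.
#' @param seed integer RNG seed; fixed seed gives a bit-identical bundle.
#' @return a validated object of class `landscape_spec`.
#' @export
landscape_spec <- function(grid_rows, grid_cols, cell_size_km = 1,
                           conversion_fraction = 0.15,
                           protected_areas = list(),
                           planted_links = list(),
                           n_positive_points = 0, n_negative_points = 0,
                           buffer_radius_km = 5, village_spacing_km = 5,
                           relief = NULL, water = NULL, seed = 1) {
  if (grid_rows < 1 || grid_cols < 1) stop("grid dimensions must be positive")
  if (conversion_fraction < 0 || conversion_fraction > 1)
    stop("`conversion_fraction` must lie in [0, 1]")
  ids <- vapply(protected_areas, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate protected-area ids")
  for (pa in protected_areas) {
    if (pa$rows[2] > grid_rows || pa$cols[2] > grid_cols)
      stop("grid too small to fit protected area '", pa$id, "'")
  }
  # pairwise disjoint interiors (touching borders allowed => contiguous)
  n <- length(protected_areas)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- protected_areas[[i]]; b <- protected_areas[[j]]
      if (a$rows[1] <= b$rows[2] && b$rows[1] <= a$rows[2] &&
          a$cols[1] <= b$cols[2] && b$cols[1] <= a$cols[2])
        stop("protected areas '", a$id, "' and '", b$id, "' overlap")
    }
  }
  for (lk in planted_links) {
    if (!lk$pa_a %in% ids || !lk$pa_b %in% ids)
      stop("planted link references unknown protected area")
    if (lk$pa_a == lk$pa_b) stop("planted link endpoints must differ")
  }
  if (n_positive_points > 0 &&
      !any(vapply(planted_links, `[[`, "", "kind") == "open_corridor"))
    stop("positive points require at least one open planted corridor")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size_km = cell_size_km,
                 conversion_fraction = conversion_fraction,
                 protected_areas = protected_areas,
                 planted_links = planted_links,
                 n_positive_points = as.integer(n_positive_points),
                 n_negative_points = as.integer(n_negative_points),
                 buffer_radius_km = buffer_radius_km,
                 village_spacing_km = village_spacing_km,
                 relief = relief, water = water, seed = as.integer(seed)),
            class = "landscape_spec")
}

rect_polygon <- function(rows, cols, cs) {
  x1 <- (cols[1] - 1) * cs; x2 <- cols[2] * cs
  y1 <- (rows[1] - 1) * cs; y2 <- rows[2] * cs
  m <- cbind(x = c(x1, x2, x2, x1), y = c(y1, y1, y2, y2))
  m
}

# geometry of the carved strip and the blockage band for a link
link_layout <- function(a, b, lk, spec) {
  w <- lk$corridor_width_cells
  if (a$rows[2] < b$rows[1] || b$rows[2] < a$rows[1]) {
    # vertically separated: vertical strip
    if (a$rows[2] >= b$rows[1]) { tmp <- a; a <- b; b <- tmp }
    gap_rows <- c(a$rows[2] + 1, b$rows[1] - 1)
    lo <- max(a$cols[1], b$cols[1]); hi <- min(a$cols[2], b$cols[2])
    if (lo > hi) stop("planted link '", lk$pa_a, "'-'", lk$pa_b,
                      "': reserves share no column range")
    mid <- floor((lo + hi) / 2)
    cols <- c(mid - floor((w - 1) / 2), mid + ceiling((w - 1) / 2))
    band_mid <- floor(mean(gap_rows))
    band <- list(rows = c(band_mid, band_mid + lk$blockage_width_cells - 1),
                 cols = lk$band_extent %||% c(1, spec$grid_cols))
    list(orient = "vertical", corridor = list(rows = gap_rows, cols = cols),
         band = band)
  } else if (a$cols[2] < b$cols[1] || b$cols[2] < a$cols[1]) {
    if (a$cols[2] >= b$cols[1]) { tmp <- a; a <- b; b <- tmp }
    gap_cols <- c(a$cols[2] + 1, b$cols[1] - 1)
    lo <- max(a$rows[1], b$rows[1]); hi <- min(a$rows[2], b$rows[2])
    if (lo > hi) stop("planted link '", lk$pa_a, "'-'", lk$pa_b,
                      "': reserves share no row range")
    mid <- floor((lo + hi) / 2)
    rows <- c(mid - floor((w - 1) / 2), mid + ceiling((w - 1) / 2))
    band_mid <- floor(mean(gap_cols))
    band <- list(rows = lk$band_extent %||% c(1, spec$grid_rows),
                 cols = c(band_mid, band_mid + lk$blockage_width_cells - 1))
    list(orient = "horizontal", corridor = list(rows = rows, cols = gap_cols),
         band = band)
  } else stop("planted link endpoints must be separated in rows or columns")
}

rect_mask <- function(nr, nc, rows, cols) {
  m <- matrix(FALSE, nr, nc)
  m[rows[1]:rows[2], cols[1]:cols[2]] <- TRUE
  m
}

# min distance (km) from points to a cell rectangle (rows, cols)
dist_to_rect <- function(x, y, rows, cols, cs) {
  x1 <- (cols[1] - 1) * cs; x2 <- cols[2] * cs
  y1 <- (rows[1] - 1) * cs; y2 <- rows[2] * cs
  dx <- pmax(0, pmax(x1 - x, x - x2))
  dy <- pmax(0, pmax(y1 - y, y - y2))
  sqrt(dx^2 + dy^2)
}

# grow random-walk blobs over eligible cells until `quota` are converted
grow_conversion_blobs <- function(nr, nc, eligible, quota) {
  conv <- matrix(0, nr, nc)
  if (quota <= 0) return(conv)
  n_converted <- 0
  elig_idx <- which(eligible)
  guard <- 0
  while (n_converted < quota && guard < quota * 200) {
    seed_cell <- elig_idx[sample.int(length(elig_idx), 1)]
    r <- (seed_cell - 1) %% nr + 1; c <- (seed_cell - 1) %/% nr + 1
    target <- sample(15:60, 1)  # blob size, cells
    steps <- 0
    while (target > 0 && n_converted < quota && steps < target * 30) {
      if (eligible[r, c] && conv[r, c] == 0) {
        conv[r, c] <- 1
        n_converted <- n_converted + 1
        target <- target - 1
      }
      mv <- sample.int(4, 1)  # rook random walk keeps blobs compact
      r <- min(nr, max(1, r + c(-1, 1, 0, 0)[mv]))
      c <- min(nc, max(1, c + c(0, 0, -1, 1)[mv]))
      steps <- steps + 1
      guard <- guard + 1
    }
  }
  conv
}

#' Generate a synthetic landscape bundle
#'
#' Produces every input the corridor pipeline needs, with known ground
#' truth. Converted background patches are grown as random-walk blobs
#' (spatially autocorrelated, like an agricultural frontier) until the
#' target background conversion fraction is met; reserves and planted
#' corridors are then carved back to natural, and planted blockage bands
#' are laid last so the ground truth holds regardless of the random
#' background. Positive validation points are midpoints between village
#' pairs straddling a planted open corridor; negative points are kept at
#' least twice the buffer radius from every planted corridor and clear of
#' the direct inter-reserve gap regions, so labels are noise-free.
#'
#' @param spec a [landscape_spec()].
#' @return an object of class `synthetic_bundle`: list with `conversion`
#'   ([conversion_grid()]), `pas` ([pa_table()]), `points` (validation
#'   points data.frame), `dem`, `wetland_mask`, `water_mask` (or `NULL`),
#'   `truth` (per planted link: `open` or `severed`), `corridors` (carved
#'   strip layouts) and the `spec`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  set.seed(spec$seed)
  nr <- spec$grid_rows; nc <- spec$grid_cols; cs <- spec$cell_size_km
  pa_by_id <- stats::setNames(spec$protected_areas,
                              vapply(spec$protected_areas, `[[`, "", "id"))

  layouts <- lapply(spec$planted_links, function(lk)
    c(link_layout(pa_by_id[[lk$pa_a]], pa_by_id[[lk$pa_b]], lk, spec),
      list(link = lk)))

  pa_mask <- matrix(FALSE, nr, nc)
  for (pa in spec$protected_areas)
    pa_mask <- pa_mask | rect_mask(nr, nc, pa$rows, pa$cols)

  corridor_mask <- matrix(FALSE, nr, nc)
  band_mask <- matrix(FALSE, nr, nc)
  for (ly in layouts) {
    corridor_mask <- corridor_mask |
      rect_mask(nr, nc, ly$corridor$rows, ly$corridor$cols)
    if (ly$link$kind == "blocked") {
      bm <- rect_mask(nr, nc, ly$band$rows, ly$band$cols)
      if (any(bm & pa_mask))
        stop("invalid spec: planted blockage for '", ly$link$pa_a, "'-'",
             ly$link$pa_b, "' overlaps a protected area")
      band_mask <- band_mask | bm
    }
  }

  water_mask <- matrix(FALSE, nr, nc)
  if (length(spec$water))
    for (rect in spec$water)
      water_mask <- water_mask | rect_mask(nr, nc, rect$rows, rect$cols)

  # background conversion over eligible cells only
  eligible <- !(pa_mask | corridor_mask | band_mask | water_mask)
  quota <- round(spec$conversion_fraction * sum(eligible))
  conv <- grow_conversion_blobs(nr, nc, eligible, quota)

  conv[pa_mask] <- 0        # reserves are natural habitat
  conv[corridor_mask] <- 0  # carve planted corridors ...
  conv[band_mask] <- 1      # ... then lay blockages on top

  pas <- pa_table(
    id = vapply(spec$protected_areas, `[[`, "", "id"),
    name = vapply(spec$protected_areas, `[[`, "", "name"),
    protection_level = vapply(spec$protected_areas, `[[`, "", "protection_level"),
    geometry = lapply(spec$protected_areas,
                      function(pa) rect_polygon(pa$rows, pa$cols, cs)))

  # validation points
  open_layouts <- Filter(function(ly) ly$link$kind == "open_corridor", layouts)
  pts <- list()
  if (spec$n_positive_points > 0) {
    for (i in seq_len(spec$n_positive_points)) {
      ly <- open_layouts[[(i - 1) %% length(open_layouts) + 1]]
      co <- ly$corridor
      if (ly$orient == "vertical") {
        y <- stats::runif(1, (co$rows[1] - 1) * cs + 1, co$rows[2] * cs - 1)
        ctr_x <- mean(c(co$cols[1] - 1, co$cols[2])) * cs
        # villages straddle the strip; the recorded point is their midpoint
        jitter <- stats::runif(1, -0.3, 0.3) * cs
        pts[[length(pts) + 1]] <- c(ctr_x + jitter, y)
      } else {
        x <- stats::runif(1, (co$cols[1] - 1) * cs + 1, co$cols[2] * cs - 1)
        ctr_y <- mean(c(co$rows[1] - 1, co$rows[2])) * cs
        jitter <- stats::runif(1, -0.3, 0.3) * cs
        pts[[length(pts) + 1]] <- c(x, ctr_y + jitter)
      }
    }
  }
  pos <- if (length(pts)) do.call(rbind, pts) else matrix(0, 0, 2)

  # gap hulls: direct inter-reserve regions negatives must stay clear of
  hulls <- lapply(layouts, function(ly) {
    a <- pa_by_id[[ly$link$pa_a]]; b <- pa_by_id[[ly$link$pa_b]]
    list(rows = range(a$rows, b$rows), cols = range(a$cols, b$cols))
  })
  neg <- matrix(0, 0, 2)
  if (spec$n_negative_points > 0) {
    need <- spec$n_negative_points
    keep <- matrix(NA_real_, need, 2)
    got <- 0; tries <- 0
    clearance <- 2 * spec$buffer_radius_km
    hull_clear <- spec$buffer_radius_km + 2 * cs
    while (got < need && tries < need * 2000) {
      x <- stats::runif(1, cs, (nc - 1) * cs)
      y <- stats::runif(1, cs, (nr - 1) * cs)
      tries <- tries + 1
      ok <- TRUE
      for (pa in spec$protected_areas)
        if (dist_to_rect(x, y, pa$rows, pa$cols, cs) <= 0) { ok <- FALSE; break }
      if (ok) for (ly in layouts)
        if (dist_to_rect(x, y, ly$corridor$rows, ly$corridor$cols, cs) <
            clearance) { ok <- FALSE; break }
      if (ok) for (h in hulls)
        if (dist_to_rect(x, y, h$rows, h$cols, cs) < hull_clear) {
          ok <- FALSE; break
        }
      if (ok && length(spec$water)) for (rect in spec$water)
        if (dist_to_rect(x, y, rect$rows, rect$cols, cs) < cs) {
          ok <- FALSE; break
        }
      if (ok) { got <- got + 1; keep[got, ] <- c(x, y) }
    }
    if (got < need)
      stop("could not place ", need, " negative points; landscape too crowded")
    neg <- keep
  }
  points <- data.frame(
    x = c(pos[, 1], neg[, 1]), y = c(pos[, 2], neg[, 2]),
    label = rep(c("movement", "none"), c(nrow(pos), nrow(neg))),
    stringsAsFactors = FALSE)

  dem <- if (!is.null(spec$relief)) generate_dem_ridge(spec) else NULL
  wetland <- NULL
  if (!is.null(spec$relief$wetland)) {
    wm <- rect_mask(nr, nc, spec$relief$wetland$rows, spec$relief$wetland$cols)
    wetland <- corridor_grid(wm + 0, cs)
  }
  water <- if (length(spec$water)) corridor_grid(water_mask + 0, cs)

  truth <- data.frame(
    pa_a = vapply(spec$planted_links, `[[`, "", "pa_a"),
    pa_b = vapply(spec$planted_links, `[[`, "", "pa_b"),
    kind = vapply(spec$planted_links, `[[`, "", "kind"),
    stringsAsFactors = FALSE)
  truth$truth <- ifelse(truth$kind == "open_corridor", "open", "severed")

  structure(list(conversion = conversion_grid(conv, cs), pas = pas,
                 points = points, dem = dem, wetland_mask = wetland,
                 water_mask = water, truth = truth, corridors = layouts,
                 spec = spec),
            class = "synthetic_bundle")
}

#' Synthetic ridge elevation model
#'
#' A linear ridge running down one column: elevation falls off linearly on
#' both flanks at `rise` km per km of horizontal distance, so the interior
#' flank slope is exactly `atan(rise)` (e.g. a rise of 0.2 gives 11.31
#' degrees, just over the 10-degree natural-barrier threshold; 0.1 gives
#' 5.71 degrees, under it).
#'
#' @param spec a [landscape_spec()] whose `relief` field is set.
#' @return a [corridor_grid()] of elevations in km.
#' @export
generate_dem_ridge <- function(spec) {
  rl <- spec$relief
  if (is.null(rl)) stop("spec has no relief description")
  nr <- spec$grid_rows; nc <- spec$grid_cols; cs <- spec$cell_size_km
  crest <- rl$crest_col %||% round(nc / 2)
  height <- rl$height_km %||% 1
  rise <- rl$rise %||% 0.2
  xdist <- abs(seq_len(nc) - crest) * cs
  prof <- pmax(0, height - rise * xdist)
  corridor_grid(matrix(prof, nr, nc, byrow = TRUE), cs)
}

#' Demonstration landscape specification
#'
#' A 200 x 200 km study region holding three reserve pairs in parallel
#' compartments separated by two full-height water channels (barriers to
#' large-mammal movement, like the great lakes of the Rift). Each pair is
#' joined by a planted natural corridor 11 cells wide — wider than the
#' largest focal-mean neighborhood, so corridor interiors keep cost 1 on
#' every surface. The western pair's corridor is left open; the central
#' pair's is cut by a thin (1-cell) converted band and serves as the
#' *reference* corridor whose cost-weighted distance calibrates the
#' open/severed threshold; the eastern pair's is cut by a thick (3-cell)
#' band. The three gaps are geometrically identical, so the planted
#' conversion alone orders the pairs' cost-weighted distances
#' (open < reference < blocked) on every cost surface. Background
#' conversion covers 15% of background cells; 34 movement and 41
#' no-movement points emulate interview records.
#'
#' @param seed integer RNG seed.
#' @param conversion_fraction background conversion fraction.
#' @return a [landscape_spec()].
#' @export
demo_landscape_spec <- function(seed = 1, conversion_fraction = 0.15) {
  landscape_spec(
    grid_rows = 200, grid_cols = 200, cell_size_km = 1,
    conversion_fraction = conversion_fraction,
    protected_areas = list(
      pa_rect("pa1", "West Highlands NP", "national_park", c(40, 70),   c(8, 58)),
      pa_rect("pa2", "West Valley GR",    "game_reserve",  c(130, 160), c(8, 58)),
      pa_rect("pa3", "Central Plains NP", "national_park", c(40, 70),   c(75, 125)),
      pa_rect("pa4", "Escarpment GR",     "game_reserve",  c(130, 160), c(75, 125)),
      pa_rect("pa5", "Lakeshore NP",      "national_park", c(40, 70),   c(142, 192)),
      pa_rect("pa6", "Southern Woods GR", "game_reserve",  c(130, 160), c(142, 192))),
    planted_links = list(
      planted_link("pa1", "pa2", "open_corridor", corridor_width_cells = 11),
      planted_link("pa3", "pa4", "blocked", corridor_width_cells = 11,
                   blockage_width_cells = 1, band_extent = c(66, 134)),
      planted_link("pa5", "pa6", "blocked", corridor_width_cells = 11,
                   blockage_width_cells = 3, band_extent = c(133, 200))),
    n_positive_points = 34, n_negative_points = 41,
    buffer_radius_km = 5, village_spacing_km = 5,
    water = list(list(rows = c(1, 200), cols = c(66, 67)),
                 list(rows = c(1, 200), cols = c(133, 134))),
    seed = seed)
}
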