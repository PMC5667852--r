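#' Derive the open/severed classification rule from a reference corridor
#'
#' The rule copies two thresholds from a reference corridor known (from
#' ground data) to have been severed: its cost-weighted distance and its
#' Euclidean distance. Corridors with CWD strictly below the first are
#' open; corridors at or above it are severed unless they qualify for the
#' long-distance exception (Euclidean distance strictly above the second
#' threshold and no converted-land crossing).
#'
#' @param reference a [pair_metrics()] result with finite CWD and EuD.
#' @return a list of class `classification_rule`: `cwd_threshold_weighted_km`,
#'   `eud_threshold_km`, `reference_pair`.
#' @export
derive_rule <- function(reference) {
  if (identical(reference$status, "contiguous"))
    stop("reference corridor is contiguous; no threshold can be derived")
  if (!is.finite(reference$cwd_weighted_km) ||
      !is.finite(reference$euclidean_km))
    stop("reference corridor must have finite CWD and Euclidean distance")
  structure(list(cwd_threshold_weighted_km = reference$cwd_weighted_km,
                 eud_threshold_km = reference$euclidean_km,
                 reference_pair = c(reference$pa_a, reference$pa_b)),
            class = "classification_rule")
}

#' Classify corridors as open or severed
#'
#' Vectorized three-branch rule: open when `cwd < cwd_threshold`; otherwise
#' open when `eud > eud_threshold` and the corridor does not cross
#' converted land (the long-distance exception, which prevents corridors
#' from being called severed on account of their length alone); otherwise
#' severed. Comparisons are strict, so a corridor exactly at the threshold
#' is severed — as the reference corridor itself is.
#'
#' @param cwd cost-weighted distances (weighted km).
#' @param eud Euclidean distances (km).
#' @param crosses_converted logical.
#' @param rule a [derive_rule()] result.
#' @return character vector `"open"`/`"severed"`.
#' @export
classify_status <- function(cwd, eud, crosses_converted, rule) {
  if (any(is.na(crosses_converted)) || any(is.na(eud)))
    stop("classification needs complete metrics")
  ifelse(cwd < rule$cwd_threshold_weighted_km, "open",
         ifelse(eud > rule$eud_threshold_km & !crosses_converted,
                "open", "severed"))
}

#' Drop corridors that intersect a third protected area
#'
#' A corridor whose swath threads through another protected area is not an
#' independent linkage (its connectivity is already represented through
#' that area) and is dropped from the network. Endpoint areas are excluded
#' from the test.
#'
#' @param status current status vector.
#' @param intersects_third_pa logical flag from [pair_metrics()].
#' @return status vector with flagged corridors set to `"dropped"`.
#' @export
drop_if_third_pa <- function(status, intersects_third_pa) {
  ifelse(!is.na(intersects_third_pa) & intersects_third_pa,
         "dropped", status)
}

#' Slope grid from a digital elevation model
#'
#' Per-cell terrain slope in degrees via Horn's 3x3 finite-difference
#' weights: `slope = atan(sqrt(gx^2 + gy^2))` where the gradients weight
#' the adjacent row/column neighbors 2:1 against the diagonals. Edge cells
#' use replicated (clamped) borders.
#'
#' @param dem a [corridor_grid()] of elevations in km.
#' @param cell_size_km optional override of the DEM cell size.
#' @return a [corridor_grid()] of slopes in degrees.
#' @export
slope_from_dem <- function(dem, cell_size_km = NULL) {
  z <- dem$values
  cs <- cell_size_km %||% dem$cell_size_km
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2)
    stop("DEM must have at least 2 rows and 2 columns")
  if (anyNA(z)) stop("DEM must be finite everywhere")
  up <- c(1, 1:(nr - 1)); dn <- c(2:nr, nr)       # clamped row shifts
  lf <- c(1, 1:(nc - 1)); rt <- c(2:nc, nc)       # clamped col shifts
  # Horn weights over the 3x3 window
  gx <- ((z[up, rt] + 2 * z[, rt] + z[dn, rt]) -
         (z[up, lf] + 2 * z[, lf] + z[dn, lf])) / (8 * cs)
  gy <- ((z[dn, lf] + 2 * z[dn, ] + z[dn, rt]) -
         (z[up, lf] + 2 * z[up, ] + z[up, rt])) / (8 * cs)
  corridor_grid(atan(sqrt(gx^2 + gy^2)) * 180 / pi, cs)
}

#' Flag corridors crossing potential natural barriers
#'
#' A corridor is flagged when its sliced swath touches any cell with slope
#' above the threshold or any permanent-wetland cell. The flag is advisory
#' (barrier permeability is species-specific) and never changes the
#' open/severed status.
#'
#' @param sliced logical corridor mask.
#' @param slope optional slope [corridor_grid()] in degrees.
#' @param wetland_mask optional binary [corridor_grid()] of permanent
#'   wetlands.
#' @param slope_threshold_deg slope threshold in degrees.
#' @return logical flag (`FALSE` when no barrier layer is supplied).
#' @export
flag_natural_barriers <- function(sliced, slope = NULL, wetland_mask = NULL,
                                  slope_threshold_deg = 10) {
  hit <- FALSE
  if (!is.null(slope))
    hit <- hit || any(sliced & slope$values > slope_threshold_deg,
                      na.rm = TRUE)
  if (!is.null(wetland_mask))
    hit <- hit || any(sliced & wetland_mask$values == 1, na.rm = TRUE)
  hit
}
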