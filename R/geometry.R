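# Planar polygon helpers for protected-area geometries.
# Polygons are open rings: n x 2 matrices of (x, y) vertices in km.

poly_segments <- function(poly) {
  n <- nrow(poly)
  list(a = poly, b = poly[c(2:n, 1), , drop = FALSE])
}

# distance from points (px, py) to segment (ax,ay)-(bx,by), vectorized
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 == 0, 0, ((px - ax) * dx + (py - ay) * dy) / len2)
  t <- pmin(1, pmax(0, t))
  qx <- ax + t * dx; qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1; d2 <- b2 - b1
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-12) return(FALSE)  # parallel; overlap handled by distance 0
  t <- ((b1[1] - a1[1]) * d2[2] - (b1[2] - a1[2]) * d2[1]) / denom
  u <- ((b1[1] - a1[1]) * d1[2] - (b1[2] - a1[2]) * d1[1]) / denom
  t >= 0 && t <= 1 && u >= 0 && u <= 1
}

#' Minimum edge-to-edge distance between two polygons
#'
#' The Euclidean gap between two protected areas, measured boundary to
#' boundary (0 if the boundaries touch or cross). This is the "EuD" used by
#' the long-distance classification exception.
#'
#' @param a,b polygon vertex matrices (two columns, x and y, in km).
#' @return distance in km.
#' @export
polygon_distance <- function(a, b) {
  sa <- poly_segments(a); sb <- poly_segments(b)
  # crossing => distance 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (segments_intersect(sa$a[i, ], sa$b[i, ], sb$a[j, ], sb$b[j, ]))
        return(0)
    }
  }
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- point_segment_distance(a[i, 1], a[i, 2],
                                sb$a[, 1], sb$a[, 2], sb$b[, 1], sb$b[, 2])
    best <- min(best, d)
  }
  for (j in seq_len(nrow(b))) {
    d <- point_segment_distance(b[j, 1], b[j, 2],
                                sa$a[, 1], sa$a[, 2], sa$b[, 1], sa$b[, 2])
    best <- min(best, d)
  }
  best
}

# Overlap length of two collinear segments; 0 if not collinear or disjoint.
collinear_overlap <- function(a1, a2, b1, b2, tol = 1e-9) {
  d1 <- a2 - a1
  len1 <- sqrt(sum(d1^2))
  if (len1 < tol) return(0)
  u <- d1 / len1
  # both b endpoints must lie on the a line
  perp <- function(p) abs((p[1] - a1[1]) * u[2] - (p[2] - a1[2]) * u[1])
  if (perp(b1) > tol || perp(b2) > tol) return(0)
  proj <- function(p) (p[1] - a1[1]) * u[1] + (p[2] - a1[2]) * u[2]
  lo <- max(0, min(proj(b1), proj(b2)))
  hi <- min(len1, max(proj(b1), proj(b2)))
  max(0, hi - lo)
}

#' Shared border length between two polygons
#'
#' Total length of boundary the two polygons hold in common (collinear
#' overlapping edge segments). Two protected areas are *contiguous* when
#' this is positive; corner-only contact counts as 0 because a point
#' contact is not a traversable border.
#'
#' @inheritParams polygon_distance
#' @return shared boundary length in km.
#' @export
shared_border_length <- function(a, b) {
  sa <- poly_segments(a); sb <- poly_segments(b)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      tot <- tot + collinear_overlap(sa$a[i, ], sa$b[i, ], sb$a[j, ], sb$b[j, ])
    }
  }
  tot
}
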