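# Independent oracles: deliberately naive implementations used only to
# check the package's optimized code paths.

# Dijkstra over an explicitly enumerated edge list, with linear-scan
# priority selection. Same graph convention as the package: 8-connected,
# link weight = mean(cost) * length, diagonals blocked between two
# corner-touching barriers.
dijkstra_oracle <- function(values, sources, cell_size = 1) {
  nr <- nrow(values); nc <- ncol(values); n <- nr * nc
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    u <- (c - 1) * nr + r
    if (is.na(values[u])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- (c2 - 1) * nr + r2
      if (is.na(values[v])) next
      if (dr != 0 && dc != 0) {
        if (is.na(values[r, c2]) && is.na(values[r2, c])) next
        len <- sqrt(2) * cell_size
      } else len <- cell_size
      from <- c(from, u); to <- c(to, v)
      w <- c(w, (values[u] + values[v]) / 2 * len)
    }
  }
  dist <- rep(Inf, n)
  ok_src <- sources[!is.na(values[sources])]
  dist[ok_src] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    for (e in which(from == u)) {
      nd <- dist[u] + w[e]
      if (nd < dist[to[e]]) dist[to[e]] <- nd
    }
  }
  matrix(dist, nr, nc)
}

# double-loop window mean; in-bounds, non-NA cells only
focal_mean_oracle <- function(v, k) {
  h <- (k - 1) / 2
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(v[r, c])) next
    win <- v[max(1, r - h):min(nr, r + h), max(1, c - h):min(nc, c + h)]
    out[r, c] <- mean(win, na.rm = TRUE)
  }
  out
}

kappa_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fn + tn) / n) * ((fp + tn) / n)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

# vectorized 8-connected flood fill over `open` cells from a start mask
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (dr in -1:1) {
    tr <- max(1, 1 - dr):min(nr, nr - dr); sr <- tr + dr
    for (dc in -1:1) {
      tc <- max(1, 1 - dc):min(nc, nc - dc); sc <- tc + dc
      out[tr, tc] <- out[tr, tc] | m[sr, sc]
    }
  }
  out
}

flood_reachable <- function(open, start_mask) {
  seen <- start_mask & open
  repeat {
    grown <- dilate8(seen) & open
    if (identical(grown, seen)) return(seen)
    seen <- grown
  }
}

# traversable natural cells of a synthetic bundle (for route existence)
natural_open_cells <- function(bundle) {
  open <- bundle$conversion$values == 0
  if (!is.null(bundle$water_mask))
    open <- open & bundle$water_mask$values == 0
  open
}

pa_cell_mask <- function(bundle, id) {
  grid <- bundle$conversion
  m <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  m[rasterize_sources(bundle$pas[bundle$pas$id == id, ], grid)] <- TRUE
  m
}

# random cost surface for oracle-equivalence checks
random_surface <- function(nr = 15, nc = 15, barrier_prob = 0.1,
                           base_cost = 10) {
  v <- matrix(stats::runif(nr * nc, 1, base_cost), nr, nc)
  v[stats::runif(nr * nc) < barrier_prob] <- NA
  if (all(is.na(v))) v[1, 1] <- 1
  cost_surface(v, base_cost = base_cost)
}
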