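nat_surface <- function(nr, nc, base = 10)
  assign_base_costs(conversion_grid(matrix(0, nr, nc)), base)

test_that("cost distance reproduces hand-computed values", {
  # 1x5 uniform strip: 4 rook links of weight 1
  s <- nat_surface(1, 5)
  cwd <- cost_distance(s, 1L)
  expect_equal(cwd$dist[1, ], 0:4)
  # 2x2: one diagonal link of weight sqrt(2)
  s2 <- nat_surface(2, 2)
  cwd2 <- cost_distance(s2, 1L)
  expect_equal(cwd2$dist[2, 2], sqrt(2))
  expect_equal(cwd2$dist[1, 1], 0)
})

test_that("cost distance matches the edge-list Dijkstra oracle", {
  set.seed(101)
  for (i in 1:20) {
    s <- random_surface()
    src <- which(!is.na(s$values))[1:2]
    got <- cost_distance(s, src)$dist
    expect_equal(got, dijkstra_oracle(s$values, src), tolerance = 1e-12)
  }
})

test_that("pinched diagonal gaps do not leak paths", {
  # two barrier cells share only a corner; the diagonal between them is shut
  v <- matrix(1, 2, 2)
  v[1, 2] <- NA; v[2, 1] <- NA
  s <- cost_surface(v, 10)
  cwd <- cost_distance(s, 1L)
  expect_true(is.infinite(cwd$dist[2, 2]))
  # with one companion open the diagonal is allowed
  v2 <- matrix(1, 2, 2); v2[1, 2] <- NA
  cwd2 <- cost_distance(cost_surface(v2, 10), 1L)
  expect_equal(cwd2$dist[2, 2], sqrt(2))
})

test_that("CWD is bounded below by straight-line length and is symmetric", {
  set.seed(202)
  for (i in 1:10) {
    s <- random_surface(12, 12, barrier_prob = 0)
    a <- sample.int(144, 1); b <- sample.int(144, 1)
    da <- cost_distance(s, a); db <- cost_distance(s, b)
    expect_equal(min(da$dist + db$dist), min(db$dist + da$dist),
                 tolerance = 1e-9)
    nr <- 12
    chord <- sqrt((((a - 1) %% nr) - ((b - 1) %% nr))^2 +
                  (((a - 1) %/% nr) - ((b - 1) %/% nr))^2)
    # cost >= 1 everywhere, and the grid chain is at least as long
    expect_gte(da$dist[b] + 1e-9, chord / sqrt(2))
  }
})

test_that("adding conversion never decreases a pair's CWD", {
  set.seed(303)
  base <- matrix(sample(0:1, 225, TRUE, c(.85, .15)), 15, 15)
  s1 <- assign_base_costs(conversion_grid(base), 100)
  d1 <- cost_distance(s1, 1L)$dist
  worse <- base
  worse[sample(which(base == 0), 10)] <- 1
  s2 <- assign_base_costs(conversion_grid(worse), 100)
  d2 <- cost_distance(s2, 1L)$dist
  expect_true(all(d2 - d1 >= -1e-9))
})

test_that("least-cost path backtracks to the source with correct length", {
  s <- nat_surface(1, 5)
  cwd <- cost_distance(s, 1L)
  p <- least_cost_path(cwd, 5L)
  expect_equal(p$cells, 1:5)
  expect_equal(p$lcp_km, 4)
  expect_equal(p$cost, 4)

  # a converted band with one natural gap: the path routes through the gap
  v <- matrix(0, 7, 7); v[4, ] <- 1; v[4, 6] <- 0
  s2 <- assign_base_costs(conversion_grid(v), 10)
  cwd2 <- cost_distance(s2, which(row(v) == 1))
  p2 <- least_cost_path(cwd2, which(row(v) == 7))
  rows_cols <- cbind((p2$cells - 1) %% 7 + 1, (p2$cells - 1) %/% 7 + 1)
  gap_col <- rows_cols[rows_cols[, 1] == 4, 2]
  expect_equal(gap_col, 6)
  # and it is cheaper than a straight crossing of the band
  straight <- 6 + (10 - 1)  # 6 rook links, one at elevated mean cost
  expect_lt(p2$cost, straight)

  # fully blocking barrier row: disconnected, reported not thrown
  vb <- matrix(1, 5, 5); vb[3, ] <- NA
  cwdb <- cost_distance(cost_surface(vb, 10), 1L)
  pb <- least_cost_path(cwdb, 25L)
  expect_false(pb$connected)
  expect_true(is.infinite(pb$cost))
})

test_that("corridor raster is zero exactly on least-cost routes", {
  s <- nat_surface(1, 5)
  ca <- cost_distance(s, 1L); cb <- cost_distance(s, 5L)
  corr <- corridor_raster(ca, cb)
  expect_equal(corr$values[1, ], rep(0, 5))  # whole strip is optimal

  # a detour cell scores its extra weighted km
  s2 <- nat_surface(3, 5)
  ca2 <- cost_distance(s2, which(col(s2$values) == 1 & row(s2$values) == 2))
  cb2 <- cost_distance(s2, which(col(s2$values) == 5 & row(s2$values) == 2))
  corr2 <- corridor_raster(ca2, cb2)
  expect_equal(corr2$values[2, 3], 0)
  expect_equal(corr2$values[1, 3], 2 * (sqrt(2) - 1), tolerance = 1e-9)
})

test_that("corridor slicing keeps the lowest percentile with ties", {
  vals <- matrix(as.numeric(1:100), 10, 10)
  corr <- corridor_grid(vals)
  sl <- slice_corridor(corr, 10)
  expect_equal(sum(sl), 10)
  expect_true(all(vals[sl] <= 10))

  const <- corridor_grid(matrix(5, 4, 4))
  expect_true(all(slice_corridor(const, 5)))  # all tie at the cutoff

  allinf <- corridor_grid(matrix(Inf, 3, 3))
  expect_equal(sum(slice_corridor(allinf, 20)), 0)

  # nested widths
  set.seed(9)
  rnd <- corridor_grid(matrix(runif(400), 20, 20))
  s5 <- slice_corridor(rnd, 5); s10 <- slice_corridor(rnd, 10)
  s15 <- slice_corridor(rnd, 15); s20 <- slice_corridor(rnd, 20)
  expect_true(all(s10[s5]) && all(s15[s10]) && all(s20[s15]))

  # cwd-cutoff variant keeps cells within a fraction of the path cost
  sc <- slice_corridor(rnd, 10, method = "cwd_cutoff", lcp_cost = 10)
  expect_equal(sc, rnd$values <= 1)
})

test_that("polygon rasterization follows the cell-center rule", {
  g <- corridor_grid(matrix(0, 20, 20))
  rect <- cbind(c(2, 12, 12, 2), c(3, 3, 13, 13))  # 10x10 km aligned
  expect_length(rasterize_sources(rect, g), 100)

  tiny <- cbind(c(4.4, 4.6, 4.6, 4.4), c(4.4, 4.4, 4.6, 4.6))  # one center
  expect_length(rasterize_sources(tiny, g), 1)

  none <- cbind(c(4.6, 4.9, 4.9, 4.6), c(4.6, 4.6, 4.9, 4.9))  # no center
  expect_error(rasterize_sources(none, g), "no cell center")
})

test_that("pair metrics assemble CWD, EuD, LCP and flags consistently", {
  # two 3x3 reserves at the ends of a 9x21 natural strip with one converted
  # column between them
  v <- matrix(0, 9, 21); v[, 11] <- 1
  conv <- conversion_grid(v)
  s <- assign_base_costs(conv, 10)
  pas <- pa_table(id = c("a", "b"), name = c("A", "B"),
                  protection_level = c("national_park", "game_reserve"),
                  geometry = list(cbind(c(1, 4, 4, 1), c(3, 3, 6, 6)),
                                  cbind(c(17, 20, 20, 17), c(3, 3, 6, 6))))
  r <- pair_metrics("a", "b", pas, s, conv = conv,
                    future_conv = project_future_conversion(conv))
  expect_equal(r$euclidean_km, 13)
  expect_true(r$crosses_converted)      # the band must be crossed
  expect_true(r$crosses_future_converted)
  expect_gte(r$cwd_weighted_km, r$lcp_km - 1e-9)
  expect_gte(r$lcp_km, r$euclidean_km - 1e-9)
  expect_true(abs(r$cwd_weighted_km - (13 + 9)) < 2)  # one band crossing
  expect_false(r$intersects_third_pa)
  # symmetric in the pair labels
  r2 <- pair_metrics("b", "a", pas, s, conv = conv)
  expect_equal(r2$cwd_weighted_km, r$cwd_weighted_km, tolerance = 1e-9)

  expect_error(pair_metrics("a", "a", pas, s), "differ")
})

test_that("an all-natural planted strip yields no converted crossing", {
  v <- matrix(0, 9, 21)
  conv <- conversion_grid(v)
  s <- assign_base_costs(conv, 10)
  pas <- pa_table(id = c("a", "b"), name = c("A", "B"),
                  protection_level = c("national_park", "game_reserve"),
                  geometry = list(cbind(c(1, 4, 4, 1), c(3, 3, 6, 6)),
                                  cbind(c(17, 20, 20, 17), c(3, 3, 6, 6))))
  r <- pair_metrics("a", "b", pas, s, conv = conv)
  expect_false(r$crosses_converted)
  expect_equal(r$status, "unclassified")
})

test_that("contiguous reserves are flagged, not modeled", {
  v <- matrix(0, 10, 10)
  s <- assign_base_costs(conversion_grid(v), 10)
  pas <- pa_table(id = c("a", "b"), name = c("A", "B"),
                  protection_level = c("national_park", "game_reserve"),
                  geometry = list(cbind(c(1, 5, 5, 1), c(1, 1, 8, 8)),
                                  cbind(c(5, 9, 9, 5), c(1, 1, 8, 8))))
  r <- pair_metrics("a", "b", pas, s)
  expect_equal(r$status, "contiguous")
  expect_true(is.na(r$cwd_weighted_km))
})

test_that("sliced corridors are nested across widths on real fields", {
  set.seed(55)
  s <- random_surface(20, 20, barrier_prob = 0)
  ca <- cost_distance(s, 1:20)            # left edge
  cb <- cost_distance(s, 381:400)         # right edge
  corr <- corridor_raster(ca, cb)
  masks <- lapply(c(5, 10, 15, 20), function(w) slice_corridor(corr, w))
  for (i in 1:3) expect_true(all(masks[[i + 1]][masks[[i]]]))
  # the LCP itself is always inside the narrowest slice
  p <- least_cost_path(ca, 381:400)
  expect_true(all(masks[[1]][p$cells]))
})
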