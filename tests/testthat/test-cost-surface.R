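test_that("base costs map natural to 1 and converted to the base cost", {
  conv <- conversion_grid(matrix(0, 4, 4))
  expect_true(all(assign_base_costs(conv, 10)$values == 1))

  one <- matrix(0, 5, 5); one[3, 3] <- 1
  s <- assign_base_costs(conversion_grid(one), 10)
  expect_equal(s$values[3, 3], 10)
  expect_equal(sum(s$values), 24 + 10)

  chk <- matrix(rep_len(c(0, 1), 25), 5, 5)
  s1000 <- assign_base_costs(conversion_grid(chk), 1000)
  expect_true(all(s1000$values %in% c(1, 1000)))
  expect_equal(s1000$values == 1000, chk == 1)

  expect_error(assign_base_costs(conversion_grid(one), 7), "base_cost")
  expect_error(conversion_grid(matrix(c(0, 2, 1, 0), 2, 2)), "binary")
})

test_that("focal mean spreads a converted cell into its neighborhood", {
  one <- matrix(0, 3, 3); one[2, 2] <- 1
  s <- focal_mean(assign_base_costs(conversion_grid(one), 10), 3)
  expect_equal(s$values[2, 2], 2.0)        # (8*1 + 10) / 9
  expect_equal(s$values[1, 1], 3.25)       # (3*1 + 10) / 4
  expect_equal(s$values[1, 2], 2.5)        # (5*1 + 10) / 6

  allconv <- assign_base_costs(conversion_grid(matrix(1, 6, 6)), 10)
  expect_true(all(focal_mean(allconv, 3)$values == 10))

  allnat <- assign_base_costs(conversion_grid(matrix(0, 6, 6)), 100)
  for (k in c(3, 5, 9)) expect_true(all(focal_mean(allnat, k)$values == 1))

  expect_error(focal_mean(allnat, 4), "odd")
  expect_error(focal_mean(allnat, -3), "odd")
})

test_that("focal mean matches the double-loop window-mean oracle", {
  set.seed(42)
  for (i in 1:25) {
    v <- matrix(sample(0:1, 400, replace = TRUE), 20, 20)
    s <- assign_base_costs(conversion_grid(v), sample(c(10, 100, 1000), 1))
    k <- sample(c(3, 5, 7, 9), 1)
    got <- focal_mean(s, k)$values
    expect_equal(got, focal_mean_oracle(s$values, k), tolerance = 1e-14)
  }
})

test_that("barrier cells are excluded from focal windows, not averaged in", {
  v <- matrix(0, 3, 3)
  s <- assign_base_costs(conversion_grid(v), 10)
  s$values[2, 2] <- NA  # water in the middle
  sm <- focal_mean(cost_surface(s$values, 10, cell_size_km = 1), 3)
  expect_true(is.na(sm$values[2, 2]))
  expect_true(all(sm$values[!is.na(sm$values)] == 1))
})

test_that("the factorial surface set has 15 members, 3 unsmoothed", {
  set.seed(7)
  conv <- conversion_grid(matrix(sample(0:1, 100, TRUE, c(.8, .2)), 10, 10))
  set <- build_cost_surface_set(conv)
  expect_length(set, 15)
  nb <- vapply(set, `[[`, 0, "neighborhood")
  expect_equal(sum(nb == 1), 3)
  expect_equal(sum(nb > 1), 12)
  expect_setequal(vapply(set, `[[`, 0, "base_cost"), c(10, 100, 1000))
  # growing neighborhoods dilute a lone converted cell: non-increasing maxima
  one <- matrix(0, 15, 15); one[8, 8] <- 1
  set1 <- build_cost_surface_set(conversion_grid(one))
  for (b in c(10, 100, 1000)) {
    mx <- vapply(c(1, 3, 5, 7, 9), function(k)
      max(set1[[sprintf("b%d_k%d", b, k)]]$values), 0)
    expect_true(all(diff(mx) <= 1e-12))
  }
})

test_that("raising the base cost never decreases any cell value", {
  set.seed(11)
  conv <- conversion_grid(matrix(sample(0:1, 400, TRUE, c(.7, .3)), 20, 20))
  for (k in c(1, 3, 9)) {
    prev <- NULL
    for (b in c(10, 100, 1000)) {
      s <- assign_base_costs(conv, b)
      if (k > 1) s <- focal_mean(s, k)
      if (!is.null(prev)) expect_true(all(s$values >= prev - 1e-12))
      prev <- s$values
    }
  }
})

test_that("water masking turns cells into barriers with precedence over cost", {
  conv <- conversion_grid(matrix(c(0, 1, 0, 1), 2, 2))
  s <- assign_base_costs(conv, 10)
  empty <- corridor_grid(matrix(0, 2, 2))
  expect_equal(apply_water_mask(s, empty)$values, s$values)

  w <- corridor_grid(matrix(c(0, 1, 0, 0), 2, 2))
  masked <- apply_water_mask(s, w)
  expect_true(is.na(masked$values[2, 1]))   # converted cell became barrier
  expect_equal(masked$values[1, 1], 1)

  expect_error(apply_water_mask(s, corridor_grid(matrix(0, 3, 3))),
               "shape mismatch")
})

test_that("a masked row is impassable downstream", {
  v <- matrix(0, 7, 7)
  s <- assign_base_costs(conversion_grid(v), 10)
  w <- matrix(0, 7, 7); w[4, ] <- 1
  s <- apply_water_mask(s, corridor_grid(w))
  cwd <- cost_distance(s, 1L)  # top-left corner
  expect_true(all(is.infinite(cwd$dist[5:7, ])))
  expect_true(all(is.finite(cwd$dist[1:3, ])))
})

test_that("future conversion is a 3x3 focal-maximum dilation", {
  one <- matrix(0, 7, 7); one[4, 4] <- 1
  fut <- project_future_conversion(conversion_grid(one))
  expect_equal(sum(fut$values), 9)
  expect_true(all(fut$values[3:5, 3:5] == 1))

  nat <- conversion_grid(matrix(0, 5, 5))
  expect_equal(project_future_conversion(nat)$values, nat$values)

  band <- matrix(0, 9, 9); band[5, ] <- 1
  fut2 <- project_future_conversion(conversion_grid(band))
  expect_true(all(fut2$values[4:6, ] == 1))
  expect_equal(sum(fut2$values), 27)

  # applying n times dilates a cell to a (2n+1)^2 block; superset invariant
  g <- conversion_grid(one)
  for (n in 1:3) {
    g2 <- project_future_conversion(g)
    expect_true(all(g2$values >= g$values))
    g <- g2
    expect_equal(sum(g$values), (2 * n + 1)^2)
  }
})
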