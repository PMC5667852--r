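sq <- function(x, y, s = 4) cbind(c(x, x + s, x + s, x), c(y, y, y + s, y + s))

toy_pas <- function() {
  pa_table(id = c("np1", "np2", "gr1", "gr2", "np3", "wma"),
           name = c("NP One", "NP Two", "GR One", "GR Two", "NP Three",
                    "Stepping WMA"),
           protection_level = c("national_park", "national_park",
                                "game_reserve", "game_reserve",
                                "national_park", "wildlife_management_area"),
           geometry = list(sq(0, 0), sq(20, 0), sq(40, 0), sq(0, 20),
                           sq(20, 20), sq(40, 20)))
}

test_that("contiguous high-protection reserves merge transitively", {
  pas <- pa_table(id = c("a", "b", "c", "d", "fr"),
                  name = c("A", "B", "C", "D", "FR"),
                  protection_level = c("game_reserve", "game_reserve",
                                       "game_reserve", "national_park",
                                       "forest_reserve"),
                  geometry = list(sq(0, 0), sq(4, 0),    # share an edge
                                  sq(8, 0),              # chain: b-c share too
                                  sq(30, 30),            # isolated NP
                                  sq(0, 4)))             # FR touching a
  cx <- build_complexes(pas)
  expect_equal(nrow(cx), 2)
  sizes <- sort(cx$n_members)
  expect_equal(sizes, c(1, 3))               # a+b+c merged, d a singleton
  expect_true(any(grepl("a", cx$members) & grepl("b", cx$members) &
                  grepl("c", cx$members)))
  # the forest reserve never merges, despite touching a
  expect_false(any(grepl("fr", cx$members)))

  # corner-only touching does not merge
  pas2 <- pa_table(id = c("a", "b"), name = c("A", "B"),
                   protection_level = c("game_reserve", "game_reserve"),
                   geometry = list(sq(0, 0), sq(4, 4)))
  expect_equal(nrow(build_complexes(pas2)), 2)
})

test_that("the network keeps classified edges and rejects duplicates", {
  pas <- toy_pas()
  cx <- build_complexes(pas)
  res <- data.frame(pa_a = c("np1", "np1", "np2", "np1"),
                    pa_b = c("np2", "gr1", "gr1", "gr2"),
                    status = c("open", "severed", "open", "dropped"),
                    stringsAsFactors = FALSE)
  net <- build_network(cx, res, pas)
  expect_equal(nrow(net$edges), 3)            # dropped edge excluded
  expect_setequal(net$edges$status, c("open", "severed"))
  expect_equal(nrow(net$nodes), 6)            # 5 singleton complexes + wma

  dup <- rbind(res, data.frame(pa_a = "np2", pa_b = "np1", status = "open"))
  expect_error(build_network(cx, dup, pas), "duplicate")

  bad <- data.frame(pa_a = "nope", pa_b = "np1", status = "open")
  expect_error(build_network(cx, bad, pas), "not in the protected-area")
})

test_that("nodes with only severed edges are isolated", {
  pas <- toy_pas()
  cx <- build_complexes(pas)
  res <- data.frame(pa_a = c("np1", "np2", "gr2"),
                    pa_b = c("np2", "gr1", "np3"),
                    status = c("open", "severed", "contiguous"),
                    stringsAsFactors = FALSE)
  net <- build_network(cx, res, pas)
  iso <- isolated_nodes(net)
  expect_true("cx_gr1" %in% iso)               # severed only
  expect_true("wma" %in% iso)                  # no edges at all
  expect_false("cx_np1" %in% iso)              # open edge
  expect_false("cx_np3" %in% iso)              # contiguous edge

  empty <- build_network(cx, res[0, ], pas)
  expect_setequal(isolated_nodes(empty), empty$nodes$node)
})

test_that("a low-protection reserve linking several high nodes is a stepping-stone", {
  pas <- toy_pas()
  cx <- build_complexes(pas)
  res <- data.frame(pa_a = c("wma", "wma", "wma", "np1"),
                    pa_b = c("np1", "np2", "gr1", "np2"),
                    status = c("open", "open", "open", "severed"),
                    stringsAsFactors = FALSE)
  net <- build_network(cx, res, pas)
  st <- stepping_stones(net, pas)
  expect_equal(st$node, "wma")
  expect_equal(st$n_linked, 3)
  expect_equal(st$role, "endpoint")

  # one open link only: not a stepping-stone
  res1 <- res[1, , drop = FALSE]
  expect_equal(nrow(stepping_stones(build_network(cx, res1, pas), pas)), 0)

  # severed links confer nothing
  res_sev <- transform(res, status = "severed")
  expect_equal(nrow(stepping_stones(build_network(cx, res_sev, pas), pas)), 0)
})

test_that("a transited low-protection reserve is detected via corridor cells", {
  pas <- toy_pas()
  cx <- build_complexes(pas)
  grid <- corridor_grid(matrix(0, 50, 50))
  res <- data.frame(pa_a = c("np2", "np2"), pa_b = c("np3", "gr1"),
                    status = c("open", "open"), stringsAsFactors = FALSE)
  net <- build_network(cx, res, pas)
  # corridor of np2-np3 passes through the wma polygon (x 40-44, y 20-24)
  mask1 <- matrix(FALSE, 50, 50); mask1[21:24, 41:44] <- TRUE
  mask2 <- matrix(FALSE, 50, 50); mask2[2, 30:38] <- TRUE
  cells <- list("np2|np3" = mask1, "np2|gr1" = mask2)
  st <- stepping_stones(net, pas, corridor_cells = cells, grid = grid)
  expect_equal(st$node, "wma")
  expect_equal(st$n_linked, 2)
  expect_equal(st$role, "transit")
})

test_that("edge status counts partition the retained corridors", {
  pas <- toy_pas()
  cx <- build_complexes(pas)
  res <- data.frame(pa_a = c("np1", "np1", "np2", "gr2"),
                    pa_b = c("np2", "gr1", "gr1", "np3"),
                    status = c("open", "severed", "open", "contiguous"),
                    stringsAsFactors = FALSE)
  net <- build_network(cx, res, pas)
  expect_equal(sum(net$edges$status == "open") +
               sum(net$edges$status == "severed") +
               sum(net$edges$status == "contiguous"), nrow(res))
})
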