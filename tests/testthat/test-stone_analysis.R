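# Stone layer helpers: fields as single cells on a 25 m grid, placed by column
# so distances are easy to read (4 cells = 100 m between centres).
stone_layer <- function(cols, nr = 5, nc = 200, row = 3) {
  m <- matrix(0L, nr, nc)
  for (i in seq_along(cols)) m[row, cols[i]] <- i
  grid_raster(m, 25)
}

test_that("stone fields chain into components by the link radius", {
  # centres 900 m apart (36 cells)
  f <- stone_fields_from_raster(stone_layer(c(10, 46)))
  expect_length(build_stone_components(f, 1000), 1)
  # centres 1100 m apart
  f2 <- stone_fields_from_raster(stone_layer(c(10, 54)))
  comps <- build_stone_components(f2, 1000)
  expect_length(comps, 2)
  expect_true(all(vapply(comps, function(cp) length(cp$member_ids), 0L) == 1))
})

test_that("chaining is transitive even when the ends are far apart", {
  # A-B 900 m, B-C 900 m, A-C 1800 m
  f <- stone_fields_from_raster(stone_layer(c(10, 46, 82)))
  comps <- build_stone_components(f, 1000)
  expect_length(comps, 1)
  expect_setequal(comps[[1]]$member_ids, 1:3)
  # union-find oracle on random field sets
  set.seed(51)
  for (i in 1:10) {
    cols <- sort(sample(seq(5, 195, by = 3), 6))
    fl <- stone_fields_from_raster(stone_layer(cols))
    comps <- build_stone_components(fl, 1000)
    # oracle: union-find over pairwise distances
    parent <- 1:6
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (a in 1:5) for (b in (a + 1):6)
      if (abs(cols[a] - cols[b]) * 25 <= 1000) parent[find(a)] <- find(b)
    expect_length(comps, length(unique(vapply(1:6, find, 0L))))
  }
})

test_that("component filtering is strictly greater-than on total area", {
  mk <- function(total_ha) structure(list(list(member_ids = 1L, members = list(),
                                               total_area_ha = total_ha, qualifying = NA)),
                                     class = "stone_component_set")
  expect_length(filter_components(mk(100.0), 100), 0)
  expect_length(filter_components(mk(100.1), 100), 1)
  expect_length(filter_components(structure(list(), class = "stone_component_set"), 100), 0)
})

test_that("raising the link radius only coarsens the partition", {
  set.seed(52)
  for (i in 1:8) {
    cols <- sort(sample(seq(5, 195, by = 2), 8))
    fl <- stone_fields_from_raster(stone_layer(cols))
    n1 <- length(build_stone_components(fl, 500))
    n2 <- length(build_stone_components(fl, 1500))
    expect_lte(n2, n1)
  }
})

test_that("accumulated cost reduces to metres on neutral terrain", {
  s <- toy_raster(matrix(1, 5, 12))
  acc <- cost_distance(s, cbind(3, 1))
  expect_equal(acc$values[3, 11], 250)      # 10 unit steps east
  expect_equal(acc$values[3, 1], 0)
})

test_that("an infinite-cost barrier makes the far side unreachable", {
  s <- toy_raster(matrix(1, 5, 12))
  s$values[, 6] <- Inf
  acc <- cost_distance(s, cbind(3, 1))
  expect_true(all(is.infinite(acc$values[, 7:12])))
  expect_true(is.finite(acc$values[1, 5]))
  s$values[] <- Inf
  expect_error(cost_distance(s, cbind(3, 1)), "infinite cost")
})

test_that("cost distance equals Bellman-Ford relaxation on random surfaces", {
  set.seed(53)
  for (i in 1:15) {
    cost <- matrix(stats::runif(225, 0.2, 3), 15, 15)
    cost[stats::runif(225) < 0.08] <- Inf
    src <- cbind(sample(15, 2, TRUE), sample(15, 2, TRUE))
    if (!any(is.finite(cost[src]))) next
    acc <- cost_distance(grid_raster(cost, 25), src)
    oracle <- bellman_ford_cost(cost, src[is.finite(cost[src]), , drop = FALSE], 25)
    expect_equal(acc$values, oracle, tolerance = 1e-9)
  }
})

test_that("raising any cell cost never lowers any accumulated value", {
  set.seed(54)
  cost <- matrix(stats::runif(100, 0.5, 2), 10, 10)
  acc1 <- cost_distance(grid_raster(cost, 25), cbind(1, 1))
  cost2 <- cost
  bump <- cbind(sample(10, 5, TRUE), sample(10, 5, TRUE))
  cost2[bump] <- cost2[bump] + 2
  acc2 <- cost_distance(grid_raster(cost2, 25), cbind(1, 1))
  expect_true(all(acc2$values - acc1$values >= -1e-12))
})

test_that("uniform-cost accumulation obeys the octile-metric bound", {
  acc <- cost_distance(toy_raster(matrix(1, 25, 25)), cbind(5, 7))
  xy <- expand.grid(r = 1:25, c = 1:25)
  euc <- 25 * sqrt((xy$r - 5)^2 + (xy$c - 7)^2)
  ratio <- acc$values[as.matrix(xy[, 1:2])] / euc
  ratio <- ratio[euc > 0]
  expect_true(all(ratio >= 1 - 1e-12))
  expect_true(all(ratio <= 1.083))
})

test_that("a low-cost corridor pulls the optimal path below the Euclidean cost", {
  cost <- matrix(1, 11, 40)
  cost[6, ] <- 0.4                       # facilitating corridor along row 6
  acc <- cost_distance(grid_raster(cost, 25), cbind(6, 1))
  expect_lt(acc$values[6, 40], 39 * 25)  # cheaper than neutral terrain
  # off-corridor target still benefits from routing along the corridor
  direct <- 25 * sqrt(5^2 + 39^2)
  expect_lt(acc$values[1, 40], direct)
})

test_that("plot-to-component distances handle the inside and neutral cases", {
  st <- matrix(0L, 30, 30); st[10:20, 10:20] <- 1L
  sr <- grid_raster(st, 25)
  fields <- stone_fields_from_raster(sr)
  comps <- filter_components(build_stone_components(fields), 1)  # 7.56 ha > 1
  surf <- grid_raster(matrix(1, 30, 30), 25)
  xy_in <- cell_centers(sr, 15, 15)
  xy_out <- cell_centers(sr, 2, 28)
  plots <- data.frame(plot_id = 1:2, x = c(xy_in[1], xy_out[1]),
                      y = c(xy_in[2], xy_out[2]))
  dt <- plot_to_component_distances(plots, comps, surf)
  expect_equal(dt$euclid_m[1], 0)
  expect_equal(dt$lcp_cost[1], 0)
  expect_gt(dt$euclid_m[2], 0)
  # neutral terrain: lcp within the octile bound of the Euclidean distance
  expect_gte(dt$lcp_cost[2], dt$euclid_m[2] - 1e-9)
  expect_lte(dt$lcp_cost[2], 1.083 * dt$euclid_m[2])
  expect_error(plot_to_component_distances(plots,
    structure(list(), class = "stone_component_set"), surf), "qualifying")
})
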