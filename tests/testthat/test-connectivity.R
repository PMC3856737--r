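test_that("threshold graphs on collinear patches have the expected edges", {
  ps <- collinear_patches()           # 300 m spacing, ends 600 m apart
  expect_equal(nrow(build_graph(ps, 250)$edges), 0)
  g500 <- build_graph(ps, 500)
  expect_equal(nrow(g500$edges), 2)
  expect_equal(g500$nl["1", "3"], 2)
  g1000 <- build_graph(ps, 1000)
  expect_equal(nrow(g1000$edges), 3)  # the 600 m end pair joins
  expect_equal(g1000$nl["1", "3"], 1)
})

test_that("edge sets grow monotonically with the dispersal threshold", {
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(0, 20, 20)
    m[cbind(sample(20, 8, TRUE), sample(20, 8, TRUE))] <- 80
    ps <- label_patches(toy_raster(m))
    if (length(ps) < 3) next
    key <- function(g) paste(g$edges$from, g$edges$to)
    e250 <- key(build_graph(ps, 250))
    e3000 <- key(build_graph(ps, 3000))
    expect_true(all(e250 %in% e3000))
  }
})

test_that("minimum link counts equal Floyd-Warshall hop counts", {
  set.seed(42)
  for (i in 1:20) {
    n <- 6
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < 0.4
    el <- pairs[keep, , drop = FALSE]
    g <- habitat_graph(1:n, rep(1, n), data.frame(from = el[, 1], to = el[, 2]))
    expect_equal(unname(g$nl), floyd_warshall_hops(n, el))
  }
})

test_that("IIC numerator matches hand enumeration on the worked examples", {
  expect_equal(iic_numerator(habitat_graph(1L, 3)), 9)
  chain <- habitat_graph(1:3, c(1, 1, 1), data.frame(from = c(1, 2), to = c(2, 3)))
  expect_equal(iic_numerator(chain), 17 / 3)
  expect_equal(iic_numerator(habitat_graph(1:2, c(1, 1))), 2)
})

test_that("IIC equals 1 only when one patch fills the landscape", {
  g <- habitat_graph(1L, 40)
  expect_equal(iic(g, 40), 1)
  expect_lt(iic(g, 50), 1)
})

test_that("dIIC fractions reproduce the unit-chain hand computation", {
  chain <- habitat_graph(1:3, c(1, 1, 1), data.frame(from = c(1, 2), to = c(2, 3)))
  fr <- iic_fractions(chain, 2)
  expect_equal(fr[["dIIC"]], 100 * (17 / 3 - 2) / (17 / 3))
  expect_equal(fr[["dIICintra"]], 100 / (17 / 3))
  expect_equal(fr[["dIICflux"]], 200 / (17 / 3))
  expect_equal(fr[["dIICconnector"]],
               fr[["dIIC"]] - fr[["dIICintra"]] - fr[["dIICflux"]])
  expect_equal(flux_per_area(chain, 2), 200 / (17 / 3))
})

test_that("degenerate graphs give the forced fraction values", {
  single <- habitat_graph(5L, 2.5)
  fr <- iic_fractions(single, 5)
  expect_equal(fr[["dIIC"]], 100)
  expect_equal(fr[["dIICintra"]], 100)
  expect_equal(fr[["dIICflux"]], 0)
  pair <- habitat_graph(1:2, c(1, 1), data.frame(from = 1, to = 2))
  fr2 <- iic_fractions(pair, 1)
  expect_equal(fr2[["dIIC"]], 100 * 2 / 3)
  expect_equal(fr2[["dIICintra"]], 100 / 3)
  expect_equal(fr2[["dIICflux"]], 100 / 3)
  expect_equal(fr2[["dIICconnector"]], 0)
  expect_equal(flux_per_area(habitat_graph(1L, 4), 1), 0)  # isolated: no flux
  expect_error(iic_fractions(pair, 99), "unknown")
})

test_that("fractions are additive and match the deletion oracle on random graphs", {
  set.seed(43)
  for (i in 1:40) {
    g <- rand_graph(sample(3:12, 1))
    num <- iic_numerator_brute(g$areas, g$nl)
    for (k in g$ids) {
      fr <- iic_fractions(g, k)
      expect_equal(fr[["dIICintra"]] + fr[["dIICflux"]] + fr[["dIICconnector"]],
                   fr[["dIIC"]], tolerance = 1e-9)
      expect_gte(fr[["dIICconnector"]], -1e-9)
      # deletion oracle: recompute hops among survivors from scratch
      keep <- g$ids != k
      el <- g$edges[g$edges$from != k & g$edges$to != k, , drop = FALSE]
      ids2 <- g$ids[keep]
      hops <- floyd_warshall_hops(length(ids2),
                                  cbind(match(el$from, ids2), match(el$to, ids2)))
      num_minus <- iic_numerator_brute(g$areas[keep], hops)
      expect_equal(fr[["dIIC"]], 100 * (num - num_minus) / num, tolerance = 1e-9)
    }
  }
})

test_that("flux fraction is invariant to area rescaling while C scales as 1/s", {
  set.seed(44)
  for (i in 1:10) {
    g <- rand_graph(6)
    s <- stats::runif(1, 0.5, 4)
    gs <- habitat_graph(g$ids, g$areas * s, g$edges)
    k <- sample(g$ids, 1)
    expect_equal(iic_fractions(gs, k)[["dIICflux"]],
                 iic_fractions(g, k)[["dIICflux"]], tolerance = 1e-9)
    expect_equal(flux_per_area(gs, k), flux_per_area(g, k) / s, tolerance = 1e-9)
  }
})

test_that("the connectivity table covers all patches and thresholds consistently", {
  ps <- collinear_patches()
  tab <- connectivity_table(ps, thresholds = c(250, 500, 1000))
  expect_equal(nrow(tab), 9)
  expect_equal(tab$C, tab$dIICflux / tab$area_ha)
  expect_true(all(tab$dIIC >= 0))
  sub <- tab[tab$d == 500 & tab$patch_id == 2, ]
  expect_equal(sub$dIICflux, 200 / (17 / 3) * (0.0625^2 / 0.0625^2), tolerance = 1e-9)
  expect_error(connectivity_table(ps, thresholds = numeric(0)), "empty")
})
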