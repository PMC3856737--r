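small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, nrow = 150, ncol = 150,
                   patch_areas_ha = exp(seq(log(2.6), log(150), length.out = 8)),
                   n_plots = 6, drop_stations = 0, ...)
}

test_that("the generator is byte-deterministic under (config, seed)", {
  l1 <- generate_landscape(small_config(seed = 5))
  l2 <- generate_landscape(small_config(seed = 5))
  expect_identical(l1$age$values, l2$age$values)
  expect_identical(l1$landclass$values, l2$landclass$values)
  expect_identical(l1$stone$values, l2$stone$values)
  l3 <- generate_landscape(small_config(seed = 6))
  expect_false(identical(l1$age$values, l3$age$values))
})

test_that("an empty patch spectrum yields a forest-free landscape", {
  cfg <- synthetic_config(seed = 2, nrow = 80, ncol = 80,
                          patch_areas_ha = numeric(0), n_plots = 1)
  land <- generate_landscape(cfg)
  expect_length(label_patches(land$age, 60), 0)
})

test_that("infeasible land-cover fractions are rejected", {
  expect_error(synthetic_config(clearcut_fraction = 0.5, lake_fraction = 0.3,
                                forest_fraction_max = 0.4), "exceed 1")
})

test_that("labeled patch areas span the requested spectrum within a factor of two", {
  for (s in 1:8) {
    cfg <- synthetic_config(seed = s)
    land <- generate_landscape(cfg)
    areas <- vapply(label_patches(land$age, 60), `[[`, 0, "area_ha")
    expect_gte(max(areas), max(cfg$patch_areas_ha) / 2)
    expect_lte(min(areas), min(cfg$patch_areas_ha) * 2)
    expect_gte(length(areas), cfg$n_plots)      # one plot per patch possible
  }
})

test_that("land classes and ages are mutually consistent", {
  land <- generate_landscape(small_config(seed = 9))
  a <- land$age$values; lc <- land$landclass$values
  expect_true(all(a[lc == 1] > 60 & a[lc == 1] <= 100))
  expect_true(all(a[lc == 2] > 100))
  expect_true(all(a[lc == 4] <= 20))
  expect_true(all(a[lc == 5] == 0))
  expect_true(all(lc %in% 1:5))
})

test_that("station covariates stay inside their legal code sets", {
  cfg <- small_config(seed = 10)
  plots <- data.frame(plot_id = 1:40, lcp_cost = runif(40, 0, 8000))
  st <- simulate_stations(plots, cfg)
  expect_equal(nrow(st), 400)                  # 10 per plot, no losses
  expect_equal(as.integer(table(st$plot_id)), rep(10L, 40))
  cs <- station_code_sets()
  info <- station_variable_info()
  for (v in info$variable[info$scale == "cover5"])
    expect_true(all(st[[v]] %in% cs$cover5), label = v)
  for (v in c("s_holes", "l_holes"))
    expect_true(all(st[[v]] %in% cs$holes), label = v)
  expect_true(all(st$ls_holes %in% cs$holes_ls))
  for (v in info$variable[info$scale == "prop"])
    expect_true(all(st[[v]] >= 0 & st[[v]] <= 1), label = v)
  expect_true(all(st$occurrence %in% 0:1))
  # default drop leaves the study's station count
  cfg223 <- synthetic_config(seed = 11)
  st223 <- simulate_stations(data.frame(plot_id = 1:23, lcp_cost = runif(23, 0, 8000)),
                             cfg223)
  expect_equal(nrow(st223), 223)
})

test_that("null occupancy collapses to the intercept rate", {
  cfg <- synthetic_config(seed = 12, beta_area = 0, beta_conn = 0,
                          beta_stone = 0, beta0 = 0)
  plots <- data.frame(plot_id = 1:500, area_ha = runif(500, 3, 2000),
                      C = runif(500, 0, 30), lcp_cost = runif(500, 0, 9000))
  sim <- simulate_occupancy(plots, cfg)
  expect_equal(mean(sim$occupied), 0.5, tolerance = 0.06)
  expect_true(all(sim$vole_count[sim$occupied == 1] >= 1))
  expect_true(all(sim$vole_count[sim$occupied == 0] == 0))
  expect_equal(sim$density, 100 * sim$vole_count / 150)
})

test_that("occupancy rises across connectivity deciles when the effect is strong", {
  cfg <- synthetic_config(seed = 13, beta_area = 0, beta_stone = 0,
                          beta_conn = 2, beta0 = 8)
  plots <- data.frame(plot_id = 1:2000, area_ha = 100,
                      C = exp(runif(2000, log(1e-4), log(0.05))),
                      lcp_cost = 0)
  sim <- simulate_occupancy(plots, cfg)
  dec <- cut(sim$C, quantile(sim$C, 0:10 / 10), include.lowest = TRUE)
  rate <- tapply(sim$occupied, dec, mean)
  expect_gt(rate[10], rate[1])
  expect_gt(cor(seq_len(10), rate, method = "spearman"), 0.8)
})

test_that("stone proximity separates occupied from unoccupied plots in sign", {
  cfg <- synthetic_config(seed = 14, beta_area = 0, beta_conn = 0,
                          beta_stone = 2, beta0 = 6)
  plots <- data.frame(plot_id = 1:800, area_ha = 100, C = 0.01,
                      lcp_cost = runif(800, 0, 9000))
  sim <- simulate_occupancy(plots, cfg)
  expect_lt(mean(sim$lcp_cost[sim$occupied == 1]),
            mean(sim$lcp_cost[sim$occupied == 0]))
})

test_that("station occurrence is iid Bernoulli when effects and sigma_u vanish", {
  cfg <- small_config(seed = 15, gamma_pine = 0, gamma_lsholes = 0,
                      sigma_u = 0, gamma0 = -1)
  plots <- data.frame(plot_id = 1:300, lcp_cost = runif(300, 0, 5000))
  st <- simulate_stations(plots, cfg)
  expect_equal(mean(st$occurrence), plogis(-1), tolerance = 0.04)
  # no plot-level clustering: between-plot variance matches binomial noise
  pm <- tapply(st$occurrence, st$plot_id, mean)
  expect_lt(var(pm), 2 * plogis(-1) * (1 - plogis(-1)) / 10)
})

test_that("stations near stone fields carry more stone structure", {
  cfg <- small_config(seed = 16)
  near <- simulate_stations(data.frame(plot_id = 1:80, lcp_cost = 0), cfg)
  cfg2 <- small_config(seed = 16)
  far <- simulate_stations(data.frame(plot_id = 1:80, lcp_cost = 9000), cfg2)
  expect_gt(mean(near$ls_holes), mean(far$ls_holes))
  expect_gt(mean(near$stones), mean(far$stones))
})
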