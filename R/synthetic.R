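#' Seeded synthetic landscapes, plots and station inventories
#'
#' The generator emulates the structure the analysis assumes, so the whole
#' pipeline runs with no field or GIS data: a 20 x 20 km boreal landscape
#' (400 x 400 cells of 50 m) holding patchy >60-year-old forest in a matrix
#' of young forest, 0-20-year-old clear-cuts and lakes; clustered stone
#' fields so that both chained (<= 1000 m) and isolated configurations occur;
#' one 1-ha sampling plot per sampled patch with a 10-station transect; and
#' vole occupancy driven by a stated logistic model in log patch area, log
#' connectivity and stone-field proximity, with station-level occurrence
#' driven by pine proportion and large stone holes around a plot random
#' intercept. Everything is deterministic under `(config, seed)`.
#'
#' @name synthetic_landscape
NULL

#' Configuration for the synthetic generator
#'
#' Defaults encode the emulated study conditions: 24 candidate forest patches
#' log-spaced over 2.6-2370 ha (the published patch-size range), 23 sampling
#' plots, 223 retained stations (10 per plot minus 7 random field losses),
#' positive effects of patch area, connectivity and stone proximity on plot
#' occupancy and of pine proportion and large stone holes on station
#' occurrence.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param nrow,ncol,cell_size grid shape and resolution (m).
#' @param patch_areas_ha target patch areas (ha).
#' @param forest_fraction_max cap on total forest cover (guard, not target).
#' @param clearcut_fraction,lake_fraction matrix composition.
#' @param n_stone_clusters,fields_per_cluster,stone_cluster_radius,stone_field_mean_ha,n_isolated_fields
#'   stone-field placement parameters.
#' @param n_plots number of sampling plots (one per sampled patch).
#' @param conn_distance dispersal threshold (m) used for the occupancy
#'   predictor `C`.
#' @param beta0,beta_area,beta_conn,beta_stone plot-occupancy logistic
#'   coefficients on `log(area_ha)`, `log(C + conn_eps)` and `-lcp_cost/1000`.
#' @param conn_eps offset added to `C` before the log (isolated patches have
#'   `C = 0`).
#' @param count_lambda mean of the zero-truncated Poisson for vole counts in
#'   occupied plots.
#' @param gamma0,gamma_pine,gamma_lsholes,sigma_u station-occurrence logistic
#'   coefficients (pine proportion in \[0,1\], large-stone-hole code / 10) and
#'   plot random-intercept SD.
#' @param drop_stations stations removed at random across the survey,
#'   emulating field losses (7 gives the study's n = 223).
#' @param stations_per_plot,traps_per_station,nights trapping design (10 x 5
#'   x 3 = 150 trap nights per plot).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             nrow = 400, ncol = 400, cell_size = 50,
                             patch_areas_ha = exp(seq(log(2.6), log(2370), length.out = 24)),
                             forest_fraction_max = 0.35,
                             clearcut_fraction = 0.12, lake_fraction = 0.05,
                             n_stone_clusters = 3,
                             fields_per_cluster = c(4, 7),
                             stone_cluster_radius = 500,
                             stone_field_mean_ha = 30,
                             n_isolated_fields = 2,
                             n_plots = 23,
                             conn_distance = 1000,
                             beta0 = 27, beta_area = 0.5, beta_conn = 2.5,
                             beta_stone = 2.2, conn_eps = 1e-4,
                             count_lambda = 6,
                             gamma0 = -4.2, gamma_pine = 4.5,
                             gamma_lsholes = 1.2, sigma_u = 1,
                             drop_stations = 7,
                             stations_per_plot = 10, traps_per_station = 5,
                             nights = 3) {
  cfg <- as.list(environment())
  if (clearcut_fraction + lake_fraction + forest_fraction_max > 1)
    stop("land-cover fractions exceed 1")
  if (sigma_u < 0) stop("sigma_u must be >= 0")
  if (cell_size <= 0 || nrow < 10 || ncol < 10) stop("invalid grid shape")
  structure(cfg, class = "synthetic_config")
}

# Grow an organic blob of ~target cells from a seed cell over free cells.
# 'free' is a logical matrix; returns linear indices of the blob.
grow_blob <- function(free, start, target, p_accept = 0.7) {
  nr <- nrow(free); nc <- ncol(free)
  mem <- matrix(FALSE, nr, nc)
  mem[start] <- TRUE
  frontier <- start
  size <- 1L
  repeat {
    if (size >= target) break
    if (!length(frontier)) {
      # rare: frontier exhausted while boundary cells still have free space
      b <- which(mem)
      frontier <- b
    }
    r <- (frontier - 1L) %% nr + 1L
    c <- (frontier - 1L) %/% nr + 1L
    cand <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
      cand <- c(cand, (c2[ok] - 1L) * nr + r2[ok])
    }
    cand <- unique(cand)
    cand <- cand[free[cand] & !mem[cand]]
    if (!length(cand)) break
    keep <- cand[stats::runif(length(cand)) < p_accept]
    if (!length(keep)) keep <- cand[sample.int(length(cand), 1)]
    if (size + length(keep) > target) keep <- keep[seq_len(target - size)]
    mem[keep] <- TRUE
    size <- size + length(keep)
    frontier <- keep
  }
  which(mem)
}

dilate1 <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    r2 <- r + dr; c2 <- c + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

#' Generate a synthetic landscape
#'
#' Places the configured forest patches (largest first, with a one-cell halo
#' so distinct patches never touch), clear-cut and lake blobs in the matrix,
#' assigns stand ages (patches 61-140 yr with some pine-dominated stands
#' >100 yr, clear-cuts 0-20 yr, other land 21-60 yr) and clustered stone
#' fields on an independent layer. Land-class codes: 1 old forest (>60 yr),
#' 2 old pine (>100 yr, facilitating movement), 3 young forest, 4 clear-cut
#' 0-20 yr (hindrance), 5 lake (hindrance).
#'
#' @param config a [synthetic_config()].
#' @return List with `age`, `landclass`, `stone` (`grid_raster`s; `stone`
#'   holds field ids, 0 elsewhere).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol; cell <- config$cell_size
  ncells <- nr * nc
  cell_ha <- cell^2 / 1e4
  claim <- matrix(0L, nr, nc)        # 0 free, -1 halo, >0 patch id
  budget <- floor(config$forest_fraction_max * ncells)
  used <- 0L
  areas <- sort(config$patch_areas_ha, decreasing = TRUE)
  patch_cells <- list()
  for (i in seq_along(areas)) {
    target <- max(4L, round(areas[i] / cell_ha))
    if (used + target > budget) target <- budget - used
    if (target < 4L) break
    free <- claim == 0L
    if (!any(free)) break
    start <- sample(which(free), 1)
    blob <- grow_blob(free, start, target)
    claim[blob] <- i
    claim[setdiff(dilate1(blob, nr, nc), blob)] <- -1L
    patch_cells[[i]] <- blob
    used <- used + length(blob)
  }
  # matrix elements: clear-cuts and lakes on non-forest cells
  age <- matrix(0L, nr, nc)
  landclass <- matrix(3L, nr, nc)    # young forest by default
  place_matrix_blobs <- function(frac, code) {
    goal <- floor(frac * ncells)
    got <- 0L
    guard <- 0L
    while (got < goal && guard < 200L) {
      guard <- guard + 1L
      free <- claim <= 0L & landclass == 3L
      if (!any(free)) break
      target <- min(goal - got, max(8L, round(stats::rlnorm(1, log(30 / cell_ha), 0.6))))
      blob <- grow_blob(free, sample(which(free), 1), target)
      landclass[blob] <<- code
      got <- got + length(blob)
    }
  }
  place_matrix_blobs(config$clearcut_fraction, 4L)
  place_matrix_blobs(config$lake_fraction, 5L)
  # ages
  age[landclass == 3L] <- sample(21:60, sum(landclass == 3L), replace = TRUE)
  age[landclass == 4L] <- sample(0:20, sum(landclass == 4L), replace = TRUE)
  for (i in seq_along(patch_cells)) {
    blob <- patch_cells[[i]]
    if (is.null(blob)) next
    mean_age <- stats::runif(1, 75, 130)
    a <- round(mean_age + stats::runif(length(blob), -12, 12))
    age[blob] <- pmin(pmax(a, 61L), 140L)
    landclass[blob] <- ifelse(age[blob] > 100, 2L, 1L)
  }
  age[landclass == 5L] <- 0L
  # stone fields: clustered blobs plus isolated singletons, own layer
  stone <- matrix(0L, nr, nc)
  fid <- 0L
  place_field <- function(center_rc, area_ha) {
    r <- min(max(center_rc[1], 2L), nr - 1L)
    c <- min(max(center_rc[2], 2L), nc - 1L)
    free <- stone == 0L
    if (!free[r, c]) return(invisible(NULL))
    fid <<- fid + 1L
    blob <- grow_blob(free, (c - 1L) * nr + r, max(4L, round(area_ha / cell_ha)))
    stone[blob] <<- fid
    invisible(NULL)
  }
  rad_cells <- config$stone_cluster_radius / cell
  # stone clusters are seeded at forest cells: boulder terrain is spared from
  # felling, so remnant old forest and stone fields co-occur spatially
  forest_idx <- which(claim > 0L)
  for (k in seq_len(config$n_stone_clusters)) {
    center <- if (length(forest_idx)) {
      i <- sample(forest_idx, 1)
      c((i - 1L) %% nr + 1L, (i - 1L) %/% nr + 1L)
    } else c(sample(seq(40L, nr - 40L), 1), sample(seq(40L, nc - 40L), 1))
    nf <- sample(config$fields_per_cluster[1]:config$fields_per_cluster[2], 1)
    for (f in seq_len(nf)) {
      off <- round(stats::rnorm(2, 0, rad_cells))
      place_field(center + off, stats::rlnorm(1, log(config$stone_field_mean_ha), 0.5))
    }
  }
  for (k in seq_len(config$n_isolated_fields)) {
    center <- c(sample(seq(20L, nr - 20L), 1), sample(seq(20L, nc - 20L), 1))
    place_field(center, stats::rlnorm(1, log(config$stone_field_mean_ha / 2), 0.5))
  }
  list(age = grid_raster(age, cell, 0, 0),
       landclass = grid_raster(landclass, cell, 0, 0),
       stone = grid_raster(stone, cell, 0, 0))
}

#' Place one 1-ha sampling plot per sampled patch
#'
#' Samples up to `n_plots` patches (without replacement, uniformly) and puts
#' the plot point — the transect midpoint of the 1-ha square — at the patch
#' cell nearest the patch centroid.
#'
#' @param patches a `patch_set`.
#' @param config a [synthetic_config()].
#' @return `data.frame` with `plot_id`, `x`, `y`, `patch_id`, `area_ha`.
#' @export
place_plots <- function(patches, config) {
  set.seed(config$seed + 1L)
  n <- min(config$n_plots, length(patches))
  sel <- sort(sample(seq_along(patches), n))
  rows <- lapply(seq_along(sel), function(i) {
    p <- patches[[sel[i]]]
    xy <- patch_xy(p, boundary = FALSE)
    ctr <- colMeans(xy)
    j <- which.min((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
    data.frame(plot_id = i, x = xy[j, 1], y = xy[j, 2],
               patch_id = p$id, area_ha = p$area_ha)
  })
  do.call(rbind, rows)
}

#' Simulate plot occupancy and vole counts
#'
#' Occupancy probability is `plogis(beta0 + beta_area * log(area_ha) +
#' beta_conn * log(C + conn_eps) + beta_stone * (-lcp_cost/1000))`; occupied
#' plots draw a vole count from a zero-truncated Poisson with mean
#' `count_lambda`, scaled by 150 trap nights into densities of the magnitude
#' seen in peak-year snap trapping.
#'
#' @param plots data frame from [place_plots()] with columns `area_ha`, `C`
#'   (area-normalized flux at the configured threshold) and `lcp_cost`.
#' @param config a [synthetic_config()].
#' @return `plots` with added `occupied` (0/1), `vole_count`, `trap_nights`,
#'   `density`.
#' @export
simulate_occupancy <- function(plots, config) {
  set.seed(config$seed + 2L)
  eta <- config$beta0 +
    config$beta_area * log(plots$area_ha) +
    config$beta_conn * log(plots$C + config$conn_eps) +
    config$beta_stone * (-plots$lcp_cost / 1000)
  plots$p_occ <- stats::plogis(eta)
  # plots without stone-field coverage carry NA predictors; occupancy stays
  # NA for them (missing, never imputed)
  plots$occupied <- as.integer(stats::runif(nrow(plots)) < plots$p_occ)
  lam <- config$count_lambda
  rztpois <- function(n, lambda)
    stats::qpois(stats::runif(n, stats::dpois(0, lambda), 1), lambda)
  plots$vole_count <- ifelse(plots$occupied == 1, rztpois(nrow(plots), lam), 0L)
  plots$trap_nights <- config$stations_per_plot * config$traps_per_station * config$nights
  plots$density <- NA_real_
  ok <- !is.na(plots$vole_count)
  plots$density[ok] <- density_index(plots$vole_count[ok], plots$trap_nights[ok])
  plots
}

sample_code <- function(n, codes, weights) {
  codes[sample.int(length(codes), n, replace = TRUE, prob = weights)]
}

#' Simulate the station-level microhabitat inventory
#'
#' Ten stations per plot with all 26 inventory covariates drawn from their
#' legal code sets. Stone-related covariates (stone and large-stone cover,
#' stone holes) are elevated near stone fields through a proximity score
#' `exp(-lcp_km / 1.5)`; pine proportion is drawn around a plot-level level;
#' every other covariate is inert (independent of occurrence). Station
#' occurrence follows `plogis(gamma0 + gamma_pine * pine + gamma_lsholes *
#' (ls_holes/10) + u_plot)` with `u_plot ~ N(0, sigma_u^2)`. `drop_stations`
#' stations are then removed at random (field losses; 7 leaves n = 223).
#'
#' @param plots data frame with `plot_id` and `lcp_cost` (cost units; used
#'   for the proximity score) — occupancy columns are not needed.
#' @param config a [synthetic_config()].
#' @return `data.frame` of station records: `plot_id`, `station`,
#'   `occurrence`, and the 26 covariates of [station_variable_info()].
#' @export
simulate_stations <- function(plots, config) {
  set.seed(config$seed + 3L)
  cs <- station_code_sets()
  info <- station_variable_info()
  nst <- config$stations_per_plot
  rows <- lapply(seq_len(nrow(plots)), function(i) {
    prox <- exp(-plots$lcp_cost[i] / 1000 / 1.5)   # 1 at a stone field, ~0 far away
    if (is.na(prox)) prox <- 0
    u <- stats::rnorm(1, 0, config$sigma_u)
    plot_pine <- stats::rbeta(1, 1.2, 1.2)
    st <- data.frame(plot_id = plots$plot_id[i], station = seq_len(nst))
    # cover-class weight profiles: a few widespread strata with real spread,
    # many sparse ones concentrated in the lowest classes (as in boreal
    # ground-structure inventories); stone covers shift up near stone fields
    spread_w <- c(1.5, 2.5, 2.5, 2, 1.5)
    sparse_w <- c(8, 2.5, 0.8, 0.3, 0.1)
    mid_w <- c(4, 3, 1.6, 0.9, 0.5)
    cover_w <- list(bilb = spread_w, cowb = c(2, 3, 2.5, 1.5, 1),
                    t_lichens = sparse_w, fwd = mid_w, lichens = sparse_w,
                    mosses = c(1, 2, 2.5, 3, 2), grasses = sparse_w,
                    u_veg = sparse_w, fl_veg = spread_w, lstones = NULL,
                    stones = NULL, bushes = sparse_w, tl1 = c(1, 2, 3, 2.5, 1.5),
                    tl2 = sparse_w)
    stone_w <- c(4, 2.5, 1.5, 0.8, 0.4) * (1 - prox) + c(1, 1.5, 2.5, 3, 3) * prox
    for (v in info$variable[info$scale == "cover5"]) {
      w <- cover_w[[v]]
      if (is.null(w)) w <- stone_w
      st[[v]] <- sample_code(nst, cs$cover5, w)
    }
    hole_w <- c(6, 2, 1, 0.7, 0.3)
    hole_w_near <- c(1.5, 2, 2.5, 2, 1.5)
    wmix <- hole_w * (1 - prox) + hole_w_near * prox
    st$s_holes <- sample_code(nst, cs$holes, wmix)
    st$l_holes <- sample_code(nst, cs$holes, wmix)
    ls_w <- c(5, 2.5, 1.5, 1, 0.6, 0.3) * (1 - prox) +
            c(0.6, 1.2, 2.2, 2.5, 2.2, 1.8) * prox
    st$ls_holes <- sample_code(nst, cs$holes_ls, ls_w)
    st$pine <- pmin(pmax(plot_pine + stats::rnorm(nst, 0, 0.15), 0), 1)
    rest <- pmax(1 - st$pine, 0)
    sh <- matrix(stats::rexp(nst * 5), nst)
    sh <- sh / rowSums(sh) * rest
    st$spruce <- sh[, 1]; st$birch <- sh[, 2]; st$aspen <- sh[, 3]
    st$g_willow <- sh[, 4]; st$other_trees <- sh[, 5]
    st$cwd <- round(stats::rexp(nst, 1 / 3), 1)
    st$snags <- stats::rpois(nst, 1.5)
    st$lstones_no <- stats::rpois(nst, 1 + 4 * prox)
    eta <- config$gamma0 + config$gamma_pine * st$pine +
      config$gamma_lsholes * (st$ls_holes / 10) + u
    st$occurrence <- as.integer(stats::runif(nst) < stats::plogis(eta))
    st
  })
  out <- do.call(rbind, rows)
  if (config$drop_stations > 0) {
    drop <- sample.int(nrow(out), min(config$drop_stations, nrow(out) - 1))
    out <- out[-drop, ]
  }
  rownames(out) <- NULL
  out[, c("plot_id", "station", "occurrence", station_variable_info()$variable)]
}
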