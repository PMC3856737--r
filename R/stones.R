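#' Stone fields, stone components, and least-cost-path distances
#'
#' Stone fields (open or forested areas with a pronounced amount of large
#' stones) are chained into network components: two fields belong to the same
#' component when they lie within a link radius (1000 m here) of each other,
#' directly or through intermediate fields. Components qualify for the
#' analysis when their total area strictly exceeds a minimum (100 ha here).
#' Distances from sampling plots to the nearest qualifying component are
#' reported both as straight-line metres and as accumulated least-cost-path
#' cost over a raster cost surface that penalizes young clear-cuts and lakes
#' and favours old pine forest.
#'
#' @name stone_analysis
NULL

#' Extract stone fields from a raster layer
#'
#' @param g `grid_raster`; cells not equal to nodata and non-zero belong to a
#'   stone field.
#' @param labeled if `TRUE` (default) cell values are field ids and fields are
#'   grouped by value; if `FALSE` the non-zero mask is split into 8-connected
#'   components.
#' @return List of class `stone_field_set`; each field has `id`, `cells`
#'   (row/col matrix), `area_ha` and the grid geometry.
#' @export
stone_fields_from_raster <- function(g, labeled = TRUE) {
  stopifnot(inherits(g, "grid_raster"))
  v <- g$values
  mask <- !is.na(v) & v != g$nodata & v != 0
  fields <- list()
  if (labeled) {
    ids <- sort(unique(v[mask]))
    for (i in seq_along(ids)) {
      w <- which(mask & v == ids[i])
      cells <- cbind(row = (w - 1L) %% nrow(v) + 1L, col = (w - 1L) %/% nrow(v) + 1L)
      fields[[i]] <- structure(
        list(id = as.integer(ids[i]), cells = cells,
             area_ha = nrow(cells) * g$cell_size^2 / 1e4,
             cell_size = g$cell_size, xll = g$xll, yll = g$yll,
             nrow = nrow(v), ncol = ncol(v)),
        class = "stone_field")
    }
  } else {
    lab <- label_patches(grid_raster(ifelse(mask, 1, 0), g$cell_size, g$xll, g$yll),
                         min_age = 0)
    fields <- lapply(lab, function(p) {
      structure(list(id = p$id, cells = p$cells, area_ha = p$area_ha,
                     cell_size = p$cell_size, xll = p$xll, yll = p$yll,
                     nrow = p$nrow, ncol = p$ncol), class = "stone_field")
    })
  }
  structure(fields, class = "stone_field_set")
}

field_xy <- function(f) {
  cbind(x = f$xll + (f$cells[, 2] - 0.5) * f$cell_size,
        y = f$yll + (f$nrow - f$cells[, 1] + 0.5) * f$cell_size)
}

field_distance <- function(f1, f2) {
  a <- field_xy(f1); b <- field_xy(f2)
  sqrt(min(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2))
}

#' Chain stone fields into network components
#'
#' Two fields are linked when their minimum edge-to-edge distance is at most
#' `link_radius`; components are the transitive closure of that relation, so
#' a chain A–B–C belongs to one component even when A and C are far apart.
#'
#' @param fields a `stone_field_set`.
#' @param link_radius chaining radius in metres (default 1000).
#' @return List of class `stone_component_set`; each component has
#'   `member_ids`, `total_area_ha`, and `qualifying = NA` until filtered.
#' @export
build_stone_components <- function(fields, link_radius = 1000) {
  stopifnot(link_radius > 0)
  n <- length(fields)
  if (!n) return(structure(list(), class = "stone_component_set"))
  el <- NULL
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    keep <- apply(pairs, 2, function(p)
      field_distance(fields[[p[1]]], fields[[p[2]]]) <= link_radius)
    el <- pairs[, keep, drop = FALSE]
  }
  g <- igraph::make_graph(if (is.null(el)) integer(0) else as.vector(el),
                          n = n, directed = FALSE)
  memb <- igraph::components(g)$membership
  comps <- lapply(sort(unique(memb)), function(m) {
    sel <- which(memb == m)
    structure(list(
      member_ids = vapply(fields[sel], `[[`, 0L, "id"),
      members = fields[sel],
      total_area_ha = sum(vapply(fields[sel], `[[`, 0, "area_ha")),
      qualifying = NA), class = "stone_component")
  })
  structure(comps, class = "stone_component_set")
}

#' Filter stone components on total area
#'
#' Strictly-greater-than filter: a component of exactly `min_component_area`
#' ha is excluded.
#'
#' @param components a `stone_component_set`.
#' @param min_component_area minimum total area in ha (default 100).
#' @return The qualifying components, `qualifying` flag set to `TRUE`.
#' @export
filter_components <- function(components, min_component_area = 100) {
  keep <- vapply(components, function(cp) cp$total_area_ha > min_component_area, TRUE)
  out <- lapply(components[keep], function(cp) { cp$qualifying <- TRUE; cp })
  structure(out, class = "stone_component_set")
}

#' Build a traversal-cost surface from a land-class raster
#'
#' @param landclass `grid_raster` of integer land-class codes.
#' @param cost_map named numeric vector mapping class codes (as names) to
#'   per-cell cost multipliers; codes absent from the map get `baseline`.
#'   Defaults preserve the analysis' ordering: old pine (>100 yr) facilitates
#'   movement (0.5), young clear-cuts (0–20 yr) and lakes hinder it (10),
#'   everything else costs 1 per metre.
#' @param baseline cost for unmapped codes.
#' @return `grid_raster` of per-cell costs (dimensionless multipliers applied
#'   to metres crossed).
#' @export
cost_surface <- function(landclass,
                         cost_map = c("2" = 0.5, "4" = 10, "5" = 10),
                         baseline = 1) {
  out <- landclass
  v <- matrix(baseline, nrow(landclass$values), ncol(landclass$values))
  for (code in names(cost_map)) v[landclass$values == as.numeric(code)] <- cost_map[[code]]
  v[landclass$values == landclass$nodata] <- Inf
  out$values <- v
  out$nodata <- -9999
  out
}

# Weighted 8-neighbour lattice edges over finite-cost cells.
cost_lattice_edges <- function(cost, vid) {
  nr <- nrow(cost$values); nc <- ncol(cost$values)
  fin <- is.finite(cost$values)
  off <- adjacency_offsets(8)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    step <- cost$cell_size * sqrt(dr^2 + dc^2)
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- fin[r1, c1, drop = FALSE] & fin[r1 + dr, c1 + dc, drop = FALSE]
    if (any(a)) {
      wh <- which(a)
      rr <- r1[(wh - 1L) %% length(r1) + 1L]
      cc <- c1[(wh - 1L) %/% length(r1) + 1L]
      i1 <- cbind(rr, cc); i2 <- cbind(rr + dr, cc + dc)
      from <- c(from, vid[i1]); to <- c(to, vid[i2])
      w <- c(w, (cost$values[i1] + cost$values[i2]) / 2 * step)
    }
  }
  list(from = from, to = to, weight = w)
}

#' Accumulated least-cost distance from a set of source cells
#'
#' Dijkstra's algorithm over the 8-neighbour lattice: the cost of moving
#' between adjacent cells is the mean of their per-cell costs times the step
#' length (`cell_size`, or `cell_size * sqrt(2)` diagonally). Source cells
#' start at 0; cells unreachable without crossing infinite-cost cells get
#' `Inf`. This is the conventional GIS cost-distance semantics, so on a
#' uniform cost of 1 the result approximates Euclidean metres from the source
#' set (octile-metric overestimate at most ~8.3%).
#'
#' @param surface `grid_raster` of per-cell costs (>= 0, `Inf` = barrier).
#' @param sources 2-column matrix of row/col indices of source cells.
#' @return `grid_raster` of accumulated cost.
#' @export
cost_distance <- function(surface, sources) {
  stopifnot(inherits(surface, "grid_raster"))
  sources <- matrix(as.integer(sources), ncol = 2)
  fin <- is.finite(surface$values)
  src_fin <- fin[sources]
  if (!any(src_fin)) stop("all source cells have infinite cost")
  sources <- sources[src_fin, , drop = FALSE]
  k <- sum(fin)
  vid <- matrix(0L, nrow(surface$values), ncol(surface$values))
  vid[fin] <- seq_len(k)
  el <- cost_lattice_edges(surface, vid)
  virt <- k + 1L
  from <- c(el$from, rep(virt, nrow(sources)))
  to <- c(el$to, vid[sources])
  w <- c(el$weight, rep(0, nrow(sources)))
  g <- igraph::make_graph(rbind(from, to), n = virt, directed = FALSE)
  d <- igraph::distances(g, v = virt, weights = w)[1, seq_len(k)]
  out <- surface
  out$values <- matrix(Inf, nrow(surface$values), ncol(surface$values))
  out$values[fin] <- d
  out
}

xy_to_cell <- function(g, x, y) {
  col <- pmin(pmax(floor((x - g$xll) / g$cell_size) + 1L, 1L), ncol(g$values))
  row <- pmin(pmax(nrow(g$values) - floor((y - g$yll) / g$cell_size), 1L), nrow(g$values))
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Euclidean and least-cost distances from plots to stone components
#'
#' For each sampling plot, the straight-line distance to the nearest cell of
#' any qualifying stone component and the accumulated least-cost-path cost at
#' the plot's cell, with every qualifying-component cell acting as a Dijkstra
#' source. Plots are represented by a single point (the transect midpoint).
#'
#' @param plots data frame with `plot_id`, `x`, `y` (metres).
#' @param components a `stone_component_set` of qualifying components (see
#'   [filter_components()]); must be non-empty.
#' @param surface cost surface `grid_raster` (see [cost_surface()]); when
#'   `NULL`, only Euclidean distances are reported.
#' @return `data.frame` with `plot_id`, `euclid_m`, `lcp_cost`,
#'   `nearest_component_id`.
#' @export
plot_to_component_distances <- function(plots, components, surface = NULL) {
  if (!length(components)) stop("no qualifying stone components")
  comp_xy <- lapply(components, function(cp) do.call(rbind, lapply(cp$members, field_xy)))
  euclid <- numeric(nrow(plots)); nearest <- integer(nrow(plots))
  for (i in seq_len(nrow(plots))) {
    dmin <- vapply(comp_xy, function(xy)
      sqrt(min((xy[, 1] - plots$x[i])^2 + (xy[, 2] - plots$y[i])^2)), 0)
    nearest[i] <- which.min(dmin)
    euclid[i] <- min(dmin)
    # a plot inside a component cell is at distance 0
    ref <- components[[nearest[i]]]$members[[1]]
    if (euclid[i] <= ref$cell_size / sqrt(2) + 1e-9) {
      cell <- xy_to_cell(list(values = matrix(0, ref$nrow, ref$ncol),
                              cell_size = ref$cell_size, xll = ref$xll, yll = ref$yll),
                         plots$x[i], plots$y[i])
      inside <- any(vapply(components[[nearest[i]]]$members, function(f)
        any(f$cells[, 1] == cell[1] & f$cells[, 2] == cell[2]), TRUE))
      if (inside) euclid[i] <- 0
    }
  }
  lcp <- rep(NA_real_, nrow(plots))
  if (!is.null(surface)) {
    src <- do.call(rbind, lapply(components, function(cp)
      do.call(rbind, lapply(cp$members, `[[`, "cells"))))
    acc <- cost_distance(surface, src)
    cells <- xy_to_cell(acc, plots$x, plots$y)
    lcp <- acc$values[cells]
  }
  data.frame(plot_id = plots$plot_id, euclid_m = euclid, lcp_cost = lcp,
             nearest_component_id = nearest)
}
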