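#' Habitat graph constructors and the integral index of connectivity (IIC)
#'
#' The landscape is abstracted as a graph whose nodes are forest patches with
#' areas \eqn{a_i} (ha) and whose edges join patches whose edge-to-edge
#' distance does not exceed a dispersal threshold \eqn{d}. Habitat
#' availability is measured by the integral index of connectivity,
#' \deqn{IIC = \sum_i \sum_j \frac{a_i a_j}{1 + nl_{ij}} / A_L^2,}
#' where \eqn{nl_{ij}} is the minimum number of links between patches i and j
#' (0 on the diagonal, infinite — contributing 0 — for disconnected pairs) and
#' \eqn{A_L} the total landscape area. Patch importance dIIC is the percentage
#' drop in IIC when a patch is removed, and decomposes into intra, flux and
#' connector fractions. The analysis' connectivity predictor is the flux
#' fraction divided by focal patch area (`C = dIICflux / a_k`), which breaks
#' the collinearity between flux and patch area.
#'
#' @name connectivity
NULL

new_habitat_graph <- function(ids, areas, edges, d) {
  o <- order(ids)
  ids <- as.integer(ids[o]); areas <- as.numeric(areas[o])
  if (anyDuplicated(ids)) stop("duplicate patch ids")
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  if (nrow(edges)) {
    g <- igraph::make_graph(rbind(idx[as.character(edges$from)],
                                  idx[as.character(edges$to)]),
                            n = n, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  }
  nl <- igraph::distances(g, algorithm = "unweighted")
  dimnames(nl) <- list(ids, ids)
  structure(list(ids = ids, areas = areas, edges = edges, d = d, nl = nl),
            class = "habitat_graph")
}

#' @export
print.habitat_graph <- function(x, ...) {
  cat(sprintf("<habitat_graph> %d patches, %d edges, threshold %g m\n",
              length(x$ids), nrow(x$edges), x$d))
  invisible(x)
}

#' Build the dispersal-threshold habitat graph
#'
#' Patches whose minimum edge-to-edge distance is at most `d` metres are
#' linked. Minimum link counts `nl` between all pairs are computed by
#' breadth-first search (infinite for pairs in different components).
#'
#' @param patches a `patch_set` (see [label_patches()]).
#' @param d dispersal threshold in metres, > 0.
#' @param dist_matrix optional precomputed [patch_distance_matrix()] (its
#'   pruning distance must be at least `d`); computed when missing.
#' @return A `habitat_graph` with fields `ids`, `areas` (ha), `edges`
#'   (`from`, `to`, `distance`), `d`, and the `nl` matrix.
#' @export
build_graph <- function(patches, d, dist_matrix = NULL) {
  stopifnot(d > 0)
  ids <- vapply(patches, `[[`, 0L, "id")
  areas <- vapply(patches, `[[`, 0, "area_ha")
  if (is.null(dist_matrix)) dist_matrix <- patch_distance_matrix(patches, max_distance = d)
  edges <- which(upper.tri(dist_matrix) & dist_matrix <= d, arr.ind = TRUE)
  edges <- data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                      distance = dist_matrix[edges])
  new_habitat_graph(ids, areas, edges, d)
}

#' Habitat graph from explicit node and edge tables
#'
#' Convenience constructor for abstract graphs (tests, worked examples) where
#' patch geometry is irrelevant: nodes carry areas, edges carry distances.
#'
#' @param ids integer patch ids.
#' @param areas patch areas in ha.
#' @param edges data frame with columns `from`, `to` and optionally
#'   `distance` (defaults to 0).
#' @param d nominal dispersal threshold recorded on the graph.
#' @return A `habitat_graph`.
#' @export
habitat_graph <- function(ids, areas, edges = NULL, d = Inf) {
  if (is.null(edges)) edges <- data.frame(from = integer(0), to = integer(0))
  if (is.null(edges$distance)) edges$distance <- rep(0, nrow(edges))
  new_habitat_graph(ids, areas, edges, d)
}

graph_without <- function(graph, k) {
  keep <- graph$ids != k
  e <- graph$edges
  e <- e[e$from != k & e$to != k, , drop = FALSE]
  new_habitat_graph(graph$ids[keep], graph$areas[keep], e, graph$d)
}

#' IIC numerator of a habitat graph
#'
#' \eqn{\sum_i \sum_j a_i a_j / (1 + nl_{ij})} in ha^2, both orderings of each
#' pair counted and self-terms contributing \eqn{a_i^2}; disconnected pairs
#' contribute 0. Summation runs in ascending patch id order so the result is
#' bit-deterministic.
#'
#' @param graph a `habitat_graph`.
#' @return Numerator in ha^2.
#' @export
iic_numerator <- function(graph) {
  if (!length(graph$ids)) stop("graph is empty")
  w <- 1 / (1 + graph$nl)          # 0 where nl = Inf
  a <- graph$areas
  sum((a %o% a) * w)
}

#' IIC on [0, 1]
#'
#' @param graph a `habitat_graph`.
#' @param landscape_area_ha total landscape area \eqn{A_L} in ha.
#' @return `iic_numerator(graph) / landscape_area_ha^2`.
#' @export
iic <- function(graph, landscape_area_ha) {
  iic_numerator(graph) / landscape_area_ha^2
}

#' dIIC of a patch and its intra/flux/connector fractions
#'
#' `dIIC` is the percentage drop in the IIC numerator when patch `k` is
#' removed (minimum link counts recomputed on the reduced graph). The intra
#' fraction is the patch's own-area term, the flux fraction collects both
#' orderings of pairs involving `k` with other patches (link counts of the
#' intact graph), and the connector fraction is the remainder — the patch's
#' role as a stepping stone between other patches.
#'
#' @param graph a `habitat_graph`.
#' @param k patch id.
#' @return Named numeric vector `dIIC`, `dIICintra`, `dIICflux`,
#'   `dIICconnector`, all in percent of the intact IIC.
#' @export
iic_fractions <- function(graph, k) {
  pos <- match(k, graph$ids)
  if (is.na(pos)) stop("unknown patch id: ", k)
  num <- iic_numerator(graph)
  num_minus <- if (length(graph$ids) > 1) iic_numerator(graph_without(graph, k)) else 0
  dIIC <- 100 * (num - num_minus) / num
  intra <- 100 * graph$areas[pos]^2 / num
  w <- 1 / (1 + graph$nl[pos, -pos])
  flux <- 100 * 2 * sum(graph$areas[pos] * graph$areas[-pos] * w) / num
  c(dIIC = dIIC, dIICintra = intra, dIICflux = flux,
    dIICconnector = dIIC - intra - flux)
}

#' Area-normalized flux fraction of a focal patch
#'
#' The analysis' connectivity predictor `C = dIICflux / area` (percent per
#' ha): potential dispersal flux to and from the focal patch, normalized by
#' its area to remove the flux–area collinearity.
#'
#' @param graph a `habitat_graph`.
#' @param k patch id with positive area.
#' @return `C` in percent per ha.
#' @export
flux_per_area <- function(graph, k) {
  pos <- match(k, graph$ids)
  if (is.na(pos)) stop("unknown patch id: ", k)
  if (graph$areas[pos] <= 0) stop("patch area must be > 0")
  unname(iic_fractions(graph, k)["dIICflux"] / graph$areas[pos])
}

#' Patch importance table across dispersal thresholds
#'
#' Builds the habitat graph at each threshold and reports dIIC and its
#' fractions plus `C = dIICflux/area` for every patch.
#'
#' @param patches a `patch_set`.
#' @param thresholds dispersal thresholds in metres (default the six distances
#'   250, 500, 1000, 1500, 2000, 3000 spanning published vole dispersal
#'   estimates).
#' @param dist_matrix optional precomputed distance matrix with pruning
#'   distance at least `max(thresholds)`.
#' @return `data.frame` with `d`, `patch_id`, `area_ha`, `dIIC`, `dIICintra`,
#'   `dIICflux`, `dIICconnector`, `C`.
#' @export
connectivity_table <- function(patches,
                               thresholds = c(250, 500, 1000, 1500, 2000, 3000),
                               dist_matrix = NULL) {
  if (!length(thresholds)) stop("threshold list is empty")
  if (is.null(dist_matrix))
    dist_matrix <- patch_distance_matrix(patches, max_distance = max(thresholds))
  out <- lapply(sort(thresholds), function(d) {
    g <- build_graph(patches, d, dist_matrix = dist_matrix)
    fr <- t(vapply(g$ids, function(k) iic_fractions(g, k), numeric(4)))
    data.frame(d = d, patch_id = g$ids, area_ha = g$areas, fr,
               C = fr[, "dIICflux"] / g$areas)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
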