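#' Write Conefor node and connection files
#'
#' Serializes a habitat graph to the two plain-text formats used by the
#' Conefor connectivity software: a node file with one `id<TAB>area` line per
#' patch and a connection file with one `id1<TAB>id2<TAB>distance` line per
#' undirected patch pair within the dispersal threshold, each pair written
#' once with `id1 < id2`. Lines are sorted by id so output is deterministic.
#'
#' @param graph a `habitat_graph` (see [build_graph()]).
#' @param node_path,conn_path output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_conefor_files <- function(graph, node_path, conn_path) {
  stopifnot(inherits(graph, "habitat_graph"))
  ids <- graph$ids
  if (anyDuplicated(ids)) stop("duplicate node ids in graph")
  if (length(ids) < 1) stop("graph has no nodes")
  o <- order(ids)
  writeLines(sprintf("%d\t%s", ids[o], format(graph$areas[o], scientific = FALSE, trim = TRUE, digits = 15)),
             node_path)
  e <- graph$edges
  if (nrow(e)) {
    i1 <- pmin(e$from, e$to); i2 <- pmax(e$from, e$to)
    o <- order(i1, i2)
    writeLines(sprintf("%d\t%d\t%s", i1[o], i2[o],
                       format(e$distance[o], scientific = FALSE, trim = TRUE, digits = 15)),
               conn_path)
  } else {
    writeLines(character(0), conn_path)
  }
  invisible(list(node_path = node_path, conn_path = conn_path))
}

#' Read Conefor node and connection files back into a habitat graph
#'
#' @param node_path,conn_path paths written by [write_conefor_files()] (or by
#'   Conefor-compatible tools).
#' @param d dispersal threshold (m) to record on the graph; defaults to the
#'   maximum connection distance present (or `Inf` when there are none).
#' @return A `habitat_graph`.
#' @export
read_conefor_files <- function(node_path, conn_path, d = NULL) {
  nodes <- utils::read.table(node_path, col.names = c("id", "area"))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids in node file")
  edges <- if (file.size(conn_path) > 0)
    utils::read.table(conn_path, col.names = c("from", "to", "distance"))
  else data.frame(from = integer(0), to = integer(0), distance = numeric(0))
  if (is.null(d)) d <- if (nrow(edges)) max(edges$distance) else Inf
  new_habitat_graph(as.integer(nodes$id), nodes$area, edges, d)
}
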