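#' Reclassify recently cut cells as clear-cuts in the stand-age raster
#'
#' Cells flagged in the clear-cut mask get age 0; all other cells are
#' untouched. Used to bring a stand-age raster up to date with felling that
#' post-dates the underlying forest survey.
#'
#' @param age stand-age `grid_raster` (years).
#' @param clearcut_mask congruent `grid_raster`, non-zero where cells were cut.
#' @return The updated stand-age `grid_raster`.
#' @export
reclassify_clearcuts <- function(age, clearcut_mask) {
  stopifnot(inherits(age, "grid_raster"), inherits(clearcut_mask, "grid_raster"))
  stopifnot_congruent(age, clearcut_mask)
  out <- age
  m <- clearcut_mask$values != 0 & clearcut_mask$values != clearcut_mask$nodata
  out$values[m] <- 0
  out
}

# Half-plane neighbour offsets (dr, dc); the other half is implied by symmetry.
adjacency_offsets <- function(adjacency) {
  if (adjacency == 4) cbind(dr = c(0, 1), dc = c(1, 0))
  else if (adjacency == 8) cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))
  else stop("adjacency must be 4 or 8")
}

# Undirected edges between TRUE cells of a logical matrix under the given
# adjacency, as a 2-column matrix of vertex ids taken from 'vid' (an integer
# matrix with 0 for non-vertices).
lattice_edges <- function(mask, vid, adjacency = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  off <- adjacency_offsets(adjacency)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]; dc <- off[k, 2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (any(a)) {
      w <- which(a)
      rr <- r1[(w - 1L) %% length(r1) + 1L]
      cc <- c1[(w - 1L) %/% length(r1) + 1L]
      from <- c(from, vid[cbind(rr, cc)])
      to <- c(to, vid[cbind(rr + dr, cc + dc)])
    }
  }
  cbind(from, to)
}

#' Delineate patches of old forest from a stand-age raster
#'
#' Cells strictly older than `min_age` are partitioned into connected
#' components under the configured adjacency (8-connectivity by default, i.e.
#' diagonally touching stands merge). Patch ids are assigned in reading order
#' (top row first, left to right) of each patch's first cell, so labelling is
#' deterministic. Boundary cells are patch cells with at least one
#' non-patch neighbour (off-grid counts as non-patch).
#'
#' @param age stand-age `grid_raster` (years); nodata cells never qualify.
#' @param min_age age threshold in years; qualification is `age > min_age`.
#' @param adjacency 4 or 8 (default 8).
#' @return A list of class `patch_set`; each element is a `patch` with fields
#'   `id`, `cells` (2-column matrix of row/col indices), `boundary` (subset of
#'   `cells`), `area_ha`, and the grid geometry (`cell_size`, `xll`, `yll`,
#'   `nrow`, `ncol`).
#' @export
label_patches <- function(age, min_age = 60, adjacency = 8) {
  stopifnot(inherits(age, "grid_raster"))
  v <- age$values
  mask <- !is.na(v) & v != age$nodata & v > min_age
  k <- sum(mask)
  if (k == 0) return(structure(list(), class = "patch_set"))
  vid <- matrix(0L, nrow(v), ncol(v))
  vid[mask] <- seq_len(k)
  el <- lattice_edges(mask, vid, adjacency)
  g <- igraph::make_graph(t(el), n = k, directed = FALSE)
  memb <- igraph::components(g)$membership
  # relabel components in reading order of first occurrence
  w <- which(mask)                       # column-major order
  rr <- (w - 1L) %% nrow(v) + 1L
  cc <- (w - 1L) %/% nrow(v) + 1L
  ord <- order(rr, cc)                   # reading order
  relabel <- integer(max(memb))
  nxt <- 0L
  for (i in ord) {               # i is the vid of the cell at (rr[i], cc[i])
    m <- memb[i]
    if (relabel[m] == 0L) { nxt <- nxt + 1L; relabel[m] <- nxt }
  }
  lab <- relabel[memb]
  patches <- vector("list", nxt)
  for (p in seq_len(nxt)) {
    sel <- which(lab == p)   # vid indices; rr/cc are indexed by vid
    cells <- cbind(row = rr[sel], col = cc[sel])
    patches[[p]] <- new_patch(p, cells, age, mask, adjacency)
  }
  structure(patches, class = "patch_set")
}

new_patch <- function(id, cells, g, mask, adjacency) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  off <- adjacency_offsets(adjacency)
  off <- rbind(off, -off)
  is_boundary <- rep(FALSE, nrow(cells))
  for (k in seq_len(nrow(off))) {
    r2 <- cells[, 1] + off[k, 1]; c2 <- cells[, 2] + off[k, 2]
    outside <- r2 < 1 | r2 > nr | c2 < 1 | c2 > nc
    nb <- rep(FALSE, nrow(cells))
    nb[!outside] <- !mask[cbind(r2[!outside], c2[!outside])]
    is_boundary <- is_boundary | outside | nb
  }
  structure(
    list(id = id, cells = cells, boundary = cells[is_boundary, , drop = FALSE],
         area_ha = nrow(cells) * g$cell_size^2 / 1e4,
         cell_size = g$cell_size, xll = g$xll, yll = g$yll, nrow = nr, ncol = nc),
    class = "patch"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches, total %.2f ha\n",
              length(x), sum(vapply(x, `[[`, 0, "area_ha"))))
  invisible(x)
}

patch_xy <- function(p, boundary = TRUE) {
  cells <- if (boundary) p$boundary else p$cells
  cbind(x = p$xll + (cells[, 2] - 0.5) * p$cell_size,
        y = p$yll + (p$nrow - cells[, 1] + 0.5) * p$cell_size)
}

#' Minimum edge-to-edge distance between two patches
#'
#' Minimum Euclidean distance between cell centres of the two patches'
#' boundary cells, computed exactly (chunked so large patch pairs stay within
#' memory). Symmetric in its arguments.
#'
#' @param p,q `patch` objects from the same grid.
#' @return Distance in metres.
#' @export
edge_to_edge_distance <- function(p, q) {
  if (p$id == q$id) stop("p and q must be distinct patches")
  a <- patch_xy(p); b <- patch_xy(q)
  best <- Inf
  chunk <- max(1L, floor(4e6 / nrow(b)))
  for (s in seq(1, nrow(a), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(a))
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Pairwise edge-to-edge distances for a patch set
#'
#' Exact for all pairs closer than `max_distance`; pairs whose bounding boxes
#' are provably farther apart are reported as `Inf` without computing the full
#' cross-distance (they cannot form graph edges at any threshold of interest).
#'
#' @param patches a `patch_set`.
#' @param max_distance pruning distance in metres (default `Inf` = fully exact).
#' @return Symmetric matrix of distances (m), `0` on the diagonal, dimnames =
#'   patch ids.
#' @export
patch_distance_matrix <- function(patches, max_distance = Inf) {
  n <- length(patches)
  ids <- vapply(patches, `[[`, 0L, "id")
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  if (n < 2) return(D)
  xy <- lapply(patches, patch_xy)
  bb <- t(vapply(xy, function(m) c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2])),
                 numeric(4)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    gx <- max(0, max(bb[i, 1], bb[j, 1]) - min(bb[i, 2], bb[j, 2]))
    gy <- max(0, max(bb[i, 3], bb[j, 3]) - min(bb[i, 4], bb[j, 4]))
    if (sqrt(gx^2 + gy^2) > max_distance) next
    D[i, j] <- D[j, i] <- edge_to_edge_distance(patches[[i]], patches[[j]])
  }
  D
}

#' Summarize a patch set as a data frame
#'
#' @param patches a `patch_set`.
#' @return `data.frame` with `id`, `area_ha`, `n_cells`, and centroid `x`, `y`.
#' @export
patch_table <- function(patches) {
  if (!length(patches))
    return(data.frame(id = integer(0), area_ha = numeric(0), n_cells = integer(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(patches, function(p) {
    xy <- patch_xy(p, boundary = FALSE)
    data.frame(id = p$id, area_ha = p$area_ha, n_cells = nrow(p$cells),
               x = mean(xy[, 1]), y = mean(xy[, 2]))
  }))
}

#' Patch labels as a raster
#'
#' @param patches a `patch_set`.
#' @param template `grid_raster` giving the geometry (the age raster used for
#'   labelling).
#' @return `grid_raster` of patch ids, nodata outside patches.
#' @export
patch_label_raster <- function(patches, template) {
  out <- template
  out$values[] <- out$nodata
  for (p in patches) out$values[p$cells] <- p$id
  out
}
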