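# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (igraph, MASS, stats::fisher.test, ...).

# Recursive flood fill labelling of a logical matrix (4- or 8-adjacency).
flood_fill_labels <- function(mask, adjacency = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (adjacency == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        r2 <- cur[1] + o[1]; c2 <- cur[2] + o[2]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# All-pairs minimum hop counts by Floyd-Warshall on an edge list.
floyd_warshall_hops <- function(n, edges) {
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges[i, 1], edges[i, 2]] <- 1
    d[edges[i, 2], edges[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# IIC numerator by explicit double loop over ordered pairs.
iic_numerator_brute <- function(areas, nl) {
  s <- 0
  n <- length(areas)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (is.finite(nl[i, j])) s <- s + areas[i] * areas[j] / (1 + nl[i, j])
  s
}

# Random abstract habitat graph on n nodes (unit box geometry irrelevant).
rand_graph <- function(n, p_edge = 0.35, area_range = c(0.5, 20)) {
  ids <- seq_len(n)
  areas <- stats::runif(n, area_range[1], area_range[2])
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  habitat_graph(ids, areas,
                data.frame(from = pairs[keep, 1], to = pairs[keep, 2]))
}

# Bellman-Ford over the 8-neighbour lattice with average-cost edge weights;
# mirrors the cost-distance semantics with plain relaxation sweeps.
bellman_ford_cost <- function(cost, sources, cell_size) {
  nr <- nrow(cost); nc <- ncol(cost)
  idx <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.finite(cost[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.finite(cost[r2, c2])) next
      from <- c(from, idx(r, c)); to <- c(to, idx(r2, c2))
      w <- c(w, (cost[r, c] + cost[r2, c2]) / 2 * cell_size * sqrt(dr^2 + dc^2))
    }
  }
  d <- rep(Inf, nr * nc)
  d[idx(sources[, 1], sources[, 2])] <- 0
  repeat {
    cand <- d[from] + w
    upd <- tapply(cand, to, min)
    nd <- d
    tgt <- as.integer(names(upd))
    nd[tgt] <- pmin(nd[tgt], upd)
    if (identical(nd, d)) break
    d <- nd
  }
  matrix(d, nr, nc)
}

# Hypergeometric enumeration of the two-sided Fisher p for a 2x2 table.
fisher_brute <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  a_range <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(a_range, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# QDA posterior scores by direct Gaussian density evaluation.
qda_brute_predict <- function(train_x, train_g, test_x, priors = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  groups <- sort(unique(train_g))
  if (is.null(priors)) priors <- as.vector(table(factor(train_g, groups))) / length(train_g)
  score <- sapply(seq_along(groups), function(gi) {
    sel <- train_g == groups[gi]
    mu <- colMeans(train_x[sel, , drop = FALSE])
    S <- stats::cov(train_x[sel, , drop = FALSE])
    Sinv <- solve(S)
    apply(test_x, 1, function(x)
      -0.5 * determinant(S, logarithm = TRUE)$modulus -
        0.5 * t(x - mu) %*% Sinv %*% (x - mu) + log(priors[gi]))
  })
  groups[apply(matrix(score, nrow = nrow(test_x)), 1, which.max)]
}

# Small raster helper for fixtures.
toy_raster <- function(values, cell_size = 25, xll = 0, yll = 0) {
  grid_raster(values, cell_size, xll, yll)
}

# Three single-cell patches on one row, 300 m apart centre-to-centre (cell
# 25 m: columns 1, 13, 25).
collinear_patches <- function() {
  m <- matrix(0, 3, 25)
  m[2, c(1, 13, 25)] <- 80
  label_patches(toy_raster(m), min_age = 60)
}
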