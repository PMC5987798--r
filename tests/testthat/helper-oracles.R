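# Independent brute-force oracles used across tests. They deliberately avoid
# the package's own code paths (igraph, FISTA): distances by Floyd-Warshall,
# betweenness by exhaustive simple-path enumeration, communicability by a
# truncated Taylor series, the elastic net by dense grid minimisation.

# all-pairs shortest path lengths on edge lengths 1/w, Floyd-Warshall
bf_distances <- function(W) {
  R <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  for (k in seq_len(R)) {
    for (i in seq_len(R)) {
      for (j in seq_len(R)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_global_efficiency <- function(W) {
  d <- bf_distances(W)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (nrow(W) * (nrow(W) - 1))
}

# enumerate all simple paths s -> t and keep those of minimal total length
bf_shortest_path_set <- function(W, s, t, tol = 1e-9) {
  R <- nrow(W)
  paths <- list()
  lens <- numeric(0)
  walk <- function(path, len) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      lens[length(lens) + 1L] <<- len
      return(invisible())
    }
    for (u in seq_len(R)) {
      if (W[v, u] > 0 && !(u %in% path)) {
        walk(c(path, u), len + 1 / W[v, u])
      }
    }
  }
  walk(s, 0)
  if (!length(paths)) return(list(paths = list(), length = Inf))
  dmin <- min(lens)
  list(paths = paths[lens <= dmin + tol], length = dmin)
}

# unnormalised node and edge betweenness over unordered pairs, fractional ties
bf_betweenness <- function(W) {
  R <- nrow(W)
  node <- numeric(R)
  edge <- matrix(0, R, R)
  for (s in seq_len(R - 1)) {
    for (t in (s + 1):R) {
      sp <- bf_shortest_path_set(W, s, t)
      np <- length(sp$paths)
      if (np == 0) next
      for (p in sp$paths) {
        inner <- setdiff(p, c(s, t))
        node[inner] <- node[inner] + 1 / np
        for (k in seq_len(length(p) - 1)) {
          edge[p[k], p[k + 1]] <- edge[p[k], p[k + 1]] + 1 / np
          edge[p[k + 1], p[k]] <- edge[p[k + 1], p[k]] + 1 / np
        }
      }
    }
  }
  list(node = node, edge = edge)
}

bf_onnela_clustering <- function(W) {
  R <- nrow(W)
  mx <- max(W)
  out <- numeric(R)
  if (mx == 0) return(out)
  for (u in seq_len(R)) {
    k <- sum(W[u, ] > 0)
    if (k < 2) next
    acc <- 0
    for (v in seq_len(R)) {
      for (w in seq_len(R)) {
        if (v != u && w != u && v != w) {
          acc <- acc + (W[u, v] * W[v, w] * W[w, u] / mx^3)^(1 / 3)
        }
      }
    }
    out[u] <- acc / (k * (k - 1))
  }
  out
}

# communicability row sums via a 50-term Taylor series of the normalised
# adjacency
bf_communicability <- function(W, terms = 50) {
  diag(W) <- 0
  s <- rowSums(W)
  s[s == 0] <- 1
  A <- W / sqrt(s %o% s)
  G <- diag(nrow(W))
  P <- diag(nrow(W))
  for (k in seq_len(terms)) {
    P <- P %*% A / k
    G <- G + P
  }
  rowSums(G)
}

# random symmetric weighted graph with continuous weights (no ties)
random_weight_matrix <- function(R, p_edge = 0.6) {
  W <- matrix(0, R, R)
  ut <- upper.tri(W)
  on <- runif(sum(ut)) < p_edge
  w <- ifelse(on, runif(sum(ut), 0.2, 5), 0)
  W[ut] <- w
  W + t(W)
}

# dense two-stage grid minimisation of the elastic-net objective (m = 2)
bf_elastic_net_grid <- function(A, y, lambda, rho, span = 3, h1 = 0.05,
                                h2 = 0.002) {
  stopifnot(ncol(A) == 2)
  eval_grid <- function(x1s, x2s, cs) {
    g <- expand.grid(x1 = x1s, x2 = x2s, c = cs)
    f <- outer(as.numeric(A[, 1]), g$x1) + outer(as.numeric(A[, 2]), g$x2) +
      matrix(g$c, nrow(A), nrow(g), byrow = TRUE)
    z <- -as.numeric(y) * f
    loss <- colSums(pmax(z, 0) + log1p(exp(-abs(z))))
    obj <- loss + rho / 2 * (g$x1^2 + g$x2^2) + lambda * (abs(g$x1) + abs(g$x2))
    list(best = g[which.min(obj), ], value = min(obj))
  }
  coarse <- eval_grid(seq(-span, span, h1), seq(-span, span, h1),
                      seq(-span, span, h1))
  b <- coarse$best
  fine <- eval_grid(seq(b$x1 - 2 * h1, b$x1 + 2 * h1, h2),
                    seq(b$x2 - 2 * h1, b$x2 + 2 * h1, h2),
                    seq(b$c - 2 * h1, b$c + 2 * h1, h2))
  fine
}

# random invertible affine: rotation-ish + anisotropic scale + translation
random_affine <- function() {
  repeat {
    M <- diag(runif(3, 0.8, 3)) + matrix(runif(9, -0.2, 0.2), 3, 3)
    if (abs(det(M)) > 0.1) break
  }
  aff <- diag(4)
  aff[1:3, 1:3] <- M
  aff[1:3, 4] <- runif(3, -20, 20)
  aff
}

# tiny 3-region parcellation on a 9x3x3 grid with 2 mm voxels; region k
# occupies x-slabs of 2 voxels separated by background
toy_parcellation3 <- function() {
  labels <- array(0L, c(9, 3, 3))
  labels[1:2, , ] <- 1L
  labels[4:5, , ] <- 2L
  labels[7:8, , ] <- 3L
  aff <- diag(c(2, 2, 2, 1))
  parcellation(labels, aff, data.frame(
    id = 1:3, name = c("A", "B", "C"),
    hemisphere = c("left", "midline", "right"),
    homologue_id = c(3L, NA, 1L)
  ))
}

# a streamline (straight, densely sampled) between two world points
toy_streamline <- function(p1, p2, step = 0.5) {
  len <- sqrt(sum((p2 - p1)^2))
  np <- max(2, ceiling(len / step) + 1)
  t <- seq(0, 1, length.out = np)
  cbind(p1[1] + t * (p2[1] - p1[1]),
        p1[2] + t * (p2[2] - p1[2]),
        p1[3] + t * (p2[3] - p1[3]))
}

# centre (world mm) of region id's voxel block
region_centre <- function(parc, id) {
  v <- which(parc$labels == id, arr.ind = TRUE) - 1
  colMeans(netresect:::voxel_to_world(v, parc$affine))
}

# two-subject toy cohort engineered for the feature-assembly rules:
# 3 eligible connections, 2 region-strength features, 1 volume feature
toy_assembly_changes <- function() {
  pre <- connectivity_matrix(
    matrix(c(0, 4, 2, 4, 0, 2, 2, 2, 0), 3), 1:3)
  post1 <- connectivity_matrix(
    matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3), 1:3)
  post2 <- connectivity_matrix(
    matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3), 1:3)
  list(
    change_metrics(pre, post1, volume_remaining = c(0.8, 1, 1)),
    change_metrics(pre, post2, volume_remaining = c(1, 1, 1))
  )
}
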