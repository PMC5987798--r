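## Weighted graph measures, following the weighted-undirected conventions of
## the standard brain-connectivity toolbox: self-connections excluded, edge
## length = 1/weight for path-based measures, betweenness unnormalised.

# Coerce input to a weights matrix with zero diagonal.
metric_weights <- function(W) {
  if (inherits(W, "connectivity_matrix")) W <- W$weights
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stopf("weight matrix must be square")
  if (any(W < 0)) stopf("weights must be non-negative")
  diag(W) <- 0
  W
}

weight_graph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Region strength
#'
#' Sum of the weights of all connections incident to each region
#' (self-connections excluded).
#'
#' @param W a [connectivity_matrix()] or symmetric non-negative matrix.
#' @return numeric vector, one value per region.
#' @export
node_strength <- function(W) {
  W <- metric_weights(W)
  unname(rowSums(W))
}

#' Weighted shortest-path length matrix
#'
#' Dijkstra distances on edge lengths 1/w (an absent edge is unreachable);
#' d\[i,i\] = 0 and unreachable pairs are `Inf`.
#'
#' @inheritParams node_strength
#' @return R x R symmetric distance matrix.
#' @export
shortest_path_lengths <- function(W) {
  W <- metric_weights(W)
  g <- weight_graph(W)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  dimnames(d) <- dimnames(W)
  d
}

#' Node and edge betweenness centrality
#'
#' Brandes accumulation over all unordered source-target pairs on the 1/w
#' length graph, with tied shortest paths counted fractionally; values are
#' unnormalised path counts.
#'
#' @inheritParams node_strength
#' @return list with `node` (numeric vector) and `edge` (symmetric R x R
#'   matrix).
#' @export
betweenness_centrality <- function(W) {
  W <- metric_weights(W)
  R <- nrow(W)
  g <- weight_graph(W)
  wts <- 1 / igraph::E(g)$weight
  node <- igraph::betweenness(g, weights = wts, normalized = FALSE)
  eb <- igraph::edge_betweenness(g, weights = wts)
  E <- matrix(0, R, R, dimnames = dimnames(W))
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    E[ends] <- eb
    E[ends[, 2:1, drop = FALSE]] <- eb
  }
  list(node = unname(node), edge = E)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Geometric-mean triangle intensity around each node on max-normalised
#' weights: C(u) = sum over triangles of (w_uv w_vw w_wu / max(W)^3)^(1/3),
#' divided by k_u (k_u - 1) with k_u the binary degree; 0 when k_u < 2.
#'
#' @inheritParams node_strength
#' @return numeric vector of values in \[0, 1\].
#' @export
clustering_coefficient <- function(W) {
  W <- metric_weights(W)
  mx <- max(W)
  R <- nrow(W)
  if (mx == 0) return(numeric(R))
  cr <- (W / mx)^(1 / 3)
  num <- diag(cr %*% cr %*% cr)
  k <- rowSums(W > 0)
  out <- numeric(R)
  ok <- k >= 2
  out[ok] <- num[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Global efficiency
#'
#' Mean inverse weighted shortest-path length over all ordered region pairs,
#' with 1/Inf = 0 for unreachable pairs.
#'
#' @inheritParams node_strength
#' @return scalar in \[0, Inf).
#' @export
global_efficiency <- function(W) {
  W <- metric_weights(W)
  R <- nrow(W)
  if (R < 2) stopf("global efficiency needs at least 2 regions")
  d <- shortest_path_lengths(W)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (R * (R - 1))
}

#' Regional communicability
#'
#' Row sums of the matrix exponential of the degree-normalised adjacency
#' D^(-1/2) W D^(-1/2), with D = diag(strength); zero-strength nodes get a
#' unit normaliser. An isolated node has communicability exactly 1.
#'
#' @inheritParams node_strength
#' @return numeric vector, one value per region (>= 1).
#' @export
communicability <- function(W) {
  W <- metric_weights(W)
  s <- rowSums(W)
  s[s == 0] <- 1
  isq <- 1 / sqrt(s)
  A <- W * (isq %o% isq)
  G <- as.matrix(Matrix::expm(Matrix::Matrix(A)))
  unname(rowSums(G))
}

#' Bundle all regional, edge and global measures for one network
#'
#' @inheritParams node_strength
#' @return an object of class `network_metrics`: list with `strength`,
#'   `betweenness`, `edge_betweenness`, `clustering`, `communicability`,
#'   `efficiency` and `region_ids`.
#' @export
network_metrics <- function(W) {
  ids <- if (inherits(W, "connectivity_matrix")) W$region_ids
         else seq_len(nrow(metric_weights(W)))
  Wm <- metric_weights(W)
  bc <- betweenness_centrality(Wm)
  structure(
    list(
      strength = node_strength(Wm),
      betweenness = bc$node,
      edge_betweenness = bc$edge,
      clustering = clustering_coefficient(Wm),
      communicability = communicability(Wm),
      efficiency = global_efficiency(Wm),
      region_ids = as.integer(ids)
    ),
    class = "network_metrics"
  )
}

ratio01 <- function(post, pre) {
  out <- post / pre
  out[pre == 0 & post == 0] <- 1
  out
}

#' Pre-to-post change metrics
#'
#' Ratio rule (post/pre, with 0/0 = 1) for region volume, region strength and
#' connection strength, all computed on streamline counts so values lie in
#' \[0, 1\]; difference rule (post - pre) for node/edge betweenness,
#' clustering and communicability, computed on `metric_weight_kind` weights;
#' global efficiency is reported pre, post and as a ratio.
#'
#' @param pre,post count-weighted [connectivity_matrix()] objects on the same
#'   region set.
#' @param volume_remaining optional per-region fraction from
#'   [region_volume_remaining()] (post/pre volume ratio directly).
#' @param metric_weight_kind weights used for the path/triangle/walk
#'   measures: "log10_transformed" (default) or "streamline_count".
#' @return an object of class `change_metrics`.
#' @export
change_metrics <- function(pre, post, volume_remaining = NULL,
                           metric_weight_kind = c("log10_transformed",
                                                  "streamline_count")) {
  metric_weight_kind <- match.arg(metric_weight_kind)
  if (!inherits(pre, "connectivity_matrix") ||
      !inherits(post, "connectivity_matrix")) {
    stopf("pre and post must be connectivity_matrix objects")
  }
  if (!identical(pre$region_ids, post$region_ids)) {
    stopf("pre and post are on different region sets")
  }
  if (pre$weight_kind != "streamline_count" ||
      post$weight_kind != "streamline_count") {
    stopf("change ratios are defined on streamline-count weights")
  }
  if (!is.null(volume_remaining) &&
      length(volume_remaining) != length(pre$region_ids)) {
    stopf("volume_remaining length does not match the region set")
  }
  pre_m <- if (metric_weight_kind == "log10_transformed") {
    log_transform(pre)
  } else pre
  post_m <- if (metric_weight_kind == "log10_transformed") {
    log_transform(post)
  } else post
  mp <- network_metrics(pre_m)
  mq <- network_metrics(post_m)
  preW <- metric_weights(pre)
  postW <- metric_weights(post)
  structure(
    list(
      region_ids = pre$region_ids,
      connection_ratio = ratio01(postW, preW),
      strength_ratio = ratio01(rowSums(postW), rowSums(preW)),
      volume_ratio = volume_remaining,
      betweenness_diff = mq$betweenness - mp$betweenness,
      edge_betweenness_diff = mq$edge_betweenness - mp$edge_betweenness,
      clustering_diff = mq$clustering - mp$clustering,
      communicability_diff = mq$communicability - mp$communicability,
      efficiency = c(pre = mp$efficiency, post = mq$efficiency,
                     ratio = ratio01(mq$efficiency, mp$efficiency)),
      pre_connection = preW,
      post_connection = postW,
      metric_weight_kind = metric_weight_kind
    ),
    class = "change_metrics"
  )
}

#' @export
print.change_metrics <- function(x, ...) {
  cat(sprintf(
    "Change metrics on %d regions: efficiency %.4f -> %.4f (ratio %.4f)\n",
    length(x$region_ids), x$efficiency["pre"], x$efficiency["post"],
    x$efficiency["ratio"]))
  cat(sprintf("  connections reduced: %d; regions with strength ratio < 1: %d\n",
              sum(x$connection_ratio[upper.tri(x$connection_ratio)] < 1),
              sum(x$strength_ratio < 1)))
  invisible(x)
}

#' Tidy long-format view of change metrics
#'
#' @param x a [change_metrics()] object.
#' @param ... unused.
#' @return data frame with columns metric, unit (region id or "i-j" edge),
#'   pre, post, change.
#' @export
as.data.frame.change_metrics <- function(x, ...) {
  ids <- x$region_ids
  R <- length(ids)
  ut <- upper_triangle_order(R)
  edge_names <- paste0(ids[ut[, 1]], "-", ids[ut[, 2]])
  rows <- list(
    data.frame(metric = "connection_strength_ratio", unit = edge_names,
               pre = x$pre_connection[ut], post = x$post_connection[ut],
               change = x$connection_ratio[ut]),
    data.frame(metric = "region_strength_ratio", unit = as.character(ids),
               pre = rowSums(x$pre_connection),
               post = rowSums(x$post_connection),
               change = x$strength_ratio),
    data.frame(metric = "betweenness_diff", unit = as.character(ids),
               pre = NA_real_, post = NA_real_, change = x$betweenness_diff),
    data.frame(metric = "edge_betweenness_diff", unit = edge_names,
               pre = NA_real_, post = NA_real_,
               change = x$edge_betweenness_diff[ut]),
    data.frame(metric = "clustering_diff", unit = as.character(ids),
               pre = NA_real_, post = NA_real_, change = x$clustering_diff),
    data.frame(metric = "communicability_diff", unit = as.character(ids),
               pre = NA_real_, post = NA_real_,
               change = x$communicability_diff),
    data.frame(metric = "global_efficiency", unit = "global",
               pre = x$efficiency[["pre"]], post = x$efficiency[["post"]],
               change = x$efficiency[["ratio"]])
  )
  if (!is.null(x$volume_ratio)) {
    rows <- c(rows, list(
      data.frame(metric = "region_volume_ratio", unit = as.character(ids),
                 pre = 1, post = x$volume_ratio, change = x$volume_ratio)
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# indices of the strict upper triangle in row-major order:
# (1,2),(1,3),...,(1,R),(2,3),...
upper_triangle_order <- function(R) {
  if (R < 2) return(matrix(integer(0), 0, 2))
  i <- rep(seq_len(R - 1L), times = (R - 1L):1L)
  j <- unlist(lapply(seq_len(R - 1L), function(k) (k + 1L):R))
  cbind(i, j)
}
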