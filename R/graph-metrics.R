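#' Node strength
#'
#' Sum of a node's edge weights (weighted degree).
#'
#' @param network Symmetric non-negative weight matrix.
#' @return Numeric vector, one value per node.
#' @export
node_strength <- function(network) {
  w <- as_plain_matrix(network)
  rowSums(w)
}

#' Map edge weights to path lengths
#'
#' Uses the standard inverse mapping `L = 1/w` (a stronger connection is a
#' shorter path); absent edges become `Inf` and the diagonal is zero. Unit
#' weights reduce to binary hop lengths.
#'
#' @param network Symmetric non-negative weight matrix.
#' @return Length matrix of the same dimension.
#' @export
to_length_matrix <- function(network) {
  w <- as_plain_matrix(network)
  l <- ifelse(w > 0, 1 / w, Inf)
  diag(l) <- 0
  l
}

#' All-pairs shortest paths on a length matrix
#'
#' Exact Dijkstra single-source shortest paths from every node, with counts
#' of distinct shortest paths per ordered pair (ties in length counted
#' fractionally downstream by betweenness). Unreachable pairs have infinite
#' distance and zero paths.
#'
#' @param lengths Non-negative length matrix (`Inf` = absent edge).
#' @return List with `dist` (d\[i, j\] = shortest length from i to j) and
#'   `n_paths` (number of distinct shortest paths from i to j).
#' @export
shortest_paths <- function(lengths) {
  stopifnot(is.matrix(lengths), nrow(lengths) == ncol(lengths))
  res <- cpp_shortest_paths(lengths)
  dimnames(res$dist) <- dimnames(lengths)
  dimnames(res$n_paths) <- dimnames(lengths)
  res
}

#' Weighted betweenness centrality
#'
#' Brandes accumulation over ordered node pairs on the inverse-weight length
#' matrix, with fractional counting across equal-length shortest paths.
#' Normalized by `(N-1)(N-2)`, the number of ordered pairs a node can
#' mediate; the raw accumulation is attached as attribute `raw`.
#'
#' @param network Symmetric non-negative weight matrix.
#' @param normalized Divide by `(N-1)(N-2)`? Default `TRUE`.
#' @return Numeric vector per node (attribute `raw` holds unnormalized
#'   values).
#' @export
betweenness_centrality <- function(network, normalized = TRUE) {
  w <- as_plain_matrix(network)
  l <- to_length_matrix(w)
  raw <- as.numeric(cpp_betweenness_raw(l))
  names(raw) <- rownames(w)
  n <- nrow(w)
  out <- if (normalized && n > 2) raw / ((n - 1) * (n - 2)) else raw
  attr(out, "raw") <- raw
  out
}

#' Weighted clustering coefficient (triangle intensity)
#'
#' Onnela's geometric-mean triangle intensity on weights scaled by the
#' network-wide maximum:
#' `cc_i = sum_jh (w'_ij w'_ih w'_jh)^(1/3) / (k_i (k_i - 1))` with
#' `w' = w / max(w)` and `k_i` the number of neighbors. Nodes with fewer than
#' two neighbors have `cc_i = 0`. Values lie in \[0, 1\] and are invariant to
#' uniform weight rescaling.
#'
#' @param network Symmetric non-negative weight matrix.
#' @return Numeric vector per node.
#' @export
clustering_coefficient <- function(network) {
  w <- as_plain_matrix(network)
  n <- nrow(w)
  k <- rowSums(w > 0)
  mx <- max(w)
  cc <- numeric(n)
  names(cc) <- rownames(w)
  if (mx == 0) return(cc)
  a <- (w / mx)^(1 / 3)
  tri <- diag(a %*% a %*% a)  # 2 * sum over unordered neighbor pairs
  ok <- k >= 2
  cc[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  cc
}

#' Global efficiency
#'
#' Mean over ordered pairs `i != j` of the inverse shortest path length on
#' the inverse-weight length matrix; unreachable pairs contribute zero.
#'
#' @param network Symmetric non-negative weight matrix.
#' @return Scalar efficiency (<= 1 for weights <= 1).
#' @export
global_efficiency <- function(network) {
  w <- as_plain_matrix(network)
  n <- nrow(w)
  if (n < 2) return(0)
  d <- cpp_shortest_dist(to_length_matrix(w))
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' For each node, the [global_efficiency()] of the subgraph induced on its
#' direct neighbors with the node itself removed and paths confined to the
#' subgraph (the neighborhood fault-tolerance measure). Nodes with fewer than
#' two neighbors score 0. An alternative weighted form
#' (`variant = "cuberoot"`) uses the cube-root combination of the two stem
#' weights and the inverse neighbor-subgraph distance:
#' `eloc_i = (1/2) sum_jh (w_ij w_ih / d_jh)^(1/3) / (k_i (k_i - 1))` on
#' max-scaled weights.
#'
#' @param network Symmetric non-negative weight matrix.
#' @param variant `"subgraph"` (default) or `"cuberoot"`.
#' @return Numeric vector per node.
#' @export
local_efficiency <- function(network, variant = c("subgraph", "cuberoot")) {
  variant <- match.arg(variant)
  w <- as_plain_matrix(network)
  n <- nrow(w)
  out <- numeric(n)
  names(out) <- rownames(w)
  mx <- max(w)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) next
    sub <- w[nb, nb, drop = FALSE]
    if (variant == "subgraph") {
      out[i] <- global_efficiency(sub)
    } else {
      d <- cpp_shortest_dist(to_length_matrix(sub / mx))
      invd <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
      stems <- (w[i, nb] / mx)
      num <- sum((tcrossprod(stems) * invd)^(1 / 3))
      k <- length(nb)
      out[i] <- num / (k * (k - 1))
    }
  }
  out
}

#' All nodal metrics plus global efficiency for one network
#'
#' @param network Symmetric non-negative weight matrix (typically a
#'   `thresholded_network`).
#' @param eloc_variant Passed to [local_efficiency()].
#' @return List with vectors `bc`, `strength`, `cc`, `eloc` and scalar
#'   `eglob`.
#' @export
nodal_metrics <- function(network, eloc_variant = "subgraph") {
  list(bc = as.numeric(betweenness_centrality(network)) |>
         stats::setNames(rownames(as_plain_matrix(network))),
       strength = node_strength(network),
       cc = clustering_coefficient(network),
       eloc = local_efficiency(network, eloc_variant),
       eglob = global_efficiency(network))
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of metric values over a strictly increasing sparsity
#' grid, removing the dependence on any single threshold.
#'
#' @param grid Strictly increasing sparsity values (>= 2 points).
#' @param values Metric value at each grid point.
#' @return Scalar AUC.
#' @export
metric_auc <- function(grid, values) {
  stopifnot(length(grid) >= 2, length(grid) == length(values),
            all(diff(grid) > 0))
  pracma::trapz(grid, values)
}
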