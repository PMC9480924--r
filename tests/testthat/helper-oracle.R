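# Independent oracles for the weighted shortest-path measures. These use
# Floyd-Warshall plus a distance-ordered path-count recursion (and, for tiny
# graphs, exhaustive simple-path enumeration) -- deliberately different
# algorithms from the Dijkstra/Brandes implementation they check.

ORACLE_TOL <- 1e-9

fw_distances <- function(L) {
  n <- nrow(L)
  d <- L
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# Number of distinct shortest paths from s to every node, by dynamic
# programming over nodes in increasing distance order.
oracle_path_counts_from <- function(L, d, s) {
  n <- nrow(L)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(d[s, ])
  for (t in ord) {
    if (t == s || !is.finite(d[s, t])) next
    preds <- which(is.finite(L[, t]) & is.finite(d[s, ]) &
                     abs(d[s, ] + L[, t] - d[s, t]) <=
                       ORACLE_TOL * (1 + abs(d[s, t])))
    preds <- setdiff(preds, t)
    sigma[t] <- sum(sigma[preds])
  }
  sigma
}

oracle_betweenness <- function(w, normalized = TRUE) {
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  n <- nrow(L)
  d <- fw_distances(L)
  sigma <- t(vapply(seq_len(n), function(s)
    oracle_path_counts_from(L, d, s), numeric(n)))
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s == t || s == v || t == v) next
        if (!is.finite(d[s, t])) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) <=
            ORACLE_TOL * (1 + abs(d[s, t]))) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  if (normalized && n > 2) bc / ((n - 1) * (n - 2)) else bc
}

oracle_global_efficiency <- function(w) {
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  d <- fw_distances(L)
  n <- nrow(w)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(w) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    if (length(nb) >= 2) out[i] <- oracle_global_efficiency(w[nb, nb])
  }
  out
}

# Exhaustive simple-path enumeration for tiny graphs: returns, per ordered
# pair, the shortest length, the number of shortest paths, and accumulates
# fractional pass-through counts into a betweenness vector.
enum_betweenness <- function(w) {
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  n <- nrow(w)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- list()
      lens <- numeric()
      walk <- function(v, visited, len, trail) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- trail
          lens[[length(lens) + 1L]] <<- len
          return(invisible())
        }
        for (u in which(is.finite(L[v, ]))) {
          if (u %in% visited) next
          walk(u, c(visited, u), len + L[v, u], c(trail, u))
        }
      }
      walk(s, s, 0, s)
      if (!length(lens)) next
      dmin <- min(lens)
      sp <- paths[abs(lens - dmin) <= ORACLE_TOL * (1 + dmin)]
      for (p in sp) {
        interior <- setdiff(p, c(s, t))
        bc[interior] <- bc[interior] + 1 / length(sp)
      }
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2)) else bc
}

random_weighted_graph <- function(n, p_edge = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  vals <- ifelse(runif(sum(ut)) < p_edge, runif(sum(ut), 0.2, 1), 0)
  w[ut] <- vals
  w + t(w)
}
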