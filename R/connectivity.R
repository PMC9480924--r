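#' ROI time-series container
#'
#' One subject's T x N matrix of ROI-averaged signals with node labels.
#'
#' @param subject_id Subject identifier.
#' @param data Numeric T x N matrix, one row per timepoint, one column per
#'   node. Must be free of missing values.
#' @param node_names Node labels; defaults to `colnames(data)`.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(subject_id, data, node_names = colnames(data)) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("time-series data must be numeric")
  if (anyNA(data)) stop("time-series data contains missing values (subject ",
                        subject_id, ")")
  if (is.null(node_names) || length(node_names) != ncol(data))
    stop("node_names must label every column")
  colnames(data) <- node_names
  structure(list(subject_id = as.character(subject_id), data = data,
                 node_names = node_names),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> subject", x$subject_id, "-", nrow(x$data),
      "timepoints x", ncol(x$data), "nodes\n")
  invisible(x)
}

new_connectivity <- function(w, stage, subject_id = NULL) {
  diag(w) <- 0
  attr(w, "stage") <- stage
  attr(w, "subject_id") <- subject_id
  class(w) <- c("connectivity_matrix", class(w))
  w
}

conn_stage <- function(w) attr(w, "stage")

as_plain_matrix <- function(w) {
  a <- attributes(w)
  attributes(w) <- a[names(a) %in% c("dim", "dimnames")]
  w
}

#' Pearson connectivity matrix
#'
#' Edges are the Pearson correlations between each pair of ROI time series;
#' correlations are stored untransformed (no Fisher r-to-z step) and the
#' diagonal is zero.
#'
#' @param ts An [roi_timeseries()].
#' @return A `connectivity_matrix` at stage `"raw"`.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (nrow(ts$data) < 3L) stop("need at least 3 timepoints")
  sds <- apply(ts$data, 2, sd)
  if (any(sds == 0)) {
    stop("constant time series for node(s): ",
         paste(ts$node_names[sds == 0], collapse = ", "),
         " (subject ", ts$subject_id, ")")
  }
  w <- cor(ts$data)
  new_connectivity(w, "raw", ts$subject_id)
}

#' Remove age and sex from edge weights across subjects
#'
#' For every edge, fits `weight ~ intercept + age + sex` by ordinary least
#' squares across all subjects (groups pooled) and replaces the weight by its
#' residual plus the edge's grand mean, so the cohort-average connectivity is
#' preserved while linear age and sex trends are removed. If a covariate is
#' constant across subjects (e.g. a single-sex cohort) it is dropped with a
#' warning.
#'
#' @param matrices List of `connectivity_matrix` objects, one per subject, in
#'   the same order as `subjects`.
#' @param subjects Subject table containing `age` and `sex` ("F"/"M").
#' @return List of `connectivity_matrix` objects at stage `"residualized"`,
#'   same order as the input.
#' @export
residualize_edges <- function(matrices, subjects) {
  stopifnot(length(matrices) == nrow(subjects))
  n <- length(matrices)
  if (n < 3L) stop("need at least 3 subjects to fit age + sex")
  nn <- nrow(matrices[[1]])
  ut <- upper.tri(matrix(0, nn, nn))
  y <- t(vapply(matrices, function(m) as_plain_matrix(m)[ut],
                numeric(sum(ut))))
  covs <- list(age = as.numeric(subjects$age),
               sex = as.numeric(subjects$sex == "M"))
  keep <- vapply(covs, function(v) length(unique(v)) > 1L, logical(1))
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(covs)[!keep], collapse = ", "))
  }
  x <- cbind(intercept = rep(1, n), do.call(cbind, covs[keep]))
  fit <- lm.fit(x, y)
  resid <- y - x %*% fit$coefficients
  out_vals <- resid + rep(colMeans(y), each = n)
  lapply(seq_len(n), function(s) {
    m <- matrix(0, nn, nn, dimnames = dimnames(as_plain_matrix(matrices[[s]])))
    m[ut] <- out_vals[s, ]
    m <- m + t(m)
    new_connectivity(m, "residualized", attr(matrices[[s]], "subject_id"))
  })
}

#' Set negative edges to zero
#'
#' @param matrix A `connectivity_matrix` (typically residualized).
#' @return A `connectivity_matrix` at stage `"rectified"` with all weights
#'   non-negative. Idempotent.
#' @export
rectify_negative <- function(matrix) {
  w <- pmax(as_plain_matrix(matrix), 0)
  new_connectivity(w, "rectified", attr(matrix, "subject_id"))
}

#' Sparsity of a network
#'
#' The number of present edges (strictly positive weights above the diagonal)
#' divided by the number of possible edges `N(N-1)/2`.
#'
#' @param network Symmetric weight matrix.
#' @return Fraction in \[0, 1\].
#' @export
network_sparsity <- function(network) {
  w <- as_plain_matrix(network)
  n <- nrow(w)
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

# Upper-triangle edge list sorted by decreasing weight, ties broken by
# lexicographic (i, j); shared by thresholding and sparsity search so the two
# always agree on which edges enter first.
sorted_edge_list <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  pos <- wt > 0
  ut <- ut[pos, , drop = FALSE]
  wt <- wt[pos]
  ord <- order(-wt, ut[, 1], ut[, 2])
  list(i = ut[ord, 1], j = ut[ord, 2], w = wt[ord], n_possible = n * (n - 1) / 2)
}

#' Threshold a rectified matrix to a target sparsity
#'
#' Keeps the `k = round(target_s * N(N-1)/2)` strongest edges by weight,
#' retaining their weights (no binarization). Ties at the cutoff are broken
#' deterministically by lexicographic `(i, j)` order. If fewer than `k`
#' positive edges exist, all positive edges are kept with a warning.
#'
#' @param matrix Rectified `connectivity_matrix`.
#' @param target_s Target sparsity in (0, 1].
#' @return A `thresholded_network`: the weight matrix with attributes
#'   `sparsity` (achieved), `target_sparsity`, and `lcc_size`.
#' @export
threshold_to_sparsity <- function(matrix, target_s) {
  stopifnot(target_s > 0, target_s <= 1)
  w <- as_plain_matrix(matrix)
  if (any(w < 0)) stop("threshold_to_sparsity expects a rectified matrix")
  el <- sorted_edge_list(w)
  k <- round(target_s * el$n_possible)
  if (k > length(el$w)) {
    warning(sprintf(
      "only %d positive edges available for target %d; keeping all",
      length(el$w), k))
    k <- length(el$w)
  }
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  if (k > 0) {
    keep <- seq_len(k)
    out[cbind(el$i[keep], el$j[keep])] <- el$w[keep]
    out <- out + t(out)
  }
  structure(out,
            sparsity = k / el$n_possible,
            target_sparsity = target_s,
            lcc_size = largest_component_size(out),
            subject_id = attr(matrix, "subject_id"),
            class = c("thresholded_network", "matrix", "array"))
}

# Connected-component labels for a logical adjacency matrix (simple BFS).
component_labels <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Size of the largest connected component
#'
#' Edges are weights strictly greater than zero. By convention an edgeless
#' non-empty graph has a largest component of size 1 (a single isolated
#' node).
#'
#' @param network Symmetric weight matrix.
#' @return Node count of the largest component.
#' @export
largest_component_size <- function(network) {
  w <- as_plain_matrix(network)
  comp <- component_labels(w > 0)
  max(tabulate(comp))
}

#' Minimum sparsity at which a subject's network is fully connected
#'
#' Searches the edge-count-resolution sweep (edges entering in decreasing
#' weight order, the same order used by [threshold_to_sparsity()]) for the
#' smallest number of retained edges at which all nodes belong to one
#' component, by binary search (valid because the largest component is
#' nondecreasing as edges are added). If even the full positive matrix is
#' disconnected the result is `NA` with attribute `unreachable_nodes` naming
#' the nodes outside the largest component.
#'
#' @param matrix Rectified `connectivity_matrix`.
#' @return Sparsity fraction, or `NA` with attribute `unreachable_nodes`.
#' @export
min_connecting_sparsity <- function(matrix) {
  w <- as_plain_matrix(matrix)
  n <- nrow(w)
  el <- sorted_edge_list(w)
  lcc_at <- function(k) {
    adj <- matrix(FALSE, n, n)
    if (k > 0) {
      keep <- seq_len(k)
      adj[cbind(el$i[keep], el$j[keep])] <- TRUE
      adj <- adj | t(adj)
    }
    component_labels(adj)
  }
  full <- lcc_at(length(el$w))
  counts <- tabulate(full)
  if (max(counts) < n) {
    big <- which.max(counts)
    out <- NA_real_
    nms <- rownames(w)
    if (is.null(nms)) nms <- as.character(seq_len(n))
    attr(out, "unreachable_nodes") <- nms[full != big]
    return(out)
  }
  lo <- n - 1L
  hi <- length(el$w)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (max(tabulate(lcc_at(mid))) == n) hi <- mid else lo <- mid + 1L
  }
  lo / el$n_possible
}

#' Group-level sparsity selection
#'
#' `selected_s` is the maximum over subjects of each subject's
#' [min_connecting_sparsity()] -- the smallest sparsity at which every
#' subject's network is fully connected. `min_s` is the minimum over subjects
#' -- the point at which at least one subject first becomes fully connected.
#' Both are also reported rounded to 0.1%.
#'
#' @param matrices List of rectified `connectivity_matrix` objects.
#' @return List with `selected_s`, `min_s`, rounded variants
#'   (`selected_s_rounded`, `min_s_rounded`) and the `per_subject` vector.
#' @export
select_group_sparsity <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  per <- vapply(matrices, min_connecting_sparsity, numeric(1))
  ids <- vapply(seq_along(matrices), function(s) {
    id <- attr(matrices[[s]], "subject_id")
    if (is.null(id)) as.character(s) else id
  }, character(1))
  names(per) <- ids
  if (anyNA(per)) {
    stop("network cannot be fully connected for subject(s): ",
         paste(ids[is.na(per)], collapse = ", "))
  }
  list(selected_s = max(per), min_s = min(per),
       selected_s_rounded = round(max(per), 3),
       min_s_rounded = round(min(per), 3),
       per_subject = per)
}
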