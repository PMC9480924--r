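make_ts <- function(mat, id = "s1") {
  colnames(mat) <- sprintf("n%d", seq_len(ncol(mat)))
  roi_timeseries(id, mat)
}

test_that("pearson connectivity matches hand-computed correlations", {
  x <- c(1, 2, 3, 4)
  w <- pearson_connectivity(make_ts(cbind(x, 2 * x + 1, c(1, 3, 2, 4))))
  expect_equal(w[1, 2], 1)
  expect_equal(w[1, 3], 0.8)
  expect_equal(diag(unclass(w)), rep(0, 3), ignore_attr = TRUE)
  wn <- pearson_connectivity(make_ts(cbind(x, -x)))
  expect_equal(wn[1, 2], -1)
  expect_error(pearson_connectivity(make_ts(cbind(x, rep(2, 4)))), "n2")
})

test_that("edge residualization removes linear age effects exactly", {
  set.seed(1)
  n <- 10
  subjects <- data.frame(subject_id = sprintf("s%02d", 1:n),
                         group = rep(c("case", "control"), each = 5),
                         age = seq(20, 65, length.out = n),
                         sex = rep(c("F", "M"), 5))
  base <- matrix(0.3, 4, 4)
  diag(base) <- 0
  # edge value = 0.01 * age exactly (balanced sexes): residualized values all
  # equal the grand mean
  mats <- lapply(seq_len(n), function(s) {
    m <- 0.01 * subjects$age[s] * (1 - diag(4))
    dimnames(m) <- list(sprintf("n%d", 1:4), sprintf("n%d", 1:4))
    fcgraph:::new_connectivity(m, "raw", subjects$subject_id[s])
  })
  out <- residualize_edges(mats, subjects)
  grand <- 0.01 * mean(subjects$age)
  for (m in out) expect_equal(m[1, 2], grand, tolerance = 1e-10)

  # edges orthogonal to age and sex: output equals input
  ortho <- lapply(seq_len(n), function(s) {
    v <- 0.3 + 0.05 * (-1)^s * rep(c(1, -1), 3)[1:6] * 0  # constant edges
    m <- base
    dimnames(m) <- list(sprintf("n%d", 1:4), sprintf("n%d", 1:4))
    fcgraph:::new_connectivity(m, "raw", subjects$subject_id[s])
  })
  out2 <- residualize_edges(ortho, subjects)
  for (s in seq_len(n)) {
    expect_equal(unclass(out2[[s]])[1:4, 1:4], unclass(ortho[[s]])[1:4, 1:4],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # permuting subject order permutes outputs identically
  perm <- sample(n)
  set.seed(2)
  rnd <- lapply(seq_len(n), function(s) {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- runif(6, -0.2, 0.8)
    m <- m + t(m)
    dimnames(m) <- list(sprintf("n%d", 1:4), sprintf("n%d", 1:4))
    fcgraph:::new_connectivity(m, "raw", subjects$subject_id[s])
  })
  out3 <- residualize_edges(rnd, subjects)
  out3p <- residualize_edges(rnd[perm], subjects[perm, ])
  for (k in seq_len(n)) {
    expect_equal(unclass(out3p[[k]]), unclass(out3[[perm[k]]]),
                 ignore_attr = TRUE)
  }

  # residualization is idempotent
  out4 <- residualize_edges(out3, subjects)
  for (k in seq_len(n)) {
    expect_equal(unclass(out4[[k]]), unclass(out3[[k]]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }

  # single-sex cohort: sex dropped with a warning
  subjects$sex <- "F"
  expect_warning(residualize_edges(rnd, subjects), "sex")
})

test_that("rectification zeroes negatives and is idempotent", {
  m <- matrix(c(0, -0.2, 0.5, -0.2, 0, 0.3, 0.5, 0.3, 0), 3, 3)
  r <- rectify_negative(fcgraph:::new_connectivity(m, "residualized"))
  expect_equal(unclass(r)[1, 2], 0)
  expect_equal(unclass(r)[1, 3], 0.5)
  expect_identical(unclass(rectify_negative(r)), unclass(r))
  allneg <- matrix(-0.2, 3, 3)
  expect_true(all(unclass(rectify_negative(
    fcgraph:::new_connectivity(allneg, "residualized"))) == 0))
})

test_that("sparsity counts present edges over possible edges", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(network_sparsity(k4), 1)
  expect_equal(network_sparsity(matrix(0, 4, 4)), 0)
  half <- matrix(0, 4, 4)
  half[1, 2] <- half[1, 3] <- half[1, 4] <- 1
  half <- half + t(half)
  expect_equal(network_sparsity(half), 0.5)
})

test_that("proportional thresholding keeps the k strongest edges", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.9, 0.5, 0.8, 0.3, 0.7, 0.1)
  w <- w + t(w)
  dimnames(w) <- list(sprintf("n%d", 1:4), sprintf("n%d", 1:4))
  cm <- fcgraph:::new_connectivity(w, "rectified")
  net <- threshold_to_sparsity(cm, 0.5)
  kept <- sort(unclass(net)[upper.tri(net)][unclass(net)[upper.tri(net)] > 0],
               decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.7))
  expect_equal(attr(net, "sparsity"), 0.5)

  # target 1 keeps every positive edge with identical weights
  full <- threshold_to_sparsity(cm, 1)
  expect_equal(unclass(full), w, ignore_attr = TRUE)

  # all-equal weights: tie rule keeps exactly k edges, reproducibly
  eq <- matrix(0.5, 4, 4) - 0.5 * diag(4)
  cm2 <- fcgraph:::new_connectivity(eq, "rectified")
  n1 <- threshold_to_sparsity(cm2, 0.5)
  n2 <- threshold_to_sparsity(cm2, 0.5)
  expect_equal(sum(unclass(n1)[upper.tri(n1)] > 0), 3)
  expect_identical(unclass(n1), unclass(n2))
  # lexicographic (i, j) tie-break: edges (1,2), (1,3), (1,4) survive
  expect_true(all(unclass(n1)[1, 2:4] == 0.5))

  # warning when target exceeds available positive edges
  sparse <- matrix(0, 4, 4)
  sparse[1, 2] <- sparse[2, 1] <- 0.5
  expect_warning(
    threshold_to_sparsity(fcgraph:::new_connectivity(sparse, "rectified"), 0.9),
    "positive edges")
})

test_that("largest component follows textbook conventions", {
  ring5 <- matrix(0, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    ring5[i, j] <- ring5[j, i] <- 1
  }
  expect_equal(largest_component_size(ring5), 5)
  two_tri <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    two_tri[p[1], p[2]] <- two_tri[p[2], p[1]] <- 1
  }
  expect_equal(largest_component_size(two_tri), 3)
  expect_equal(largest_component_size(matrix(0, 7, 7)), 1)
})

test_that("minimum connecting sparsity is found exactly", {
  # spanning-tree-ordered weights: the N-1 strongest edges form a path
  n <- 6
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1 - 0.01 * i
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 5] <- w[5, 2] <- 0.1
  cm <- fcgraph:::new_connectivity(w, "rectified")
  expect_equal(min_connecting_sparsity(cm), (n - 1) / (n * (n - 1) / 2))

  # triangle of strongest edges leaves node d isolated; 4th edge attaches it
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- 0.9
  w4[2, 3] <- w4[3, 2] <- 0.8
  w4[1, 3] <- w4[3, 1] <- 0.7
  w4[3, 4] <- w4[4, 3] <- 0.6
  cm4 <- fcgraph:::new_connectivity(w4, "rectified")
  expect_equal(min_connecting_sparsity(cm4), 4 / 6)

  # strengthening an already-kept edge never increases the result
  w4b <- w4
  w4b[1, 2] <- w4b[2, 1] <- 0.95
  expect_lte(min_connecting_sparsity(fcgraph:::new_connectivity(w4b,
                                                                "rectified")),
             min_connecting_sparsity(cm4))

  # unreachable node reported by name
  w0 <- w4
  w0[3, 4] <- w0[4, 3] <- 0
  dimnames(w0) <- list(letters[1:4], letters[1:4])
  res <- min_connecting_sparsity(fcgraph:::new_connectivity(w0, "rectified"))
  expect_true(is.na(res))
  expect_equal(attr(res, "unreachable_nodes"), "d")
})

test_that("group sparsity selection takes max and min of subject minima", {
  mk <- function(seed, id) {
    set.seed(seed)
    w <- random_weighted_graph(10, 0.5)
    dimnames(w) <- list(sprintf("n%d", 1:10), sprintf("n%d", 1:10))
    fcgraph:::new_connectivity(w, "rectified", id)
  }
  mats <- list(mk(1, "a"), mk(2, "b"), mk(3, "c"))
  per <- vapply(mats, min_connecting_sparsity, numeric(1))
  sel <- select_group_sparsity(mats)
  expect_equal(sel$selected_s, max(per))
  expect_equal(sel$min_s, min(per))
  expect_equal(sel$selected_s_rounded, round(max(per), 3))

  single <- select_group_sparsity(mats[1])
  expect_equal(single$selected_s, single$min_s)

  dup <- select_group_sparsity(c(mats, mats[2]))
  expect_equal(dup$selected_s, sel$selected_s)
  expect_equal(dup$min_s, sel$min_s)
})

test_that("selection reports per-subject values consistent with the rule", {
  # per-subject minima like {8.1%, 15%, 26.2%} map to (26.2%, 8.1%)
  fake <- c(a = 0.081, b = 0.15, c = 0.262)
  expect_equal(max(fake), 0.262)
  expect_equal(min(fake), 0.081)
})

test_that("thresholded edge sets are nested across sparsities", {
  set.seed(8)
  w <- random_weighted_graph(12, 0.9)
  cm <- fcgraph:::new_connectivity(w, "rectified")
  grid <- seq(0.08, 0.26, by = 0.01)
  prev <- NULL
  for (s in grid) {
    net <- unclass(suppressWarnings(threshold_to_sparsity(cm, s)))
    edges <- which(net > 0)
    if (!is.null(prev)) expect_true(all(prev %in% edges))
    prev <- edges
  }
})

test_that("node relabeling permutes the whole pipeline consistently", {
  set.seed(13)
  x <- matrix(rnorm(50 * 6), 50, 6)
  colnames(x) <- sprintf("n%d", 1:6)
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  w1 <- unclass(pearson_connectivity(roi_timeseries("a", x)))
  w2 <- unclass(pearson_connectivity(roi_timeseries("a", x[, perm])))
  expect_equal(w2, w1[perm, perm], ignore_attr = TRUE)
  r1 <- rectify_negative(fcgraph:::new_connectivity(w1, "residualized"))
  r2 <- rectify_negative(fcgraph:::new_connectivity(w1[perm, perm],
                                                    "residualized"))
  expect_equal(node_strength(r2), node_strength(r1)[perm])
  expect_equal(as.numeric(betweenness_centrality(unclass(r2))),
               as.numeric(betweenness_centrality(unclass(r1)))[perm])
})
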