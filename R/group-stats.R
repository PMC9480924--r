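#' Pooled-variance two-sample t statistic
#'
#' Classical equal-variance two-sample t, oriented as group `a` minus group
#' `b` (case minus control throughout the package). A zero pooled variance
#' yields `t = 0` with a warning.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Scalar t statistic.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  if (sp2 <= 0) {
    warning("zero pooled variance; returning t = 0")
    return(0)
  }
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# n x n_perm logical matrix of case-group assignments, sizes preserved.
perm_group_matrix <- function(n, n_case, n_perm) {
  z <- matrix(FALSE, n, n_perm)
  for (b in seq_len(n_perm)) z[sample.int(n, n_case), b] <- TRUE
  z
}

# Pooled t statistics for every permutation column of z (TRUE = pseudo-case).
perm_t_stats <- function(x, z) {
  n <- length(x)
  na <- sum(z[, 1])
  nb <- n - na
  sa <- as.numeric(crossprod(x, z))
  sqa <- as.numeric(crossprod(x^2, z))
  ma <- sa / na
  mb <- (sum(x) - sa) / nb
  ssa <- sqa - na * ma^2
  ssb <- (sum(x^2) - sqa) - nb * mb^2
  sp2 <- (ssa + ssb) / (n - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / na + 1 / nb))
  t <- (ma - mb) / se
  t[!is.finite(t)] <- 0
  t
}

#' Permutation null distribution of the two-sample t
#'
#' Subjects are pooled and randomly reassigned to pseudo-groups of the
#' original sizes; each shuffle yields a pseudo t-value.
#'
#' @param a,b Observed group values (case, control).
#' @param n_perm Number of label permutations (default 10,000).
#' @param seed Integer seed.
#' @return Numeric vector of `n_perm` pseudo t-values.
#' @export
permutation_null <- function(a, b, n_perm = 10000L, seed = 1L) {
  set.seed(seed)
  x <- c(a, b)
  z <- perm_group_matrix(length(x), length(a), n_perm)
  perm_t_stats(x, z)
}

# Nearest-rank percentile of a sample (exact and unambiguous at n = 10,000).
nearest_rank <- function(sorted_x, p) {
  sorted_x[max(1L, ceiling(p * length(sorted_x)))]
}

perm_result <- function(t_obs, null_t, rule = c("two_tailed", "lower")) {
  rule <- match.arg(rule)
  s <- sort(null_t)
  if (rule == "two_tailed") {
    lo <- nearest_rank(s, 0.025)
    hi <- nearest_rank(s, 0.975)
    sig <- t_obs > hi || t_obs < lo
    dir <- if (!sig) "none" else if (t_obs > hi) "increased" else "decreased"
    p_emp <- (1 + sum(abs(null_t) >= abs(t_obs))) / (length(null_t) + 1)
  } else {
    lo <- nearest_rank(s, 0.05)
    hi <- Inf
    sig <- t_obs < lo
    dir <- if (sig) "decreased" else "none"
    p_emp <- (1 + sum(null_t <= t_obs)) / (length(null_t) + 1)
  }
  list(t_obs = t_obs, null_lo = lo, null_hi = hi,
       n_perm = length(null_t), significant = sig, direction = dir,
       p_emp = p_emp)
}

#' Nodal permutation test between groups
#'
#' For each node, compares case versus control metric values with the pooled
#' two-sample t and a label-permutation null (group sizes preserved). The
#' observed t is declared significant when it falls above the 97.5th or below
#' the 2.5th nearest-rank percentile of its null. Each node gets an
#' independent, reproducible substream of the seed. No multiplicity
#' correction is applied by default (the nodal maps are exploratory); an
#' optional Benjamini-Hochberg column can be switched on.
#'
#' @param case_mat,control_mat Subjects x nodes metric matrices with matching
#'   column (node) sets.
#' @param n_perm Permutations per node (default 10,000).
#' @param seed Master seed; per-node seeds are derived from it.
#' @param fdr Add a `p_fdr` column (BH over `p_emp`)? Default `FALSE`.
#' @return Data frame with one row per node: `node`, `t_obs`, `null_lo`,
#'   `null_hi`, `p_emp`, `significant`, `direction` (and `p_fdr` if
#'   requested).
#' @export
nodal_permutation_test <- function(case_mat, control_mat, n_perm = 10000L,
                                   seed = 1L, fdr = FALSE) {
  stopifnot(ncol(case_mat) == ncol(control_mat))
  if (!is.null(colnames(case_mat)) && !is.null(colnames(control_mat)))
    stopifnot(identical(colnames(case_mat), colnames(control_mat)))
  n_nodes <- ncol(case_mat)
  set.seed(seed)
  node_seeds <- .sub_seeds(n_nodes)
  rows <- lapply(seq_len(n_nodes), function(j) {
    a <- case_mat[, j]
    b <- control_mat[, j]
    t_obs <- suppressWarnings(two_sample_t(a, b))
    null_t <- permutation_null(a, b, n_perm, node_seeds[j])
    perm_result(t_obs, null_t, "two_tailed")
  })
  nodes <- colnames(case_mat)
  if (is.null(nodes)) nodes <- as.character(seq_len(n_nodes))
  out <- data.frame(
    node = nodes,
    t_obs = vapply(rows, `[[`, numeric(1), "t_obs"),
    null_lo = vapply(rows, `[[`, numeric(1), "null_lo"),
    null_hi = vapply(rows, `[[`, numeric(1), "null_hi"),
    p_emp = vapply(rows, `[[`, numeric(1), "p_emp"),
    significant = vapply(rows, `[[`, logical(1), "significant"),
    direction = vapply(rows, `[[`, character(1), "direction"),
    stringsAsFactors = FALSE)
  if (fdr) out$p_fdr <- p.adjust(out$p_emp, method = "BH")
  out
}

#' One-tailed permutation test for global efficiency
#'
#' One scalar per subject; the null hypothesis is rejected only when the
#' observed case-minus-control t falls below the nearest-rank 5th percentile
#' of the permutation null (a lower-tailed rule: a case group above the
#' controls can never be declared significant).
#'
#' @param case,control Per-subject global efficiency values.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return List with `t_obs`, `null_lo`, `null_hi` (`Inf`), `n_perm`,
#'   `significant`, `direction`, `p_emp`.
#' @export
eglob_permutation_test <- function(case, control, n_perm = 10000L,
                                   seed = 1L) {
  t_obs <- suppressWarnings(two_sample_t(case, control))
  null_t <- permutation_null(case, control, n_perm, seed)
  perm_result(t_obs, null_t, "lower")
}

#' One-sided rank-sum comparison of node-averaged metrics
#'
#' Wilcoxon rank-sum (Mann-Whitney) test on per-subject node-averaged metric
#' values, exact when the combined sample size is at most 12 (and ties
#' permit), otherwise the normal approximation with continuity and tie
#' correction.
#'
#' @param case,control Per-subject node-averaged values.
#' @param side `"case_less"` (alternative: case below control, the default)
#'   or `"case_greater"`.
#' @return One-sided p-value.
#' @export
ranksum_global <- function(case, control, side = c("case_less",
                                                   "case_greater")) {
  side <- match.arg(side)
  alt <- if (side == "case_less") "less" else "greater"
  exact <- (length(case) + length(control)) <= 12
  suppressWarnings(
    wilcox.test(case, control, alternative = alt, exact = exact,
                correct = TRUE)$p.value)
}

#' Group comparison table for clinical and cognitive scores
#'
#' Per score: group mean and standard deviation plus a pooled-variance
#' two-sample t-test p-value with the requested sidedness (two-sided for
#' clinical scales, one-sided for cognitive t-scores by convention). Subjects
#' with a missing value are dropped per score; scores with fewer than two
#' observations in a group are skipped with a warning.
#'
#' @param subjects Subject table with a `group` column (`"case"` /
#'   `"control"`) and the score columns.
#' @param scores Character vector of score column names.
#' @param sides Named character vector mapping scores to `"two.sided"`,
#'   `"less"` (case below control) or `"greater"`; unnamed scores default to
#'   `default_side`.
#' @param default_side Side used when `sides` has no entry for a score.
#' @return Data frame: `score`, `mean_case`, `sd_case`, `mean_control`,
#'   `sd_control`, `n_case`, `n_control`, `side`, `p`.
#' @export
compare_score_table <- function(subjects, scores,
                                sides = character(),
                                default_side = "less") {
  stopifnot(all(scores %in% names(subjects)))
  rows <- lapply(scores, function(sc) {
    side <- if (sc %in% names(sides)) sides[[sc]] else default_side
    a <- subjects[[sc]][subjects$group == "case"]
    b <- subjects[[sc]][subjects$group == "control"]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      warning("score ", sc, " skipped: fewer than 2 observations in a group")
      return(NULL)
    }
    p <- t.test(a, b, alternative = side, var.equal = TRUE)$p.value
    data.frame(score = sc, mean_case = mean(a), sd_case = sd(a),
               mean_control = mean(b), sd_control = sd(b),
               n_case = length(a), n_control = length(b),
               side = side, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Metric matrices (subjects x nodes) and eglob vector for a list of networks.
metric_matrices <- function(networks, eloc_variant = "subgraph") {
  per <- lapply(networks, nodal_metrics, eloc_variant = eloc_variant)
  nodes <- rownames(as_plain_matrix(networks[[1]]))
  ids <- vapply(seq_along(networks), function(s) {
    id <- attr(networks[[s]], "subject_id")
    if (is.null(id)) as.character(s) else id
  }, character(1))
  pack <- function(name) {
    m <- do.call(rbind, lapply(per, `[[`, name))
    rownames(m) <- ids
    colnames(m) <- nodes
    m
  }
  list(bc = pack("bc"), strength = pack("strength"), cc = pack("cc"),
       eloc = pack("eloc"),
       eglob = stats::setNames(vapply(per, `[[`, numeric(1), "eglob"), ids))
}

# AUC-over-sparsity metric matrices: networks_by_subject[[s]] is a list of
# thresholded networks on the same increasing grid.
metric_auc_matrices <- function(networks_by_subject, grid,
                                eloc_variant = "subgraph") {
  per <- lapply(networks_by_subject, function(nets) {
    stopifnot(length(nets) == length(grid))
    mm <- lapply(nets, nodal_metrics, eloc_variant = eloc_variant)
    list(bc = apply(vapply(mm, `[[`, mm[[1]]$bc, "bc"), 1,
                    function(v) metric_auc(grid, v)),
         strength = apply(vapply(mm, `[[`, mm[[1]]$strength, "strength"), 1,
                          function(v) metric_auc(grid, v)),
         cc = apply(vapply(mm, `[[`, mm[[1]]$cc, "cc"), 1,
                    function(v) metric_auc(grid, v)),
         eloc = apply(vapply(mm, `[[`, mm[[1]]$eloc, "eloc"), 1,
                      function(v) metric_auc(grid, v)),
         eglob = metric_auc(grid, vapply(mm, `[[`, numeric(1), "eglob")))
  })
  nodes <- rownames(as_plain_matrix(networks_by_subject[[1]][[1]]))
  ids <- vapply(seq_along(networks_by_subject), function(s) {
    id <- attr(networks_by_subject[[s]][[1]], "subject_id")
    if (is.null(id)) as.character(s) else id
  }, character(1))
  pack <- function(name) {
    m <- do.call(rbind, lapply(per, `[[`, name))
    rownames(m) <- ids
    colnames(m) <- nodes
    m
  }
  list(bc = pack("bc"), strength = pack("strength"), cc = pack("cc"),
       eloc = pack("eloc"),
       eglob = stats::setNames(vapply(per, `[[`, numeric(1), "eglob"), ids))
}

#' Full group comparison of network measures
#'
#' Orchestrates the nodal and global comparisons for a two-group cohort of
#' rectified connectivity matrices: networks are thresholded (at one sparsity
#' or over a grid with AUC summarization), the four nodal measures are tested
#' per node with [nodal_permutation_test()], global efficiency with the
#' one-tailed [eglob_permutation_test()], and the node-averaged measures with
#' the one-sided rank-sum rule (or, optionally, a one-sided pooled t-test).
#' A single master seed determines every permutation null.
#'
#' @param case_mats,control_mats Lists of rectified `connectivity_matrix`
#'   objects.
#' @param sparsity Single sparsity (mode `"single_sparsity"`) or increasing
#'   grid of sparsities (mode `"auc_range"`, chosen automatically when
#'   `length(sparsity) > 1`).
#' @param n_perm Permutations per test (default 10,000).
#' @param seed Master seed.
#' @param eloc_variant Passed to [local_efficiency()].
#' @param global_test `"ranksum"` (default) or `"ttest"` for the
#'   node-averaged comparisons.
#' @return A `fc_group_report` list: `mode`, `sparsity`, `nodal` (named list
#'   of per-node test tables for bc/strength/cc/eloc), `eglob_test`,
#'   `global` (node-averaged comparison table), and the per-subject metric
#'   matrices in `metrics`.
#' @export
run_group_comparison <- function(case_mats, control_mats, sparsity,
                                 n_perm = 10000L, seed = 1L,
                                 eloc_variant = "subgraph",
                                 global_test = c("ranksum", "ttest")) {
  global_test <- match.arg(global_test)
  mode <- if (length(sparsity) > 1) "auc_range" else "single_sparsity"
  thr <- function(mats) {
    if (mode == "single_sparsity") {
      lapply(mats, threshold_to_sparsity, target_s = sparsity)
    } else {
      lapply(mats, function(m)
        lapply(sparsity, function(s) threshold_to_sparsity(m, s)))
    }
  }
  suppress_sparsity_warn <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("positive edges available", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  }
  case_nets <- suppress_sparsity_warn(thr(case_mats))
  ctrl_nets <- suppress_sparsity_warn(thr(control_mats))
  mm <- if (mode == "single_sparsity") {
    list(case = metric_matrices(case_nets, eloc_variant),
         control = metric_matrices(ctrl_nets, eloc_variant))
  } else {
    list(case = metric_auc_matrices(case_nets, sparsity, eloc_variant),
         control = metric_auc_matrices(ctrl_nets, sparsity, eloc_variant))
  }
  set.seed(seed)
  seeds <- .sub_seeds(5L)
  metrics <- c("bc", "strength", "cc", "eloc")
  nodal <- lapply(seq_along(metrics), function(k) {
    nodal_permutation_test(mm$case[[metrics[k]]], mm$control[[metrics[k]]],
                           n_perm = n_perm, seed = seeds[k])
  })
  names(nodal) <- metrics
  eglob_test <- eglob_permutation_test(mm$case$eglob, mm$control$eglob,
                                       n_perm = n_perm, seed = seeds[5])
  global <- do.call(rbind, lapply(metrics, function(k) {
    a <- rowMeans(mm$case[[k]])
    b <- rowMeans(mm$control[[k]])
    p <- if (global_test == "ranksum") {
      ranksum_global(a, b, "case_less")
    } else {
      t.test(a, b, alternative = "less", var.equal = TRUE)$p.value
    }
    data.frame(metric = k, mean_case = mean(a), sd_case = sd(a),
               mean_control = mean(b), sd_control = sd(b), p = p,
               stringsAsFactors = FALSE)
  }))
  structure(list(mode = mode, sparsity = sparsity, nodal = nodal,
                 eglob_test = eglob_test, global = global, metrics = mm,
                 settings = list(n_perm = n_perm, seed = seed,
                                 eloc_variant = eloc_variant,
                                 global_test = global_test)),
            class = "fc_group_report")
}

#' @export
print.fc_group_report <- function(x, ...) {
  cat("<fc_group_report>", x$mode, "at sparsity",
      paste(signif(range(x$sparsity), 3), collapse = "-"), "\n")
  for (m in names(x$nodal)) {
    sig <- x$nodal[[m]][x$nodal[[m]]$significant, , drop = FALSE]
    cat(sprintf("  %-9s %d/%d nodes flagged\n", m, nrow(sig),
                nrow(x$nodal[[m]])))
  }
  cat(sprintf("  eglob     t = %.3f, %s (p_emp = %.4f)\n",
              x$eglob_test$t_obs,
              if (x$eglob_test$significant) "significant" else
                "not significant",
              x$eglob_test$p_emp))
  invisible(x)
}
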