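#' Pearson correlation with two-sided p-value
#'
#' @param x,y Paired numeric vectors, `n >= 3`, non-constant.
#' @return List with `r`, `p_raw` and `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("zero variance in x")
  if (sd(y) == 0) stop("zero variance in y")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_raw = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, monotone and capped at 1,
#' returned in the original input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Fisher r-to-z transform
#'
#' @param r Correlation with `|r| < 1`.
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for a finite Fisher z")
  atanh(r)
}

#' Fisher-z difference between two independent correlations
#'
#' The standard two-sample statistic
#' `z_diff = (atanh(r_case) - atanh(r_control)) /
#'  sqrt(1/(n_case - 3) + 1/(n_control - 3))`
#' with a two-sided standard-normal p-value.
#'
#' @param r_case,r_control Correlations (`|r| < 1`).
#' @param n_case,n_control Sample sizes, each > 3.
#' @return List with `z_case`, `z_control`, `z_diff`, `p_normal`.
#' @export
z_difference <- function(r_case, n_case, r_control, n_control) {
  if (n_case <= 3 || n_control <= 3) stop("each group needs n > 3")
  zc <- fisher_z(r_case)
  zk <- fisher_z(r_control)
  se <- sqrt(1 / (n_case - 3) + 1 / (n_control - 3))
  z <- (zc - zk) / se
  list(z_case = zc, z_control = zk, z_diff = z,
       p_normal = 2 * pnorm(-abs(z)))
}

# Per-permutation correlations of (x, y) within pseudo-case (z TRUE) and
# pseudo-control columns, vectorized over permutations.
perm_group_correlations <- function(x, y, z) {
  n <- length(x)
  na <- sum(z[, 1])
  nb <- n - na
  sx <- as.numeric(crossprod(x, z))
  sy <- as.numeric(crossprod(y, z))
  sxx <- as.numeric(crossprod(x^2, z))
  syy <- as.numeric(crossprod(y^2, z))
  sxy <- as.numeric(crossprod(x * y, z))
  ra <- (na * sxy - sx * sy) /
    sqrt(pmax(na * sxx - sx^2, 0) * pmax(na * syy - sy^2, 0))
  tx <- sum(x); ty <- sum(y); txx <- sum(x^2); tyy <- sum(y^2)
  txy <- sum(x * y)
  bx <- tx - sx; by <- ty - sy
  bxx <- txx - sxx; byy <- tyy - syy; bxy <- txy - sxy
  rb <- (nb * bxy - bx * by) /
    sqrt(pmax(nb * bxx - bx^2, 0) * pmax(nb * byy - by^2, 0))
  list(r_case = ra, r_control = rb)
}

#' Permutation test for a group difference in correlation
#'
#' Shuffles group labels over the pooled (metric, score) pairs, recomputes
#' the per-group correlations and their Fisher-z difference each time, and
#' compares the observed z-difference to the two-sided empirical tail of the
#' null, `p_perm = (1 + #[|z_null| >= |z_obs|]) / (n_perm + 1)`. Subjects
#' with a missing score or metric are dropped before permuting. Permutations
#' producing a degenerate correlation (|r| numerically 1) are redrawn and
#' counted in `n_redrawn`.
#'
#' @param metric Per-subject nodal metric values.
#' @param score Per-subject behavioral scores (may contain `NA`).
#' @param group Character/factor of `"case"` / `"control"` labels.
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @return List: `z_case`, `z_control`, `n_case`, `n_control`, `z_diff`,
#'   `p_perm`, `p_normal`, `r_case`, `r_control`, `n_redrawn`.
#' @export
z_difference_permutation_test <- function(metric, score, group,
                                          n_perm = 10000L, seed = 1L) {
  ok <- is.finite(metric) & is.finite(score)
  x <- metric[ok]
  y <- score[ok]
  g <- as.character(group)[ok]
  n_case <- sum(g == "case")
  n_ctrl <- sum(g == "control")
  if (n_case <= 3 || n_ctrl <= 3) stop("each group needs n > 3")
  r_case <- cor(x[g == "case"], y[g == "case"])
  r_ctrl <- cor(x[g == "control"], y[g == "control"])
  obs <- z_difference(r_case, n_case, r_ctrl, n_ctrl)

  set.seed(seed)
  se <- sqrt(1 / (n_case - 3) + 1 / (n_ctrl - 3))
  z <- perm_group_matrix(length(x), n_case, n_perm)
  rr <- perm_group_correlations(x, y, z)
  bad <- !is.finite(rr$r_case) | !is.finite(rr$r_control) |
    abs(rr$r_case) >= 1 - 1e-12 | abs(rr$r_control) >= 1 - 1e-12
  n_redrawn <- 0L
  tries <- 0L
  while (any(bad) && tries < 50L) {
    n_redrawn <- n_redrawn + sum(bad)
    z2 <- perm_group_matrix(length(x), n_case, sum(bad))
    rr2 <- perm_group_correlations(x, y, z2)
    rr$r_case[bad] <- rr2$r_case
    rr$r_control[bad] <- rr2$r_control
    bad <- !is.finite(rr$r_case) | !is.finite(rr$r_control) |
      abs(rr$r_case) >= 1 - 1e-12 | abs(rr$r_control) >= 1 - 1e-12
    tries <- tries + 1L
  }
  null_z <- (atanh(rr$r_case) - atanh(rr$r_control)) / se
  p_perm <- (1 + sum(abs(null_z) >= abs(obs$z_diff))) / (n_perm + 1)
  list(z_case = obs$z_case, z_control = obs$z_control,
       n_case = n_case, n_control = n_ctrl, z_diff = obs$z_diff,
       p_perm = p_perm, p_normal = obs$p_normal,
       r_case = r_case, r_control = r_ctrl, n_redrawn = n_redrawn)
}

#' Robust outlier mask by median absolute deviation
#'
#' Flags points whose robust distance `|x - median| / (1.4826 * MAD)` exceeds
#' `n_mads` (default 2.5, a conservative recommendation for outlier
#' screening); the scaled MAD equals the standard deviation for normal data.
#' If the MAD is zero all points are kept with a warning.
#'
#' @param values Numeric vector (`n >= 4`).
#' @param n_mads Cutoff in scaled-MAD units.
#' @return Logical keep-mask, `TRUE` for retained points.
#' @export
mad_outlier_mask <- function(values, n_mads = 2.5) {
  stopifnot(length(values) >= 4)
  m <- mad(values)  # 1.4826 * median(|x - median|)
  if (m == 0) {
    warning("MAD is zero; keeping all points")
    return(rep(TRUE, length(values)))
  }
  abs(values - median(values)) / m <= n_mads
}

# Correlations of one metric column against many score columns, with
# pairwise-complete observations; p from the t distribution.
cor_with_p <- function(x, score_mat) {
  r <- numeric(ncol(score_mat))
  p <- numeric(ncol(score_mat))
  n <- integer(ncol(score_mat))
  for (k in seq_len(ncol(score_mat))) {
    y <- score_mat[, k]
    ok <- is.finite(x) & is.finite(y)
    n[k] <- sum(ok)
    if (n[k] < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      r[k] <- NA_real_
      p[k] <- NA_real_
      next
    }
    r[k] <- cor(x[ok], y[ok])
    tt <- r[k] * sqrt((n[k] - 2) / max(1 - r[k]^2, .Machine$double.eps))
    p[k] <- 2 * pt(-abs(tt), n[k] - 2)
  }
  list(r = r, p = p, n = n)
}

#' Brain-behavior correlation workflow
#'
#' For every requested (metric, node) pair this computes, within each group,
#' the Pearson correlation between the nodal metric and each behavioral
#' score, applies Benjamini-Hochberg correction across the score battery
#' within that (metric, node, group) family, and forwards every pair that is
#' FDR-significant in either group to the Fisher-z difference permutation
#' test between groups. A sensitivity rerun with MAD outlier screening (on
#' metric and score within each group) is reported alongside.
#'
#' @param subject_metrics Named list of metric matrices (subjects x nodes,
#'   rownames = subject ids).
#' @param subjects Subject table (`subject_id`, `group`, score columns).
#' @param scores Score column names (default: the 16 cognitive subtests).
#' @param nodes Node names or indices to analyze (default: all).
#' @param metrics Which metrics from `subject_metrics` to analyze.
#' @param fdr_q FDR threshold (default 0.05).
#' @param n_perm Permutations for the z-difference test.
#' @param seed Master seed.
#' @param n_mads MAD cutoff for the sensitivity rerun.
#' @return List of class `fc_behavior_report`: `correlations` (tidy table:
#'   metric, node, score, group, n, r, p_raw, p_fdr, significant,
#'   r_mad, p_mad, outliers_removed) and `z_tests` (one row per flagged
#'   pair with the permutation result).
#' @export
run_brain_behavior <- function(subject_metrics, subjects,
                               scores = cnt_subtest_names(),
                               nodes = NULL,
                               metrics = names(subject_metrics),
                               fdr_q = 0.05, n_perm = 10000L, seed = 1L,
                               n_mads = 2.5) {
  stopifnot(all(scores %in% names(subjects)))
  score_mat <- as.matrix(subjects[, scores, drop = FALSE])
  groups <- c("case", "control")
  set.seed(seed)
  cor_rows <- list()
  flagged <- list()
  for (m in metrics) {
    mat <- subject_metrics[[m]]
    mat <- mat[subjects$subject_id, , drop = FALSE]
    node_set <- if (is.null(nodes)) colnames(mat) else nodes
    if (is.null(node_set)) node_set <- seq_len(ncol(mat))
    for (v in node_set) {
      fam <- list()
      for (g in groups) {
        idx <- subjects$group == g
        res <- cor_with_p(mat[idx, v], score_mat[idx, , drop = FALSE])
        p_fdr <- bh_fdr(res$p)
        # MAD sensitivity rerun within group
        r_mad <- rep(NA_real_, length(scores))
        p_mad <- rep(NA_real_, length(scores))
        removed <- rep(NA_integer_, length(scores))
        for (k in seq_along(scores)) {
          x <- mat[idx, v]
          y <- score_mat[idx, k]
          ok <- is.finite(x) & is.finite(y)
          if (sum(ok) < 5) next
          keep <- suppressWarnings(
            mad_outlier_mask(x[ok], n_mads) & mad_outlier_mask(y[ok], n_mads))
          removed[k] <- sum(!keep)
          if (sum(keep) >= 3 && sd(x[ok][keep]) > 0 && sd(y[ok][keep]) > 0) {
            sub <- cor_with_p(x[ok][keep],
                              matrix(y[ok][keep], ncol = 1))
            r_mad[k] <- sub$r
            p_mad[k] <- sub$p
          }
        }
        fam[[g]] <- data.frame(
          metric = m, node = as.character(v), score = scores, group = g,
          n = res$n, r = res$r, p_raw = res$p, p_fdr = p_fdr,
          significant = !is.na(p_fdr) & p_fdr < fdr_q,
          r_mad = r_mad, p_mad = p_mad, outliers_removed = removed,
          stringsAsFactors = FALSE)
      }
      fam_df <- rbind(fam$case, fam$control)
      cor_rows[[length(cor_rows) + 1L]] <- fam_df
      hit <- unique(fam_df$score[fam_df$significant])
      for (sc in hit) {
        flagged[[length(flagged) + 1L]] <-
          list(metric = m, node = as.character(v), score = sc)
      }
    }
  }
  correlations <- do.call(rbind, cor_rows)
  z_seeds <- if (length(flagged)) .sub_seeds(length(flagged)) else integer()
  z_tests <- do.call(rbind, lapply(seq_along(flagged), function(i) {
    f <- flagged[[i]]
    mat <- subject_metrics[[f$metric]][subjects$subject_id, , drop = FALSE]
    zt <- z_difference_permutation_test(
      mat[, f$node], subjects[[f$score]], subjects$group,
      n_perm = n_perm, seed = z_seeds[i])
    data.frame(metric = f$metric, node = f$node, score = f$score,
               r_case = zt$r_case, r_control = zt$r_control,
               n_case = zt$n_case, n_control = zt$n_control,
               z_diff = zt$z_diff, p_perm = zt$p_perm,
               p_normal = zt$p_normal, n_redrawn = zt$n_redrawn,
               stringsAsFactors = FALSE)
  }))
  structure(list(correlations = correlations, z_tests = z_tests,
                 settings = list(fdr_q = fdr_q, n_perm = n_perm, seed = seed,
                                 n_mads = n_mads)),
            class = "fc_behavior_report")
}

#' @export
print.fc_behavior_report <- function(x, ...) {
  nsig <- sum(x$correlations$significant, na.rm = TRUE)
  cat("<fc_behavior_report>", nrow(x$correlations), "correlations,",
      nsig, "FDR-significant,",
      if (is.null(x$z_tests)) 0L else nrow(x$z_tests),
      "z-difference tests\n")
  invisible(x)
}
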