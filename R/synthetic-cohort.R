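#' Configuration for a synthetic resting-state cohort
#'
#' Describes a two-group cohort of ROI-averaged time series with modular
#' correlation structure, an optional group-specific attenuation of the
#' couplings of chosen "effect" nodes, linear age/sex confounds acting on all
#' edges through a shared latent signal, and an optional coupling between a
#' nodal network metric and one behavioral score.
#'
#' Defaults follow the study design the package validates against: 112 nodes,
#' 29 subjects per group, and time series long enough (180 timepoints, about
#' six minutes of fMRI at a 2 s repetition time) for stable Pearson
#' correlations. The within/between-module correlation targets (0.4 / 0.1)
#' give realistic resting-state connectivity levels with clear community
#' structure.
#'
#' @param n_nodes Number of network nodes (ROIs).
#' @param n_modules Number of correlation modules (communities); nodes are
#'   split into contiguous, nearly equal blocks.
#' @param t_points Timepoints per subject (>= 30).
#' @param n_per_group Subjects in each of the case and control groups.
#' @param base_within_r Target correlation between nodes sharing a module.
#' @param base_between_r Target correlation between nodes in different
#'   modules; must satisfy `0 < base_between_r <= base_within_r < 1`.
#' @param effect_nodes Integer indices (1-based) of nodes whose couplings are
#'   attenuated in the case group.
#' @param effect_attenuation Multiplicative factor in \[0, 1\] applied to the
#'   off-diagonal covariance entries involving `effect_nodes` in the case
#'   group. 1 means no group difference.
#' @param confound_age_slope Amplitude of the shared latent confound signal at
#'   the top of the age range (see Details).
#' @param confound_sex_delta Additional latent-signal amplitude for male
#'   subjects.
#' @param behavior_coupling Optional list describing a metric-to-score
#'   coupling: `list(metric=, node=, score=, slope=, noise_sd=, case_only=)`.
#'   Applied by [generate_behavior_scores()] once nodal metrics are available.
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   cohort exactly.
#'
#' @details Confounds are injected by mixing a per-subject scaled standard
#' normal latent signal into every node:
#' `alpha_s = confound_age_slope * (age_s - 20)/50 + confound_sex_delta *
#' (sex_s == "M")`, which adds `alpha_s^2` to every edge covariance -- a
#' rank-one edge confound that edge-wise residualization on age and sex is
#' meant to remove.
#'
#' @return A validated `cohort_config` list.
#' @seealso [build_covariance()], [generate_cohort()],
#'   [generate_behavior_scores()]
#' @export
#' @examples
#' cfg <- cohort_config(n_nodes = 20, n_modules = 4, t_points = 60,
#'                      n_per_group = 8, seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort$timeseries)
cohort_config <- function(n_nodes = 112L, n_modules = 6L, t_points = 180L,
                          n_per_group = 29L, base_within_r = 0.4,
                          base_between_r = 0.1, effect_nodes = integer(),
                          effect_attenuation = 1, confound_age_slope = 0.2,
                          confound_sex_delta = 0.1, behavior_coupling = NULL,
                          seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes), n_modules = as.integer(n_modules),
              t_points = as.integer(t_points),
              n_per_group = as.integer(n_per_group),
              base_within_r = base_within_r, base_between_r = base_between_r,
              effect_nodes = as.integer(effect_nodes),
              effect_attenuation = effect_attenuation,
              confound_age_slope = confound_age_slope,
              confound_sex_delta = confound_sex_delta,
              behavior_coupling = behavior_coupling, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_nodes < 2L) stop("n_nodes must be >= 2")
  if (cfg$n_modules < 1L || cfg$n_modules > cfg$n_nodes)
    stop("n_modules must be in [1, n_nodes]")
  if (cfg$t_points < 30L) stop("t_points must be >= 30")
  if (cfg$n_per_group < 2L) stop("n_per_group must be >= 2")
  if (!(cfg$base_between_r > 0 && cfg$base_between_r <= cfg$base_within_r &&
        cfg$base_within_r < 1))
    stop("need 0 < base_between_r <= base_within_r < 1")
  if (length(cfg$effect_nodes) &&
      (any(cfg$effect_nodes < 1L) || any(cfg$effect_nodes > cfg$n_nodes)))
    stop("effect_nodes must index nodes in [1, n_nodes]")
  if (cfg$effect_attenuation < 0 || cfg$effect_attenuation > 1)
    stop("effect_attenuation must be in [0, 1]")
  if (cfg$confound_age_slope < 0 || cfg$confound_sex_delta < 0)
    stop("confound magnitudes must be non-negative")
  if (!is.null(cfg$behavior_coupling)) {
    bc <- cfg$behavior_coupling
    need <- c("metric", "node", "score", "slope", "noise_sd")
    if (!all(need %in% names(bc)))
      stop("behavior_coupling needs fields: ", paste(need, collapse = ", "))
  }
  invisible(cfg)
}

# Contiguous near-equal module assignment.
module_assignment <- function(n_nodes, n_modules) {
  sort(rep_len(seq_len(n_modules), n_nodes))
}

#' Group covariance matrix for a synthetic cohort
#'
#' Builds the node-by-node covariance implied by a [cohort_config()]: unit
#' diagonal, `base_within_r` within modules, `base_between_r` between modules.
#' For the case group, off-diagonal entries in the rows and columns of the
#' configured effect nodes are multiplied by `effect_attenuation`. If the
#' attenuated matrix loses positive semidefiniteness it is repaired by
#' clipping negative eigenvalues at zero and renormalizing to a unit diagonal;
#' the returned matrix then carries attribute `repaired = TRUE` and a message
#' is emitted.
#'
#' @param config A [cohort_config()].
#' @param group `"case"` or `"control"`.
#' @return A symmetric positive-semidefinite matrix with unit diagonal.
#' @export
build_covariance <- function(config, group = c("control", "case")) {
  validate_cohort_config(config)
  group <- match.arg(group)
  mod <- module_assignment(config$n_nodes, config$n_modules)
  same <- outer(mod, mod, "==")
  sigma <- ifelse(same, config$base_within_r, config$base_between_r)
  diag(sigma) <- 1
  repaired <- FALSE
  if (group == "case" && length(config$effect_nodes) &&
      config$effect_attenuation < 1) {
    a <- config$effect_attenuation
    f <- config$effect_nodes
    scal <- matrix(1, config$n_nodes, config$n_nodes)
    scal[f, ] <- a
    scal[, f] <- a
    diag(scal) <- 1
    sigma <- sigma * scal
    ev <- eigen(sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-10) {
      vals <- pmax(ev$values, 0)
      sigma <- ev$vectors %*% (vals * t(ev$vectors))
      d <- 1 / sqrt(diag(sigma))
      sigma <- sigma * tcrossprod(d)
      sigma <- (sigma + t(sigma)) / 2
      diag(sigma) <- 1
      repaired <- TRUE
      message("build_covariance: attenuated covariance repaired by ",
              "eigenvalue clipping")
    }
  }
  attr(sigma, "repaired") <- repaired
  sigma
}

#' Names of the 16 cognitive subtests
#'
#' Subtest battery layout used by the cohort generator and the score-table
#' report: executive set-shifting, forward/backward digit span, verbal and
#' visual learning (first trial, fifth trial, delayed recall, trial sum), and
#' five word-color attention conditions. All are reported as t-scores
#' (population mean 50, standard deviation 10).
#'
#' @return Character vector of length 16.
#' @export
cnt_subtest_names <- function() {
  c("card_sorting",
    "digit_span_forward", "digit_span_backward",
    "verbal_learning_a1", "verbal_learning_a5",
    "verbal_learning_delayed", "verbal_learning_sum",
    "visual_learning_a1", "visual_learning_a5",
    "visual_learning_delayed", "visual_learning_sum",
    "word_color_word", "word_color_color",
    "word_color_colorword", "word_color_word_of_colorword",
    "word_color_color_of_colorword")
}

default_node_names <- function(n_nodes) {
  if (n_nodes == 112L) {
    default_node_table()$name
  } else {
    sprintf("node%03d", seq_len(n_nodes))
  }
}

#' Generate a synthetic multi-subject cohort
#'
#' Draws each subject's ROI time series as independent multivariate-normal
#' samples from the group covariance of [build_covariance()], adds the
#' age/sex-driven latent confound signal, and assembles a subject table with
#' demographics, clinical scales (depression, global cognition, frontal
#' battery, with realistic group separation) and 16 cognitive t-scores drawn
#' as N(50, 10). Behavioral coupling to a network metric, if configured, is
#' applied later by [generate_behavior_scores()] because it needs computed
#' metrics.
#'
#' @param config A [cohort_config()].
#' @return A list with `timeseries` (list of [roi_timeseries()] objects,
#'   cases then controls) and `subjects` (data.frame with `subject_id`,
#'   `group`, `age`, `sex`, clinical columns and one column per cognitive
#'   subtest).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_per_group
  ids <- c(sprintf("case%03d", seq_len(n)), sprintf("ctrl%03d", seq_len(n)))
  group <- rep(c("case", "control"), each = n)
  age <- round(runif(2L * n, 20, 70))
  sex <- c(rep_len(c("F", "M"), n), rep_len(c("F", "M"), n))
  node_names <- default_node_names(config$n_nodes)

  chol_case <- chol(nearest_psd_chol(build_covariance(config, "case")))
  chol_ctrl <- chol(nearest_psd_chol(build_covariance(config, "control")))
  alpha <- config$confound_age_slope * (age - 20) / 50 +
    config$confound_sex_delta * (sex == "M")

  subj_seeds <- .sub_seeds(2L * n + 1L)
  ts <- vector("list", 2L * n)
  for (s in seq_len(2L * n)) {
    set.seed(subj_seeds[s])
    z <- matrix(rnorm(config$t_points * config$n_nodes), config$t_points)
    x <- z %*% (if (group[s] == "case") chol_case else chol_ctrl)
    if (alpha[s] > 0) x <- x + alpha[s] * rnorm(config$t_points)
    colnames(x) <- node_names
    ts[[s]] <- roi_timeseries(ids[s], x)
  }

  set.seed(subj_seeds[2L * n + 1L])
  subjects <- data.frame(subject_id = ids, group = group, age = age,
                         sex = sex, stringsAsFactors = FALSE)
  # Clinical scales with the group separation typical of subacute concussion
  # cohorts; clipped to instrument ranges.
  is_case <- group == "case"
  subjects$bdi <- pmax(0, round(rnorm(2L * n, ifelse(is_case, 14, 4),
                                      ifelse(is_case, 10, 4))))
  subjects$moca <- pmin(30, pmax(0, round(rnorm(2L * n,
                                                ifelse(is_case, 25, 27),
                                                ifelse(is_case, 4, 2)))))
  subjects$fab <- pmin(18, pmax(0, round(rnorm(2L * n,
                                               ifelse(is_case, 16, 17.2),
                                               ifelse(is_case, 2.2, 1.2)))))
  for (sc in cnt_subtest_names()) {
    subjects[[sc]] <- rnorm(2L * n, 50, 10)
  }
  list(timeseries = ts, subjects = subjects)
}

# Tiny diagonal jitter so chol() succeeds on matrices that are PSD only up to
# rounding (e.g. after eigenvalue clipping).
nearest_psd_chol <- function(sigma) {
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-10) sigma <- sigma + diag(1e-8 - min(ev, 0), nrow(sigma))
  sigma
}

#' Couple a behavioral score to a nodal network metric
#'
#' Produces scores `50 + slope * standardized(metric) + N(0, noise_sd)` for
#' subjects in the coupled group(s). With `case_only = TRUE` (mirroring an
#' association present in patients but absent in controls), control scores are
#' drawn as pure noise around 50 with matched marginal variance
#' `sqrt(slope^2 + noise_sd^2)`. The implied population correlation in the
#' coupled group is slope over `sqrt(slope^2 + noise_sd^2)`; see
#' [coupling_slope_for_r()].
#'
#' @param subject_metrics Named list of metric matrices (subjects x nodes,
#'   rownames = subject ids), e.g. the `nodal` element of pipeline output.
#' @param subjects Subject table with `subject_id` and `group`.
#' @param coupling List with `metric` (name into `subject_metrics`), `node`
#'   (index or node name), `slope`, `noise_sd`, and optional `case_only`
#'   (default `TRUE`).
#' @param seed Integer seed.
#' @return Numeric score vector aligned with `subjects`.
#' @export
generate_behavior_scores <- function(subject_metrics, subjects, coupling,
                                     seed = 1L) {
  if (!coupling$metric %in% names(subject_metrics))
    stop("unknown metric name: ", coupling$metric)
  m <- subject_metrics[[coupling$metric]]
  m <- m[subjects$subject_id, , drop = FALSE]
  vals <- m[, coupling$node]
  case_only <- isTRUE(coupling$case_only) || is.null(coupling$case_only)
  set.seed(seed)
  out <- numeric(nrow(subjects))
  sd_total <- sqrt(coupling$slope^2 + coupling$noise_sd^2)
  for (g in unique(subjects$group)) {
    idx <- which(subjects$group == g)
    if (g == "case" || !case_only) {
      z <- as.numeric(scale(vals[idx]))
      out[idx] <- 50 + coupling$slope * z +
        rnorm(length(idx), 0, coupling$noise_sd)
    } else {
      out[idx] <- 50 + rnorm(length(idx), 0, sd_total)
    }
  }
  out
}

#' Slope giving a target metric-score correlation
#'
#' Inverts the relation r `= slope / sqrt(slope^2 + noise_sd^2)` so
#' simulations can plant
#' an association of known population strength.
#'
#' @param r Target correlation in (-1, 1).
#' @param noise_sd Score noise standard deviation (default 10, the t-score
#'   scale).
#' @return Slope on the t-score scale.
#' @export
#' @examples
#' coupling_slope_for_r(0.74)
coupling_slope_for_r <- function(r, noise_sd = 10) {
  stopifnot(abs(r) < 1)
  noise_sd * r / sqrt(1 - r^2)
}
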