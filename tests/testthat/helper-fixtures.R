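# Shared small-cohort fixtures, built in code at test time.

small_cohort_config <- function(seed = 1L, ...) {
  args <- list(n_nodes = 20L, n_modules = 4L, t_points = 60L,
               n_per_group = 8L, confound_age_slope = 0,
               confound_sex_delta = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_config, args)
}

# Generate a cohort and carry it through connectivity -> residualize ->
# rectify; returns the subject table and the list of rectified matrices.
cohort_rectified <- function(config) {
  co <- generate_cohort(config)
  raw <- lapply(co$timeseries, pearson_connectivity)
  rect <- lapply(residualize_edges(raw, co$subjects), rectify_negative)
  list(subjects = co$subjects, rect = rect, timeseries = co$timeseries)
}

# Strength matrix (subjects x nodes) at a fixed sparsity, plus eglob vector.
cohort_strength_eglob <- function(rect, sparsity = 0.262) {
  nets <- suppressWarnings(
    lapply(rect, threshold_to_sparsity, target_s = sparsity))
  n_nodes <- nrow(nets[[1]])
  list(strength = t(vapply(nets, node_strength, numeric(n_nodes))),
       eglob = vapply(nets, global_efficiency, numeric(1)))
}
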