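test_that("config invariants are enforced", {
  expect_error(cohort_config(base_within_r = 0.2, base_between_r = 0.5),
               "base_between_r")
  expect_error(cohort_config(t_points = 10), "t_points")
  expect_error(cohort_config(effect_nodes = 500), "effect_nodes")
  expect_error(cohort_config(effect_attenuation = 1.5), "attenuation")
})

test_that("group covariances share structure and attenuation acts on case", {
  cfg <- small_cohort_config(effect_nodes = c(3L, 7L),
                             effect_attenuation = 1)
  expect_identical(build_covariance(cfg, "case"),
                   build_covariance(cfg, "control"))

  cfg0 <- small_cohort_config(effect_nodes = 5L, effect_attenuation = 0)
  sc <- build_covariance(cfg0, "case")
  expect_true(all(sc[5, -5] == 0))
  expect_equal(diag(sc), rep(1, 20))

  cfg5 <- small_cohort_config(effect_nodes = 5L, effect_attenuation = 0.5)
  s5 <- build_covariance(cfg5, "case")
  s1 <- build_covariance(cfg5, "control")
  expect_equal(s5[5, -5], 0.5 * s1[5, -5])
  ev <- eigen(s5, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8)
})

test_that("attenuated node has lower sample strength in the case group", {
  hits <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_nodes = 12L, n_modules = 3L, t_points = 60L,
                         n_per_group = 6L, effect_nodes = 4L,
                         effect_attenuation = 0.5,
                         confound_age_slope = 0, confound_sex_delta = 0,
                         seed = 1000L + r)
    co <- generate_cohort(cfg)
    st <- vapply(co$timeseries, function(ts)
      node_strength(rectify_negative(pearson_connectivity(ts)))[4],
      numeric(1))
    is_case <- co$subjects$group == "case"
    if (mean(st[is_case]) < mean(st[!is_case])) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("cohort generation is deterministic and sized correctly", {
  cfg <- small_cohort_config(seed = 42L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  full <- cohort_config(n_nodes = 112L, n_per_group = 29L, t_points = 40L,
                        seed = 2L)
  co <- generate_cohort(full)
  expect_length(co$timeseries, 58L)
  expect_equal(nrow(co$subjects), 58L)
  expect_equal(table(co$subjects$group)[["case"]], 29L)
  expect_equal(ncol(co$timeseries[[1]]$data), 112L)
  expect_true(all(cnt_subtest_names() %in% names(co$subjects)))
})

test_that("null cohorts show no systematic group difference in edges", {
  diffs <- vapply(seq_len(50L), function(r) {
    cfg <- cohort_config(n_nodes = 10L, n_modules = 2L, t_points = 50L,
                         n_per_group = 6L, confound_age_slope = 0,
                         confound_sex_delta = 0, seed = 7000L + r)
    co <- generate_cohort(cfg)
    cors <- vapply(co$timeseries, function(ts) {
      w <- pearson_connectivity(ts)
      mean(w[upper.tri(w)])
    }, numeric(1))
    is_case <- co$subjects$group == "case"
    mean(cors[is_case]) - mean(cors[!is_case])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})

test_that("effect monotonicity: stronger attenuation, larger deficit", {
  deficit <- function(atten) {
    mean(vapply(seq_len(30L), function(r) {
      cfg <- cohort_config(n_nodes = 12L, n_modules = 3L, t_points = 60L,
                           n_per_group = 6L, effect_nodes = 4L,
                           effect_attenuation = atten,
                           confound_age_slope = 0, confound_sex_delta = 0,
                           seed = 3000L + r)
      co <- generate_cohort(cfg)
      st <- vapply(co$timeseries, function(ts)
        node_strength(rectify_negative(pearson_connectivity(ts)))[4],
        numeric(1))
      is_case <- co$subjects$group == "case"
      mean(st[!is_case]) - mean(st[is_case])
    }, numeric(1)))
  }
  d <- vapply(c(1, 0.6, 0.2), deficit, numeric(1))
  expect_true(d[2] > d[1])
  expect_true(d[3] > d[2])
})

test_that("behavior scores couple to the metric at the configured strength", {
  # slope 0: sample r stays in the null band
  set.seed(5)
  metric <- matrix(rnorm(28), ncol = 1,
                   dimnames = list(sprintf("case%03d", 1:28), "n1"))
  subjects <- data.frame(subject_id = rownames(metric), group = "case")
  s0 <- generate_behavior_scores(list(strength = metric), subjects,
                                 list(metric = "strength", node = 1,
                                      score = "s", slope = 0, noise_sd = 10),
                                 seed = 9)
  expect_lt(abs(cor(metric[, 1], s0)), 2.58 / sqrt(25))  # ~99% null band

  # near-zero noise: r -> 1
  s1 <- generate_behavior_scores(list(strength = metric), subjects,
                                 list(metric = "strength", node = 1,
                                      score = "s", slope = 5,
                                      noise_sd = 1e-8), seed = 9)
  expect_gt(cor(metric[, 1], s1), 0.999)

  # slope targeting r = 0.74 recovers r within +/- 0.15 on average at n = 28
  slope <- coupling_slope_for_r(0.74)
  rs <- vapply(seq_len(100L), function(r) {
    set.seed(100 + r)
    m <- matrix(rnorm(28), ncol = 1,
                dimnames = list(rownames(metric), "n1"))
    s <- generate_behavior_scores(list(strength = m), subjects,
                                  list(metric = "strength", node = 1,
                                       score = "s", slope = slope,
                                       noise_sd = 10), seed = 200 + r)
    cor(m[, 1], s)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.74), 0.15)

  expect_error(
    generate_behavior_scores(list(strength = metric), subjects,
                             list(metric = "nope", node = 1, score = "s",
                                  slope = 1, noise_sd = 1)),
    "unknown metric")
})
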