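#' Run the full connectivity analysis pipeline
#'
#' Executes, in order: time-series and subject-table ingestion, Pearson
#' connectivity, edge-wise age/sex residualization and negative-edge
#' rectification (order per config), sparsity selection, thresholding (single
#' sparsity and, in range mode, the full grid with AUC summaries), graph
#' metrics, permutation-based group comparison, the score-table comparison,
#' and the brain-behavior correlation workflow. Every intermediate is
#' persisted as delimited text under `output_dir` together with a JSON run
#' manifest (seed, config hash, stage log), so any table can be regenerated.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle: `subjects`, `node_table`,
#'   `selection`, `sparsity_used`, `group_report` (and `group_report_auc` in
#'   range mode), `score_table`, `behavior`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  stage <- function(name, expr) {
    stages[[length(stages) + 1L]] <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  node_table <- stage("read_nodes", {
    if (is.null(config$node_table)) default_node_table()
    else read_node_table(config$node_table)
  })
  subjects <- stage("read_subjects", read_subject_table(config$subject_table))
  ts <- stage("read_timeseries",
              read_timeseries_dir(config$timeseries_dir, node_table))
  ids <- vapply(ts, `[[`, character(1), "subject_id")
  if (!setequal(ids, subjects$subject_id))
    stop("pipeline stage 'read_timeseries' failed: subject ids in time ",
         "series and subject table differ", call. = FALSE)
  ts <- ts[match(subjects$subject_id, ids)]

  raw <- stage("connectivity", lapply(ts, pearson_connectivity))
  proc <- stage("residualize_rectify", {
    if (config$residualize_first) {
      lapply(residualize_edges(raw, subjects), rectify_negative)
    } else {
      residualize_edges(lapply(raw, rectify_negative), subjects)
    }
  })
  # After rectify-then-residualize the matrices can re-acquire small negative
  # entries; clamp so thresholding sees a rectified matrix either way.
  if (!config$residualize_first) proc <- lapply(proc, rectify_negative)

  conn_dir <- file.path(out, "connectivity")
  dir.create(conn_dir, showWarnings = FALSE)
  for (m in proc) {
    write_matrix_tsv(m, file.path(conn_dir,
                                  paste0(attr(m, "subject_id"), ".tsv")))
  }

  selection <- NULL
  sparsity_used <- switch(config$sparsity_mode,
    fixed = config$sparsity,
    auto_select = {
      selection <- stage("sparsity_selection", select_group_sparsity(proc))
      selection$selected_s
    },
    range = {
      selection <- stage("sparsity_selection", select_group_sparsity(proc))
      selection$selected_s
    })

  is_case <- subjects$group == "case"
  report <- stage("group_comparison",
                  run_group_comparison(proc[is_case], proc[!is_case],
                                       sparsity = sparsity_used,
                                       n_perm = config$n_perm,
                                       seed = config$seed,
                                       eloc_variant = config$eloc_variant,
                                       global_test = config$global_test))
  report_auc <- NULL
  if (config$sparsity_mode == "range") {
    report_auc <- stage("group_comparison_auc",
                        run_group_comparison(proc[is_case], proc[!is_case],
                                             sparsity = sparsity_grid(config),
                                             n_perm = config$n_perm,
                                             seed = config$seed + 1L,
                                             eloc_variant =
                                               config$eloc_variant,
                                             global_test =
                                               config$global_test))
  }

  metric_dir <- file.path(out, "metrics")
  dir.create(metric_dir, showWarnings = FALSE)
  for (m in c("bc", "strength", "cc", "eloc")) {
    tab <- rbind(report$metrics$case[[m]], report$metrics$control[[m]])
    write.table(data.frame(subject_id = rownames(tab), tab,
                           check.names = FALSE),
                file.path(metric_dir, paste0(m, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  eg <- c(report$metrics$case$eglob, report$metrics$control$eglob)
  write.table(data.frame(subject_id = names(eg), eglob = eg),
              file.path(metric_dir, "eglob.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  score_cols <- intersect(config$scores, names(subjects))
  score_table <- if (length(score_cols)) {
    stage("score_comparison",
          suppressWarnings(compare_score_table(subjects, score_cols)))
  }

  behavior <- if (length(score_cols)) {
    stage("brain_behavior",
          run_brain_behavior(report$metrics$case |>
                               merge_metric_groups(report$metrics$control),
                             subjects, scores = score_cols,
                             fdr_q = config$fdr_q, n_perm = config$n_perm,
                             seed = config$seed + 2L,
                             n_mads = config$n_mads))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("fcgraph")),
    seed = config$seed,
    n_perm = config$n_perm,
    sparsity_mode = config$sparsity_mode,
    sparsity_used = sparsity_used,
    config_hash = unname(tools::md5sum(
      write_pipeline_config(config, file.path(out, "config.yaml")))),
    n_subjects = nrow(subjects),
    n_nodes = nrow(node_table),
    stages = stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  bundle <- list(subjects = subjects, node_table = node_table,
                 selection = selection, sparsity_used = sparsity_used,
                 group_report = report, group_report_auc = report_auc,
                 score_table = score_table, behavior = behavior,
                 manifest = manifest)
  write_report(bundle, out)
  invisible(bundle)
}

# Stack case and control metric matrices into full-cohort matrices keyed by
# subject id, as run_brain_behavior() expects.
merge_metric_groups <- function(case_m, control_m) {
  out <- lapply(c("bc", "strength", "cc", "eloc"), function(m) {
    rbind(case_m[[m]], control_m[[m]])
  })
  names(out) <- c("bc", "strength", "cc", "eloc")
  out
}

#' Write human-readable report tables
#'
#' Emits the delimited-text report tables for a pipeline result bundle: the
#' score comparison (score, group means and SDs, p), the global network
#' table (metric, group means and SDs, p), the significant-nodes table
#' (characteristic, region, lobe, direction coded +1/-1, t), the tidy
#' correlation results, and a machine-readable `results.json`.
#'
#' @param bundle Result bundle from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[length(paths) + 1L]] <<- p
  }

  if (!is.null(bundle$score_table)) {
    emit(bundle$score_table, "score_comparison.tsv")
  }

  rep <- bundle$group_report
  glob <- rbind(
    data.frame(metric = "eglob",
               mean_case = mean(rep$metrics$case$eglob),
               sd_case = sd(rep$metrics$case$eglob),
               mean_control = mean(rep$metrics$control$eglob),
               sd_control = sd(rep$metrics$control$eglob),
               p = rep$eglob_test$p_emp, stringsAsFactors = FALSE),
    rep$global)
  emit(glob, "global_metrics.tsv")

  lobes <- bundle$node_table
  sig_rows <- do.call(rbind, lapply(names(rep$nodal), function(m) {
    tab <- rep$nodal[[m]]
    tab <- tab[tab$significant, , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    data.frame(characteristic = m, region = tab$node,
               lobe = lobes$lobe[match(tab$node, lobes$name)],
               direction = ifelse(tab$direction == "increased", 1L, -1L),
               t = tab$t_obs, stringsAsFactors = FALSE)
  }))
  if (is.null(sig_rows)) {
    sig_rows <- data.frame(characteristic = character(), region = character(),
                           lobe = character(), direction = integer(),
                           t = numeric())
  }
  emit(sig_rows, "nodal_significant.tsv")

  if (!is.null(bundle$behavior)) {
    emit(bundle$behavior$correlations, "correlations.tsv")
    if (!is.null(bundle$behavior$z_tests) && nrow(bundle$behavior$z_tests)) {
      emit(bundle$behavior$z_tests, "z_difference_tests.tsv")
    }
  }

  results <- list(
    sparsity_used = bundle$sparsity_used,
    selection = bundle$selection[c("selected_s", "min_s",
                                   "selected_s_rounded", "min_s_rounded")],
    eglob = list(t = rep$eglob_test$t_obs,
                 significant = rep$eglob_test$significant,
                 p_emp = rep$eglob_test$p_emp),
    n_significant_nodes = vapply(rep$nodal, function(t) sum(t$significant),
                                 integer(1)))
  jsonlite::write_json(results, file.path(dir, "results.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths[[length(paths) + 1L]] <- file.path(dir, "results.json")
  invisible(unlist(paths))
}
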