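#' Packaged 112-region node table
#'
#' An AAL-derived set of 112 regions of interest: the 90 cerebral AAL regions
#' plus 18 cerebellar hemispheric lobules and 4 vermis regions, each labeled
#' with one of six lobes (frontal, limbic, parietal, temporal, occipital,
#' cerebellum) and a hemisphere (L/R, or M for midline vermis). This is a
#' reconstruction of a typical AAL-based 112-node parcellation, shipped so
#' the pipeline and the cohort generator share realistic region labels.
#'
#' @return Data frame with columns `name`, `lobe`, `hemisphere`.
#' @export
default_node_table <- function() {
  path <- system.file("extdata", "aal112_nodes.tsv", package = "fcgraph")
  read_node_table(path)
}

#' Read a node table
#'
#' @param path Tab-delimited file with columns `name`, `lobe`, `hemisphere`.
#' @return Data frame with those columns.
#' @export
read_node_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "lobe", "hemisphere")
  if (!all(need %in% names(tab)))
    stop("node table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$name)) stop("duplicate node names in node table")
  tab
}

#' Write per-subject time series as delimited text
#'
#' One file per subject (`<subject_id>.tsv`), one row per timepoint, one
#' column per node, header = node names.
#'
#' @param timeseries List of [roi_timeseries()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_timeseries_dir <- function(timeseries, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(timeseries, function(ts) {
    path <- file.path(dir, paste0(ts$subject_id, ".tsv"))
    write.table(ts$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read per-subject time series
#'
#' Reads every `.tsv` file in a directory as one subject's T x N series,
#' validates against the node table (all nodes present, no extras, no
#' missing values, no constant columns), reorders columns to node-table
#' order, and returns subjects sorted by id.
#'
#' @param dir Directory of `<subject_id>.tsv` files.
#' @param node_table Node table (see [read_node_table()]).
#' @return List of [roi_timeseries()] objects sorted by subject id.
#' @export
read_timeseries_dir <- function(dir, node_table) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) stop("no .tsv time-series files in ", dir)
  lapply(files, function(f) {
    id <- sub("\\.tsv$", "", basename(f))
    dat <- as.matrix(read.delim(f, check.names = FALSE))
    missing <- setdiff(node_table$name, colnames(dat))
    if (length(missing))
      stop(f, ": missing node column(s): ", paste(missing, collapse = ", "))
    extra <- setdiff(colnames(dat), node_table$name)
    if (length(extra))
      stop(f, ": unknown node column(s): ", paste(extra, collapse = ", "))
    dat <- dat[, node_table$name, drop = FALSE]
    if (anyNA(dat)) stop(f, ": missing values in time series")
    sds <- apply(dat, 2, sd)
    if (any(sds == 0))
      stop(f, ": constant column(s): ",
           paste(colnames(dat)[sds == 0], collapse = ", "))
    roi_timeseries(id, dat)
  })
}

#' Write the subject table
#'
#' @param subjects Subject data frame.
#' @param path Output path (tab-delimited).
#' @export
write_subject_table <- function(subjects, path) {
  write.table(subjects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate the subject table
#'
#' Requires columns `subject_id`, `group`, `age`, `sex`; any additional
#' numeric columns are retained as clinical/cognitive scores (missing cells
#' allowed). Duplicate ids and unknown group labels are errors.
#'
#' @param path Tab-delimited subject table.
#' @param group_levels Allowed group labels (first = case group).
#' @return Data frame sorted by `subject_id`.
#' @export
read_subject_table <- function(path, group_levels = c("case", "control")) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  if (!all(need %in% names(tab)))
    stop("subject table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject id(s): ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  bad <- setdiff(unique(tab$group), group_levels)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (!all(tab$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  tab[order(tab$subject_id), , drop = FALSE]
}

#' Write a matrix with node-name headers
#'
#' @param mat Square matrix with dimnames.
#' @param path Output path (tab-delimited, node names as header row and
#'   first column).
#' @export
write_matrix_tsv <- function(mat, path) {
  m <- as_plain_matrix(mat)
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$node
  m
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with defaults reproducing the
#' reference study design: sparsity selection by the connectedness rule with
#' a fallback 8-26% grid in 1% steps (19 levels), 10,000 permutations,
#' residualize-then-rectify edge processing, neighborhood-subgraph local
#' efficiency, rank-sum node-averaged comparisons, MAD multiplier 2.5 and
#' FDR threshold 0.05. Round-trips losslessly through YAML.
#'
#' @param timeseries_dir Directory of per-subject time-series tables.
#' @param subject_table Path to the subject table.
#' @param output_dir Output directory for intermediates and reports.
#' @param node_table Path to a node table, or `NULL` for the packaged
#'   112-region table.
#' @param sparsity_mode `"auto_select"`, `"fixed"`, or `"range"`.
#' @param sparsity Fixed sparsity (required for `"fixed"`).
#' @param grid_min,grid_max,grid_step Sparsity grid for `"range"` mode.
#' @param n_perm Number of permutations for every permutation test.
#' @param seed Master seed; all randomness derives from it.
#' @param residualize_first Residualize edges before rectifying negatives
#'   (default) or after.
#' @param eloc_variant `"subgraph"` or `"cuberoot"`.
#' @param global_test `"ranksum"` or `"ttest"` for node-averaged metrics.
#' @param n_mads MAD multiplier for outlier screening.
#' @param fdr_q FDR threshold for the behavior analysis.
#' @param scores Score columns analyzed in the behavior stage (default: the
#'   16 cognitive subtests).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(timeseries_dir, subject_table, output_dir,
                            node_table = NULL,
                            sparsity_mode = c("auto_select", "fixed",
                                              "range"),
                            sparsity = NULL,
                            grid_min = 0.08, grid_max = 0.26,
                            grid_step = 0.01,
                            n_perm = 10000L, seed = 1L,
                            residualize_first = TRUE,
                            eloc_variant = "subgraph",
                            global_test = "ranksum",
                            n_mads = 2.5, fdr_q = 0.05,
                            scores = cnt_subtest_names()) {
  sparsity_mode <- match.arg(sparsity_mode)
  if (sparsity_mode == "fixed" && is.null(sparsity))
    stop("fixed sparsity mode needs a sparsity value")
  cfg <- list(timeseries_dir = timeseries_dir,
              subject_table = subject_table, output_dir = output_dir,
              node_table = node_table, sparsity_mode = sparsity_mode,
              sparsity = sparsity, grid_min = grid_min, grid_max = grid_max,
              grid_step = grid_step, n_perm = as.integer(n_perm),
              seed = as.integer(seed),
              residualize_first = residualize_first,
              eloc_variant = eloc_variant, global_test = global_test,
              n_mads = n_mads, fdr_q = fdr_q, scores = scores)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config` returns the `pipeline_config`;
#'   `write_pipeline_config` returns the path invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

sparsity_grid <- function(config) {
  seq(config$grid_min, config$grid_max, by = config$grid_step)
}
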