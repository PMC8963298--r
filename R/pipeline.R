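# End-to-end orchestration: normalization (when configured), raw
# summaries, filtering, filtered summaries, batch effects, power grids,
# output tables, HTML report and per-feature document.

summarize_with_pca <- function(matrix, annotation, config) {
  clustering <- NULL
  pca <- NULL
  n_accel <- NULL
  n_parallel <- NULL
  ids <- tryCatch(eligible_features(matrix, annotation, config),
                  error = function(e) NULL)
  if (!is.null(ids)) {
    clustering <- cluster_features(matrix, ids, config$tree_cut_height)
    work <- matrix[, clustering$representatives, drop = FALSE]
    if (config$pca_outlier_mode != "leave") {
      fl <- outlier_flags(work, config$outlier_iqr_multiplier)$flags
      work <- handle_outlier_values(work, fl, config$pca_outlier_mode)
    }
    xs <- suppressWarnings(impute_standardize(work))
    if (ncol(xs) >= 2 && nrow(xs) >= 3) {
      pca <- run_pca(xs)
      n_accel <- if (length(pca$eigenvalues) >= 3)
        acceleration_factor_n(pca$eigenvalues, config$pc_min_components)
      else config$pc_min_components
      n_accel <- min(n_accel, ncol(pca$scores))
      n_parallel <- parallel_analysis_n(pca$eigenvalues, nrow(xs), ncol(xs),
                                        seed = config$rng_seed)
    }
  }
  ss <- sample_summary(matrix, annotation, config, pca)
  fs <- feature_summary(matrix, annotation, clustering, config)
  list(sample_summary = ss, feature_summary = fs, clustering = clustering,
       pca = pca, n_accel = n_accel, n_parallel = n_parallel)
}

#' Run the full pre-analysis pipeline
#'
#' Performs the six main actions in order: (i) ingest the data, (ii)
#' median batch normalization when a batch column is configured, (iii)
#' summary statistics on the (normalized) raw data, (iv) the ordered
#' sample/feature filter pipeline, (v) summary statistics on the filtered
#' data and (vi) output tables, the HTML report and the per-feature plot
#' document.
#'
#' @param matrix samples x features abundance matrix, or a path to a
#'   delimited text file readable by [read_matrix()].
#' @param meta sample metadata data.frame (or path), optional.
#' @param annotation feature annotation data.frame (or path), optional.
#' @param config a `metab_config` (see [default_config()], [read_config()]).
#' @param outdir output directory; NULL skips all file output.
#' @param report,feature_doc toggles for the HTML report and the
#'   per-feature PDF (only used when `outdir` is set).
#' @return invisible list with the raw and filtered matrices and
#'   summaries, the clustering/PCA objects, component-retention estimates,
#'   PC outlier ids, exclusion log, batch-effect table, power grid, the
#'   configuration, and the paths of any files written.
#' @export
run_pipeline <- function(matrix, meta = NULL, annotation = NULL,
                         config = default_config(), outdir = NULL,
                         report = TRUE, feature_doc = TRUE) {
  if (is.character(matrix)) matrix <- read_matrix(matrix)
  if (is.character(meta)) meta <- read_sample_metadata(meta)
  if (is.character(annotation)) annotation <- read_feature_annotation(annotation)
  if (!inherits(config, "metab_config")) config <- validate_config(config)
  validate_abundance(matrix)

  normalized <- FALSE
  if (!is.na(config$batch_normalization_column)) {
    if (is.null(meta))
      stop("batch normalization requested but no sample metadata given")
    matrix <- median_batch_normalize(matrix, meta,
                                     config$batch_normalization_column)
    normalized <- TRUE
  }

  raw <- summarize_with_pca(matrix, annotation, config)
  filt <- apply_filter_pipeline(matrix, annotation, config)
  post <- summarize_with_pca(filt$matrix, annotation, config)

  pc_outlier_ids <- character()
  if (!is.null(filt$pca) && !is.null(filt$n_components))
    pc_outlier_ids <- pc_outliers(filt$pca$scores, filt$n_components,
                                  config$pc_sd_threshold)

  batch <- NULL
  if (!is.null(meta)) {
    vars <- setdiff(names(meta), "sample_id")
    vars <- vars[vapply(vars, function(v) !is.numeric(meta[[v]]),
                        logical(1))]
    if (length(vars))
      batch <- suppressWarnings(
        batch_effects(raw$sample_summary, meta, vars))
  }

  power_grid <- power_grid_for_missingness(
    nrow(filt$matrix), post$feature_summary$missingness)

  results <- list(
    raw_matrix = matrix, filtered_matrix = filt$matrix,
    raw_sample_summary = raw$sample_summary,
    raw_feature_summary = raw$feature_summary,
    filtered_sample_summary = post$sample_summary,
    filtered_feature_summary = post$feature_summary,
    clustering = post$clustering, pca = post$pca,
    n_accel = post$n_accel, n_parallel = post$n_parallel,
    raw_clustering = raw$clustering, raw_pca = raw$pca,
    pc_outlier_ids = pc_outlier_ids,
    exclusion_log = filt$log, batch_effects = batch,
    power_grid = power_grid, meta = meta, annotation = annotation,
    config = config, normalized = normalized, files = NULL)

  if (!is.null(outdir)) {
    files <- write_tables(outdir, matrix, filt$matrix,
                          raw$sample_summary, raw$feature_summary,
                          post$sample_summary, post$feature_summary,
                          filt$log)
    if (isTRUE(report)) {
      rp <- file.path(outdir, "report.html")
      render_report(results, rp)
      files <- c(files, report = rp)
    }
    if (isTRUE(feature_doc)) {
      fd <- file.path(outdir, "feature_plots.pdf")
      render_feature_document(filt$matrix, post$feature_summary, fd,
                              config$outlier_iqr_multiplier)
      files <- c(files, feature_doc = fd)
    }
    log_path <- file.path(outdir, "run_log.txt")
    writeLines(c("metabscreen run log",
                 sprintf("project: %s", config$project_name),
                 sprintf("input: %d samples x %d features",
                         nrow(matrix), ncol(matrix)),
                 sprintf("batch normalization: %s",
                         if (normalized) config$batch_normalization_column
                         else "none"),
                 utils::capture.output(print(
                   filt$log[, c("step", "name", "entity", "threshold",
                                "n_before", "n_removed", "n_after")],
                   row.names = FALSE)),
                 sprintf("output: %d samples x %d features",
                         nrow(filt$matrix), ncol(filt$matrix))),
               log_path)
    files <- c(files, run_log = log_path)
    results$files <- files
  }
  invisible(results)
}
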