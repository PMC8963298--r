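# The ordered sample/feature exclusion pipeline. Missingness exclusions
# are made at >= threshold; TSA and PC exclusions at strictly > threshold
# SD from the mean. Missingness thresholds of 0 are documented
# no-exclusion settings (the corresponding steps are disabled).

new_log <- function() {
  data.frame(step = integer(), name = character(), entity = character(),
             threshold = character(), n_before = integer(),
             n_removed = integer(), n_after = integer(),
             removed_ids = character(), stringsAsFactors = FALSE)
}

log_step <- function(log, step, name, entity, threshold, before, removed) {
  rbind(log, data.frame(
    step = step, name = name, entity = entity, threshold = threshold,
    n_before = length(before), n_removed = length(removed),
    n_after = length(before) - length(removed),
    removed_ids = paste(removed, collapse = ";"),
    stringsAsFactors = FALSE))
}

#' Apply the ordered sample and feature exclusion pipeline
#'
#' Executes, in order, recording each step in the exclusion log:
#' \enumerate{
#'   \item samples with extreme missingness (>= 80%) removed; sample
#'     missingness always excludes xenobiotics and, when configured,
#'     derived measures;
#'   \item features with extreme missingness (>= 80%) removed —
#'     xenobiotics are exempt at any missingness;
#'   \item missingness recomputed; samples at or above
#'     `sample_missingness_max` removed (0 disables);
#'   \item features at or above `feature_missingness_max` removed
#'     (xenobiotics exempt; 0 disables);
#'   \item total sum abundance over complete features computed on the
#'     surviving matrix; samples more than `tsa_sd_threshold` SD from the
#'     mean removed;
#'   \item feature clustering and PCA rerun on the survivors (honouring
#'     `pca_outlier_mode`); samples more than `pc_sd_threshold` SD from
#'     the mean on the top n PCs removed, n given by the acceleration
#'     factor with a floor of 2.
#' }
#' The filtered matrix keeps the original value scale: the imputation,
#' NA-conversion or winsorization used inside the PCA step is never
#' persisted.
#'
#' @param matrix samples x features abundance matrix.
#' @param annotation feature annotation data.frame (or NULL: no flags).
#' @param config a `metab_config`. If `batch_normalization_column` is in
#'   use, normalization is expected to have been applied already.
#' @return list of class `metab_filter` with `matrix` (filtered), `log`
#'   (the exclusion-log data.frame), `clustering`, `pca` and
#'   `n_components` from step 6 (NULL when the step could not run).
#' @export
apply_filter_pipeline <- function(matrix, annotation = NULL,
                                  config = default_config()) {
  validate_abundance(matrix)
  if (!inherits(config, "metab_config")) config <- validate_config(config)
  ann <- annotation
  is_xeno <- function(ids) {
    if (is.null(ann)) return(rep(FALSE, length(ids)))
    ann$is_xenobiotic[match(ids, ann$feature_id)] %in% TRUE
  }
  log <- new_log()
  m <- matrix
  check_nonempty <- function(m, step_name) {
    if (nrow(m) == 0 || ncol(m) == 0)
      stop("no data remain after step: ", step_name)
    m
  }
  excl_now <- function(m) intersect(excluded_feature_set(ann, config),
                                    colnames(m))

  # 1. extreme sample missingness
  sm <- sample_missingness(m, excl_now(m))
  rm1 <- names(sm)[sm >= config$extreme_missingness]
  log <- log_step(log, 1L, "extreme sample missingness", "sample",
                  sprintf(">=%g", config$extreme_missingness),
                  rownames(m), rm1)
  m <- check_nonempty(m[!rownames(m) %in% rm1, , drop = FALSE],
                      "extreme sample missingness")

  # 2. extreme feature missingness (xenobiotics exempt)
  fm <- feature_missingness(m)
  rm2 <- names(fm)[fm >= config$extreme_missingness & !is_xeno(names(fm))]
  log <- log_step(log, 2L, "extreme feature missingness", "feature",
                  sprintf(">=%g", config$extreme_missingness),
                  colnames(m), rm2)
  m <- check_nonempty(m[, !colnames(m) %in% rm2, drop = FALSE],
                      "extreme feature missingness")

  # 3. user-threshold sample missingness
  rm3 <- character()
  if (config$sample_missingness_max > 0) {
    sm <- sample_missingness(m, excl_now(m))
    rm3 <- names(sm)[sm >= config$sample_missingness_max]
  }
  log <- log_step(log, 3L, "sample missingness", "sample",
                  if (config$sample_missingness_max > 0)
                    sprintf(">=%g", config$sample_missingness_max)
                  else "disabled",
                  rownames(m), rm3)
  m <- check_nonempty(m[!rownames(m) %in% rm3, , drop = FALSE],
                      "sample missingness")

  # 4. user-threshold feature missingness (xenobiotics exempt)
  rm4 <- character()
  if (config$feature_missingness_max > 0) {
    fm <- feature_missingness(m)
    rm4 <- names(fm)[fm >= config$feature_missingness_max &
                       !is_xeno(names(fm))]
  }
  log <- log_step(log, 4L, "feature missingness", "feature",
                  if (config$feature_missingness_max > 0)
                    sprintf(">=%g", config$feature_missingness_max)
                  else "disabled",
                  colnames(m), rm4)
  m <- check_nonempty(m[, !colnames(m) %in% rm4, drop = FALSE],
                      "feature missingness")

  # 5. TSA on complete features
  rm5 <- character()
  tsa <- suppressWarnings(
    total_sum_abundance(m, complete_only = TRUE,
                        excluded_features = excl_now(m)))
  if (!all(is.na(tsa))) {
    mu <- mean(tsa, na.rm = TRUE)
    s <- stats::sd(tsa, na.rm = TRUE)
    if (!is.na(s) && s > 0)
      rm5 <- names(tsa)[!is.na(tsa) &
                          abs(tsa - mu) > config$tsa_sd_threshold * s]
  } else {
    warning("no complete features; TSA exclusion step made no exclusions")
  }
  log <- log_step(log, 5L, "sample TSA (complete features)", "sample",
                  sprintf(">%gSD", config$tsa_sd_threshold),
                  rownames(m), rm5)
  m <- check_nonempty(m[!rownames(m) %in% rm5, , drop = FALSE],
                      "sample TSA")

  # 6. PC outliers on representative features
  rm6 <- character()
  clustering <- NULL
  pca <- NULL
  n_comp <- NULL
  ids <- tryCatch(eligible_features(m, ann, config), error = function(e) {
    warning("PCA outlier step skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(ids)) {
    clustering <- cluster_features(m, ids, config$tree_cut_height)
    reps <- clustering$representatives
    work <- m[, reps, drop = FALSE]
    if (config$pca_outlier_mode != "leave" && length(reps) >= 1) {
      fl <- outlier_flags(work, config$outlier_iqr_multiplier)$flags
      work <- handle_outlier_values(work, fl, config$pca_outlier_mode)
    }
    xs <- suppressWarnings(impute_standardize(work))
    if (ncol(xs) >= 2 && nrow(xs) >= 3) {
      pca <- run_pca(xs)
      n_comp <- if (length(pca$eigenvalues) >= 3)
        acceleration_factor_n(pca$eigenvalues, config$pc_min_components)
      else config$pc_min_components
      n_comp <- min(n_comp, ncol(pca$scores))
      rm6 <- pc_outliers(pca$scores, n_comp, config$pc_sd_threshold)
    } else {
      warning("PCA outlier step skipped: too few usable features")
    }
  }
  log <- log_step(log, 6L, "PCA outliers", "sample",
                  sprintf(">%gSD", config$pc_sd_threshold),
                  rownames(m), rm6)
  m <- check_nonempty(m[!rownames(m) %in% rm6, , drop = FALSE],
                      "PCA outliers")

  structure(list(matrix = m, log = log, clustering = clustering,
                 pca = pca, n_components = n_comp),
            class = "metab_filter")
}

#' @export
print.metab_filter <- function(x, ...) {
  cat("filter pipeline result:", nrow(x$matrix), "samples x",
      ncol(x$matrix), "features retained\n")
  print(x$log[, c("step", "name", "entity", "threshold",
                  "n_before", "n_removed", "n_after")], row.names = FALSE)
  invisible(x)
}
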