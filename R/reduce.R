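# Correlation-based data reduction and PCA sample-outlier detection.
# Features are clustered on a 1 - |Spearman rho| distance (complete
# linkage); one least-missing representative per cluster yields a set of
# approximately independent signals — the "effective number" of features —
# on which sample PCs are computed.

#' Features eligible for clustering and PCA
#'
#' Restricts to common, variable features: xenobiotics are always dropped,
#' derived measures when `config$exclude_derived` is set, features with
#' more than 20% missingness, and features without variance among observed
#' values.
#'
#' @param matrix samples x features abundance matrix.
#' @param annotation feature annotation data.frame (or NULL).
#' @param config a `metab_config`.
#' @return character vector of eligible feature ids (>= 2, else an error).
#' @export
eligible_features <- function(matrix, annotation = NULL,
                              config = default_config()) {
  validate_abundance(matrix)
  ids <- colnames(matrix)
  if (!is.null(annotation)) {
    ann <- annotation[match(ids, annotation$feature_id), ]
    drop <- ann$is_xenobiotic %in% TRUE
    if (isTRUE(config$exclude_derived)) drop <- drop | ann$is_derived %in% TRUE
    ids <- ids[!drop]
  }
  miss <- feature_missingness(matrix[, ids, drop = FALSE])
  ids <- ids[miss <= 0.2]
  if (length(ids)) {
    sds <- apply(matrix[, ids, drop = FALSE], 2, stats::sd, na.rm = TRUE)
    ids <- ids[!is.na(sds) & sds > 0]
  }
  if (length(ids) < 2)
    stop("fewer than 2 features eligible for clustering/PCA")
  ids
}

#' Cluster features on Spearman-correlation distance
#'
#' Pairwise Spearman's rho is computed on pairwise-complete observations
#' and converted to the distance 1 - |rho|; complete-linkage agglomeration
#' followed by a static tree cut at `cut_height` defines the clusters.
#' Pairs sharing fewer than 3 observations get distance 1 with a warning.
#' Within each cluster the feature with the least missingness is tagged as
#' representative (ties broken by input column order).
#'
#' @param matrix samples x features abundance matrix.
#' @param ids feature ids to cluster (>= 2), e.g. from
#'   [eligible_features()].
#' @param cut_height tree cut height in 1 - |rho| units, in (0, 1].
#' @return object of class `feature_clustering`: list with `ids`,
#'   `distance` (full symmetric matrix), `hclust`, `clusters` (integer
#'   assignment per feature), `k` (cluster count, the effective number of
#'   features) and `representatives` (one id per cluster, cluster order).
#' @export
cluster_features <- function(matrix, ids, cut_height = 0.5) {
  validate_abundance(matrix)
  stopifnot(length(ids) >= 2, all(ids %in% colnames(matrix)),
            cut_height > 0, cut_height <= 1)
  x <- matrix[, ids, drop = FALSE]
  rho <- suppressWarnings(
    stats::cor(x, method = "spearman", use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(x))
  few <- shared < 3
  diag(few) <- FALSE
  if (any(few)) {
    warning(sum(few) / 2, " feature pair(s) share < 3 observations; ",
            "distance set to 1")
    rho[few] <- 0
  }
  rho[is.na(rho)] <- 0              # undefined correlation -> max distance
  d <- 1 - abs(rho)
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  cl <- stats::cutree(hc, h = cut_height)
  miss <- feature_missingness(x)
  k <- max(cl)
  reps <- character(k)
  for (g in seq_len(k)) {
    members <- which(cl == g)               # in input column order
    reps[g] <- ids[members[which.min(miss[members])]]
  }
  structure(list(ids = ids, distance = d, hclust = hc, clusters = cl,
                 k = k, representatives = reps),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat("feature clustering:", length(x$ids), "features in", x$k,
      "clusters (effective number of features)\n")
  invisible(x)
}

#' Median-impute and z-standardize a feature subset
#'
#' Strictly for deriving PCs: missing values are imputed to the feature
#' median of observed values, then each feature is z-transformed (mean 0,
#' SD 1, n-1 denominator). Features that end up constant are dropped with a
#' warning.
#'
#' @param matrix samples x features abundance matrix.
#' @param ids feature ids to use.
#' @return complete numeric matrix (samples x retained features).
#' @export
impute_standardize <- function(matrix, ids = colnames(matrix)) {
  validate_abundance(matrix)
  stopifnot(all(ids %in% colnames(matrix)))
  x <- matrix[, ids, drop = FALSE]
  drop <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    obs <- x[, j][!is.na(x[, j])]
    if (!length(obs)) { drop[j] <- TRUE; next }
    x[is.na(x[, j]), j] <- stats::median(obs)
    if (stats::sd(x[, j]) == 0) drop[j] <- TRUE
  }
  if (any(drop)) {
    warning("dropping ", sum(drop), " all-missing or constant feature(s): ",
            paste(ids[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  scale(x)[, , drop = FALSE]
}

#' Principal component analysis of a standardized matrix
#'
#' Components of the covariance of the (already standardized) input.
#' Component signs are fixed so each component's largest-magnitude loading
#' is positive, making scores byte-reproducible.
#'
#' @param x complete numeric matrix, samples x features (>= 2 of each).
#' @return object of class `metab_pca`: list with `scores`, `rotation`,
#'   `eigenvalues` (component variances) and `variance_explained`
#'   (fractions, non-increasing).
#' @export
run_pca <- function(x) {
  if (anyNA(x)) stop("PCA input must be complete; impute first")
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("PCA needs at least 2 samples and 2 features")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  eig <- p$sdev^2
  if (length(eig) < 2) stop("fewer than 2 components available")
  structure(list(scores = p$x, rotation = p$rotation, eigenvalues = eig,
                 variance_explained = eig / sum(eig)),
            class = "metab_pca")
}

#' @export
print.metab_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", length(x$eigenvalues),
      "components; PC1", sprintf("%.1f%%", 100 * x$variance_explained[1]),
      "of variance\n")
  invisible(x)
}

#' Number of components by the acceleration factor
#'
#' Scree-based retention: the acceleration factor is the second difference
#' of the eigenvalue sequence, a_i = e_{i+1} - 2 e_i + e_{i-1}; the number
#' retained is one less than the position of its maximum (earliest position
#' on ties), floored at `min_components`.
#'
#' @param eigenvalues non-increasing positive eigenvalues (>= 3).
#' @param min_components floor on the retained count (default 2).
#' @return integer count of retained components.
#' @export
acceleration_factor_n <- function(eigenvalues, min_components = 2L) {
  e <- as.numeric(eigenvalues)
  p <- length(e)
  if (p < 3) stop("acceleration factor needs >= 3 eigenvalues")
  a <- e[3:p] - 2 * e[2:(p - 1)] + e[1:(p - 2)]   # a[i - 1] is a_i, i = 2..p-1
  i_star <- which.max(a) + 1L                      # earliest max
  max(as.integer(min_components), i_star - 1L)
}

#' Number of components by parallel analysis
#'
#' Compares observed eigenvalues with those of simulated uncorrelated data
#' of the same shape: `reps` standard normal matrices are drawn, column
#' standardized, and their eigenvalue distributions summarized at the 95th
#' percentile; the retained count is the number of observed eigenvalues
#' exceeding their null percentile.
#'
#' @param eigenvalues observed eigenvalues (variances of the standardized
#'   data's components).
#' @param n_samples,n_features dimensions of the observed data.
#' @param reps number of null replicates (>= 10; default 100).
#' @param seed integer seed; identical seeds give identical results.
#' @param centile null percentile used (default 0.95).
#' @return integer count of retained components.
#' @export
parallel_analysis_n <- function(eigenvalues, n_samples, n_features,
                                reps = 100L, seed = 2022L, centile = 0.95) {
  stopifnot(reps >= 10, n_samples >= 3, n_features >= 2)
  ncomp <- min(n_samples - 1, n_features)
  null_eig <- with_seed(seed, {
    t(vapply(seq_len(reps), function(r) {
      m <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features)
      ev <- stats::prcomp(scale(m), center = FALSE, scale. = FALSE)$sdev^2
      ev[seq_len(ncomp)]
    }, numeric(ncomp)))
  })
  q95 <- apply(null_eig, 2, stats::quantile, probs = centile, type = 7)
  e <- as.numeric(eigenvalues)
  n_use <- min(length(e), ncomp)
  sum(e[seq_len(n_use)] > q95[seq_len(n_use)])
}

#' Identify PC-outlier samples
#'
#' A sample is flagged when, on any of the top `n_components` components,
#' its score lies more than `sd_threshold` standard deviations from that
#' component's mean.
#'
#' @param scores samples x components score matrix (rownames = sample ids).
#' @param n_components number of leading components examined.
#' @param sd_threshold positive threshold in SD units (default 5).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
pc_outliers <- function(scores, n_components, sd_threshold = 5) {
  stopifnot(n_components >= 1, n_components <= ncol(scores),
            sd_threshold > 0)
  sub <- scores[, seq_len(n_components), drop = FALSE]
  mu <- colMeans(sub)
  sds <- apply(sub, 2, stats::sd)
  flag <- abs(sweep(sub, 2, mu, "-")) > sweep(
    array(1, dim(sub)), 2, sd_threshold * sds, "*")
  rownames(scores)[rowSums(flag, na.rm = TRUE) > 0]
}

#' Treat flagged outlier values for the PCA working copy
#'
#' Applies the configured treatment of extreme values before PC
#' derivation: `"to_na"` turns flagged cells into missing values (later
#' median-imputed), `"winsorize"` replaces each flagged cell with the most
#' extreme non-flagged observed value of that feature on the same side of
#' the median, and `"leave"` is the identity. This only ever affects the
#' internal PCA copy; exported data are never modified.
#'
#' @param matrix samples x features abundance matrix.
#' @param flags logical flag matrix from [outlier_flags()] (same shape).
#' @param mode one of `"leave"`, `"to_na"`, `"winsorize"`.
#' @return treated copy of `matrix`.
#' @export
handle_outlier_values <- function(matrix, flags,
                                  mode = c("leave", "to_na", "winsorize")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(matrix), dim(flags)))
  if (mode == "leave" || !any(flags)) return(matrix)
  out <- matrix
  if (mode == "to_na") {
    out[flags] <- NA_real_
    return(out)
  }
  for (j in which(colSums(flags) > 0)) {
    v <- matrix[, j]
    fl <- flags[, j]
    keep <- v[!fl & !is.na(v)]
    if (!length(keep)) next      # everything flagged: leave untouched
    med <- stats::median(v[!is.na(v)])
    hi <- fl & !is.na(v) & v > med
    lo <- fl & !is.na(v) & v < med
    out[hi, j] <- max(keep)
    out[lo, j] <- min(keep)
  }
  out
}
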