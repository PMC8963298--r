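# Per-sample and per-feature quality statistics computed on a given
# abundance matrix. All quantile computations use linear interpolation
# between order statistics (R's default type 7).

#' Per-sample missingness
#'
#' Fraction of missing entries per sample, computed over features not in
#' `excluded_features`. Xenobiotics (and, optionally, derived measures) are
#' typically excluded here because their missingness carries biological
#' rather than technical meaning.
#'
#' @param matrix samples x features abundance matrix.
#' @param excluded_features feature ids to leave out of the calculation.
#' @return named numeric vector of fractions in \[0,1\], one per sample.
#' @export
sample_missingness <- function(matrix, excluded_features = character()) {
  validate_abundance(matrix)
  bad <- setdiff(excluded_features, colnames(matrix))
  if (length(bad)) stop("excluded features not in matrix: ",
                        paste(bad, collapse = ", "))
  keep <- setdiff(colnames(matrix), excluded_features)
  if (!length(keep)) stop("all features excluded from sample missingness")
  rowMeans(is.na(matrix[, keep, drop = FALSE]))
}

#' Per-feature missingness
#'
#' @param matrix samples x features abundance matrix.
#' @return named numeric vector of fractions in \[0,1\], one per feature.
#' @export
feature_missingness <- function(matrix) {
  validate_abundance(matrix)
  if (nrow(matrix) < 1) stop("matrix has no samples")
  colMeans(is.na(matrix))
}

#' Total sum abundance (TSA) per sample
#'
#' Each retained feature is z-transformed (mean 0, SD 1 over its observed
#' entries) and the whole standardized matrix is shifted upward by the
#' absolute value of its global minimum, so all entries are non-negative.
#' TSA is the per-sample sum of these shifted values — a proxy for the
#' total measured metabolite content (total peak area in MS parlance).
#' With `complete_only = TRUE` only features without any missing entry
#' contribute, which is the variant used for sample exclusion because the
#' all-feature variant is by construction correlated with missingness.
#'
#' @param matrix samples x features abundance matrix (>= 2 samples).
#' @param complete_only use only features with zero missingness.
#' @param excluded_features feature ids removed before any calculation.
#' @return named numeric vector, one TSA value per sample. All-missing
#'   degenerate cases yield NA with a warning.
#' @export
total_sum_abundance <- function(matrix, complete_only = FALSE,
                                excluded_features = character()) {
  validate_abundance(matrix)
  if (nrow(matrix) < 2) stop("TSA needs at least 2 samples")
  keep <- setdiff(colnames(matrix), excluded_features)
  x <- matrix[, keep, drop = FALSE]
  if (complete_only) {
    complete <- colSums(is.na(x)) == 0
    if (!any(complete)) {
      warning("no complete features; TSA (complete) is NA")
      return(stats::setNames(rep(NA_real_, nrow(matrix)), rownames(matrix)))
    }
    x <- x[, complete, drop = FALSE]
  }
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  degenerate <- is.na(sds) | sds == 0
  if (any(degenerate)) {
    warning("dropping ", sum(degenerate),
            " zero-variance feature(s) from TSA: ",
            paste(colnames(x)[degenerate], collapse = ", "))
    x <- x[, !degenerate, drop = FALSE]
  }
  if (!ncol(x)) {
    warning("no usable features; TSA is NA")
    return(stats::setNames(rep(NA_real_, nrow(matrix)), rownames(matrix)))
  }
  z <- scale(x)                      # per-feature z-transform, NA preserved
  z <- z + abs(min(z, na.rm = TRUE)) # recentre to the global minimum
  tsa <- rowSums(z, na.rm = TRUE)
  tsa[rowSums(!is.na(z)) == 0] <- NA_real_
  stats::setNames(as.numeric(tsa), rownames(matrix))
}

#' Flag extreme values by the IQR rule
#'
#' A cell is flagged when it lies more than `k` interquartile-range units
#' from its feature's median (median and IQR over observed entries,
#' linear-interpolation quantiles). Features with IQR = 0 produce no flags.
#' Missing entries are never flagged.
#'
#' @param matrix samples x features abundance matrix.
#' @param k positive IQR multiplier (default 5).
#' @return list with `flags` (logical samples x features matrix),
#'   `sample_counts` (row sums) and `feature_counts` (column sums).
#' @export
outlier_flags <- function(matrix, k = 5) {
  validate_abundance(matrix)
  stopifnot(is.numeric(k), k > 0)
  med <- apply(matrix, 2, stats::median, na.rm = TRUE)
  iqr <- apply(matrix, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    unname(diff(stats::quantile(v, c(0.25, 0.75), type = 7)))
  })
  dev <- abs(sweep(matrix, 2, med, "-"))
  lim <- k * iqr
  flags <- sweep(dev, 2, lim, ">")
  flags[is.na(flags)] <- FALSE     # missing cells and NA limits never flag
  list(flags = flags,
       sample_counts = rowSums(flags),
       feature_counts = colSums(flags))
}

# Adjusted Fisher-Pearson standardized third moment:
# G1 = g1 * sqrt(n (n-1)) / (n-2), g1 = m3 / m2^(3/2).
skewness_adj <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 3) return(NA_real_)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((v - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Per-feature descriptive statistics
#'
#' @param matrix samples x features abundance matrix.
#' @return data.frame with one row per feature: `feature_id`, `n`
#'   (observed count), `mean`, `sd` (n-1 denominator), `skew` (adjusted
#'   Fisher-Pearson), `cv` (sd/mean). Statistics needing more data than is
#'   present are NA.
#' @export
feature_descriptives <- function(matrix) {
  validate_abundance(matrix)
  one <- function(v) {
    obs <- v[!is.na(v)]
    n <- length(obs)
    mu <- if (n) mean(obs) else NA_real_
    s <- if (n >= 2) stats::sd(obs) else NA_real_
    c(n = n, mean = mu, sd = s,
      skew = skewness_adj(obs),
      cv = if (!is.na(s) && !is.na(mu) && mu != 0) s / mu else NA_real_)
  }
  stats <- t(apply(matrix, 2, one))
  data.frame(feature_id = colnames(matrix), stats,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shapiro-Wilk W on raw and log10 scales
#'
#' Computes Shapiro's W statistic on the observed values and again on
#' log10-transformed values, where non-positive entries are treated as
#' missing for the transformed variant (no pseudo-count is added). Above
#' 5000 observations a seeded random subsample of 5000 is used, mirroring
#' the sample-size restriction of the standard estimator.
#'
#' @param values numeric vector (missing entries allowed).
#' @param seed integer seed for the large-n subsample.
#' @return list with `w_raw`, `w_log10` and reason codes
#'   (`reason_raw`, `reason_log10`; NA when the statistic was computed).
#' @export
normality_w <- function(values, seed = 2022L) {
  sw <- function(v) {
    v <- v[!is.na(v) & is.finite(v)]
    if (length(v) < 4)
      return(list(w = NA_real_, reason = "insufficient n"))
    if (stats::sd(v) == 0)
      return(list(w = NA_real_, reason = "zero variance"))
    if (length(v) > 5000)
      v <- with_seed(seed, sample(v, 5000))
    w <- tryCatch(unname(stats::shapiro.test(v)$statistic),
                  error = function(e) NA_real_)
    list(w = w, reason = if (is.na(w)) "estimator failure" else NA_character_)
  }
  raw <- sw(values)
  lg <- sw(log10(values[!is.na(values) & values > 0]))
  list(w_raw = raw$w, w_log10 = lg$w,
       reason_raw = raw$reason, reason_log10 = lg$reason)
}

#' Assemble the per-sample summary table
#'
#' Combines missingness (with and without the excluded feature classes),
#' both TSA variants, the IQR outlier occurrence count and, when a PCA
#' result is supplied, the top 10 PC scores.
#'
#' @param matrix samples x features abundance matrix.
#' @param annotation feature annotation data.frame (or NULL).
#' @param config a `metab_config`.
#' @param pca optional result of [run_pca()] whose scores are appended.
#' @return data.frame, one row per sample.
#' @export
sample_summary <- function(matrix, annotation = NULL,
                           config = default_config(), pca = NULL) {
  excl <- excluded_feature_set(annotation, config)
  excl <- intersect(excl, colnames(matrix))
  miss_all <- sample_missingness(matrix)
  miss_excl <- if (length(excl) &&
                   length(setdiff(colnames(matrix), excl)) > 0)
    sample_missingness(matrix, excl) else miss_all
  tsa_all <- suppressWarnings(total_sum_abundance(matrix))
  tsa_complete <- suppressWarnings(
    total_sum_abundance(matrix, complete_only = TRUE,
                        excluded_features = excl))
  oc <- outlier_flags(matrix, config$outlier_iqr_multiplier)$sample_counts
  out <- data.frame(sample_id = rownames(matrix),
                    missingness_all = as.numeric(miss_all),
                    missingness_excl = as.numeric(miss_excl),
                    tsa_all = as.numeric(tsa_all),
                    tsa_complete = as.numeric(tsa_complete),
                    outlier_count = as.integer(oc),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(pca)) {
    k <- min(10, ncol(pca$scores))
    sc <- pca$scores[match(out$sample_id, rownames(pca$scores)),
                     seq_len(k), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(k))
    out <- cbind(out, as.data.frame(sc, row.names = NULL))
  }
  out
}

#' Assemble the per-feature summary table
#'
#' Descriptive statistics, missingness, Shapiro W on raw and log10 scales,
#' IQR outlier counts and the representative-feature indicator column
#' `independent_features_binary` (1 for the least-missing member of each
#' correlation cluster).
#'
#' @param matrix samples x features abundance matrix.
#' @param annotation feature annotation data.frame (or NULL).
#' @param clustering optional result of [cluster_features()].
#' @param config a `metab_config`.
#' @return data.frame, one row per feature.
#' @export
feature_summary <- function(matrix, annotation = NULL, clustering = NULL,
                            config = default_config()) {
  desc <- feature_descriptives(matrix)
  miss <- feature_missingness(matrix)
  oc <- outlier_flags(matrix, config$outlier_iqr_multiplier)$feature_counts
  w <- lapply(seq_len(ncol(matrix)), function(j)
    normality_w(matrix[, j], seed = config$rng_seed))
  reps <- if (!is.null(clustering)) clustering$representatives else character()
  data.frame(feature_id = desc$feature_id,
             missingness = as.numeric(miss),
             n = desc$n, mean = desc$mean, sd = desc$sd,
             skew = desc$skew, cv = desc$cv,
             w_raw = vapply(w, `[[`, numeric(1), "w_raw"),
             w_log10 = vapply(w, `[[`, numeric(1), "w_log10"),
             outlier_count = as.integer(oc),
             independent_features_binary =
               as.integer(desc$feature_id %in% reps),
             row.names = NULL, stringsAsFactors = FALSE)
}
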