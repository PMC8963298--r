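# Median batch normalization across platform batches (e.g. run days or MS
# batches). Scaling is multiplicative to the overall feature median so the
# abundance scale — and hence TSA — is preserved.

#' Median batch normalization
#'
#' For every feature and batch, values are multiplied by
#' (overall feature median) / (within-batch feature median), so after
#' normalization every batch's within-batch median equals the feature's
#' overall (pre-scaling) median. Batch-feature pairs whose batch median is
#' zero or undefined (no observed values) are left unscaled with a warning,
#' as are features whose overall median is zero. The missingness pattern is
#' never altered, and reapplying the normalization is a no-op up to
#' floating point.
#'
#' @param matrix samples x features abundance matrix.
#' @param meta sample metadata data.frame with a `sample_id` column.
#' @param batch_column name of the metadata column holding batch labels;
#'   every sample in `matrix` must have a non-missing label.
#' @return normalized abundance matrix with the same dimensions.
#' @export
median_batch_normalize <- function(matrix, meta, batch_column) {
  validate_abundance(matrix)
  if (!batch_column %in% names(meta))
    stop("batch column '", batch_column, "' not found in sample metadata")
  idx <- match(rownames(matrix), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(rownames(matrix)[is.na(idx)], collapse = ", "))
  extra <- setdiff(meta$sample_id, rownames(matrix))
  if (length(extra))
    warning(length(extra), " metadata row(s) have no matching sample")
  batch <- meta[[batch_column]][idx]
  if (anyNA(batch))
    stop("missing batch label for sample(s): ",
         paste(rownames(matrix)[is.na(batch)], collapse = ", "))
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(matrix)   # single batch: identity
  out <- matrix
  skipped <- 0L
  for (j in seq_len(ncol(matrix))) {
    overall <- stats::median(matrix[, j], na.rm = TRUE)
    if (is.na(overall) || overall == 0) { skipped <- skipped + nlevels(batch); next }
    for (b in levels(batch)) {
      rows <- which(batch == b)
      bmed <- stats::median(matrix[rows, j], na.rm = TRUE)
      if (is.na(bmed) || bmed == 0) { skipped <- skipped + 1L; next }
      out[rows, j] <- matrix[rows, j] * (overall / bmed)
    }
  }
  if (skipped > 0)
    warning(skipped, " batch-feature pair(s) left unscaled ",
            "(zero or undefined median)")
  out
}
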