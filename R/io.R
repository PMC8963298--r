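# Plain-text readers and writers for the tabular artifacts. Delimiter is
# sniffed from the file extension (.csv -> comma, anything else -> tab).
# Missing-value tokens are fixed to "NA", "" and "NaN" (case sensitive),
# matching the write conventions of the R ecosystem these files come from.

MISSING_TOKENS <- c("NA", "", "NaN")

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an abundance matrix from a delimited text file
#'
#' The first column must hold row identifiers and the header row column
#' identifiers. Cells equal to `NA`, `NaN` or empty are treated as missing;
#' every other cell must parse as a non-negative number.
#'
#' @param path path to a `.txt`/`.tsv` (tab) or `.csv` (comma) file.
#' @param orientation `"samples_in_rows"` (default), `"features_in_rows"`,
#'   or `"auto"`. With `"auto"`, `sample_ids` must be supplied and the
#'   orientation is inferred from which dimension matches them; ambiguous
#'   or unmatched files are an error, so silent transposition cannot occur.
#' @param sample_ids known sample identifiers, only used for
#'   `orientation = "auto"`.
#' @return numeric matrix, samples in rows, features in columns.
#' @export
read_matrix <- function(path,
                        orientation = c("samples_in_rows", "features_in_rows",
                                        "auto"),
                        sample_ids = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                           row.names = NULL, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "", na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("matrix file needs an id column plus data columns")
  row_ids <- raw[[1]]
  col_ids <- colnames(raw)[-1]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup)) stop("duplicated row ids in ", path, ": ",
                        paste(dup, collapse = ", "))
  dup <- unique(col_ids[duplicated(col_ids)])
  if (length(dup)) stop("duplicated column ids in ", path, ": ",
                        paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  is_miss <- cells %in% MISSING_TOKENS
  num <- suppressWarnings(as.numeric(cells))
  bad <- !is_miss & is.na(num)
  if (any(bad)) {
    at <- which(matrix(bad, nrow = nrow(cells)), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                 row_ids[at[1]], col_ids[at[2]], cells[at[1], at[2]]))
  }
  neg <- !is.na(num) & num < 0
  if (any(neg)) {
    at <- which(matrix(neg, nrow = nrow(cells)), arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', column '%s': %s",
                 row_ids[at[1]], col_ids[at[2]], cells[at[1], at[2]]))
  }
  m <- matrix(num, nrow = nrow(cells),
              dimnames = list(row_ids, col_ids))
  if (orientation == "auto") {
    if (is.null(sample_ids))
      stop("orientation = 'auto' requires sample_ids")
    in_rows <- mean(row_ids %in% sample_ids)
    in_cols <- mean(col_ids %in% sample_ids)
    if (in_rows >= 0.5 && in_cols < 0.5) {
      orientation <- "samples_in_rows"
    } else if (in_cols >= 0.5 && in_rows < 0.5) {
      orientation <- "features_in_rows"
    } else {
      stop("cannot auto-detect orientation; pass it explicitly")
    }
  }
  if (orientation == "features_in_rows") m <- t(m)
  validate_abundance(m)
  m
}

#' Read a sample metadata table
#'
#' First column = sample id; remaining columns are batch/technical
#' variables kept as character. Rows for samples absent from the matrix
#' are permitted (with a warning at matching time).
#'
#' @param path delimited text file.
#' @return data.frame with a `sample_id` column.
#' @export
read_sample_metadata <- function(path) {
  d <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         quote = "\"", comment.char = "",
                         stringsAsFactors = FALSE)
  names(d)[1] <- "sample_id"
  if (anyDuplicated(d$sample_id))
    stop("duplicated sample ids in metadata")
  if (anyDuplicated(names(d))) stop("duplicated variable names in metadata")
  d[d == ""] <- NA
  d
}

#' Read a feature annotation table
#'
#' Expects a first id column and optionally columns `is_xenobiotic`,
#' `is_derived` (TRUE/FALSE or 1/0) and `pathway`. Absent flags default to
#' FALSE.
#'
#' @param path delimited text file.
#' @return data.frame as produced by [feature_annotation()].
#' @export
read_feature_annotation <- function(path) {
  d <- utils::read.table(path, sep = sniff_sep(path), header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         quote = "\"", comment.char = "",
                         stringsAsFactors = FALSE)
  names(d)[1] <- "feature_id"
  if (anyDuplicated(d$feature_id)) stop("duplicated feature ids in annotation")
  as_flag <- function(x) {
    if (is.null(x)) return(rep(FALSE, nrow(d)))
    toupper(x) %in% c("TRUE", "T", "1", "YES")
  }
  out <- data.frame(feature_id = d$feature_id,
                    is_xenobiotic = as_flag(d$is_xenobiotic),
                    is_derived = as_flag(d$is_derived),
                    pathway = if ("pathway" %in% names(d)) d$pathway
                              else NA_character_,
                    stringsAsFactors = FALSE)
  out
}

# All floating point output uses 12 significant digits so that re-runs give
# byte-identical, diff-able files.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = 12, format = "g")
  }, character(1))
  out
}

format_df <- function(d) {
  for (j in seq_along(d)) if (is.numeric(d[[j]])) d[[j]] <- format_num(d[[j]])
  d
}

#' Write an abundance matrix to tab-delimited text
#'
#' Floats are written with 12 significant digits; missing entries as `NA`.
#' [read_matrix()] on the result reproduces values and missingness exactly
#' at that precision.
#'
#' @param matrix samples x features numeric matrix.
#' @param path output path.
#' @export
write_matrix <- function(matrix, path) {
  validate_abundance(matrix)
  d <- as.data.frame(matrix(format_num(matrix), nrow = nrow(matrix)),
                     stringsAsFactors = FALSE)
  colnames(d) <- colnames(matrix)
  d <- cbind(sample_id = rownames(matrix), d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all pipeline output tables
#'
#' Writes the raw and filtered abundance matrices, the raw and filtered
#' sample and feature summary tables, and the exclusion log, all
#' tab-delimited with fixed column order. Re-running with identical inputs
#' yields byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @param raw_matrix,filtered_matrix abundance matrices.
#' @param raw_sample_summary,raw_feature_summary,filtered_sample_summary,filtered_feature_summary
#'   summary data.frames as built by [sample_summary()] / [feature_summary()].
#' @param exclusion_log exclusion-log data.frame from
#'   [apply_filter_pipeline()].
#' @return named character vector of the files written.
#' @export
write_tables <- function(outdir, raw_matrix, filtered_matrix,
                         raw_sample_summary, raw_feature_summary,
                         filtered_sample_summary, filtered_feature_summary,
                         exclusion_log) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0)
    stop("output directory is not writable: ", outdir)
  files <- c(
    raw_matrix = "raw_abundance.tsv",
    filtered_matrix = "filtered_abundance.tsv",
    raw_sample_summary = "sample_summary_raw.tsv",
    raw_feature_summary = "feature_summary_raw.tsv",
    filtered_sample_summary = "sample_summary_filtered.tsv",
    filtered_feature_summary = "feature_summary_filtered.tsv",
    exclusion_log = "exclusion_log.tsv")
  paths <- file.path(outdir, files)
  names(paths) <- names(files)
  write_matrix(raw_matrix, paths["raw_matrix"])
  write_matrix(filtered_matrix, paths["filtered_matrix"])
  wt <- function(d, p) utils::write.table(format_df(d), p, sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wt(raw_sample_summary, paths["raw_sample_summary"])
  wt(raw_feature_summary, paths["raw_feature_summary"])
  wt(filtered_sample_summary, paths["filtered_sample_summary"])
  wt(filtered_feature_summary, paths["filtered_feature_summary"])
  wt(exclusion_log, paths["exclusion_log"])
  paths
}
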