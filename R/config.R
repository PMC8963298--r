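# Pipeline configuration: the user-settable thresholds plus fixed internal
# constants. The parameter-file key names are this package's own; the
# grammar is flat key=value, one per line, with "#" comments.

config_defaults <- function() {
  list(
    project_name = "metabscreen project",
    platform = NA_character_,
    data_file = NA_character_,
    sample_metadata_file = NA_character_,
    feature_annotation_file = NA_character_,
    feature_missingness_max = 0.2,
    sample_missingness_max = 0.2,
    tsa_sd_threshold = 5,
    outlier_iqr_multiplier = 5,
    pca_outlier_mode = "leave",
    tree_cut_height = 0.5,
    pc_sd_threshold = 5,
    exclude_derived = TRUE,
    batch_normalization_column = NA_character_,
    rng_seed = 2022L,
    # fixed internals, not settable through the parameter file
    extreme_missingness = 0.8,
    pc_min_components = 2L
  )
}

config_file_keys <- function() {
  setdiff(names(config_defaults()),
          c("extreme_missingness", "pc_min_components"))
}

#' Default pipeline configuration
#'
#' Returns the full set of pipeline parameters at their default values,
#' optionally overriding any of them. Settable parameters:
#' \describe{
#'   \item{feature_missingness_max}{fraction in \[0,1\]; features with
#'     missingness at or above this are excluded (default 0.2). 0 disables
#'     the step.}
#'   \item{sample_missingness_max}{fraction in \[0,1\]; samples with
#'     missingness at or above this are excluded (default 0.2). 0 disables
#'     the step.}
#'   \item{tsa_sd_threshold}{total-sum-abundance exclusion threshold in SD
#'     units from the mean, on complete features only (default 5).}
#'   \item{outlier_iqr_multiplier}{a value is an outlier when more than this
#'     many IQR units from the feature median (default 5).}
#'   \item{pca_outlier_mode}{how outlying values are treated in the PCA
#'     working copy: "leave", "to_na" or "winsorize".}
#'   \item{tree_cut_height}{dendrogram cut height in 1 - |Spearman rho|
#'     units, in (0,1\] (default 0.5).}
#'   \item{pc_sd_threshold}{PC sample-outlier threshold in SD units
#'     (default 5).}
#'   \item{exclude_derived}{drop derived measures (ratios etc.) from
#'     missingness/TSA/PCA calculations (default TRUE).}
#'   \item{batch_normalization_column}{sample-metadata column used for
#'     median batch normalization; NA disables normalization.}
#'   \item{rng_seed}{integer seed controlling every stochastic step.}
#' }
#' Two internal constants are fixed and not settable via the parameter
#' file: `extreme_missingness` (0.8, the first-pass missingness cut) and
#' `pc_min_components` (2, the floor on retained PCs).
#'
#' @param ... name = value overrides of the settable parameters.
#' @return a list of class `metab_config`.
#' @export
#' @examples
#' cfg <- default_config(tree_cut_height = 0.4)
default_config <- function(...) {
  cfg <- config_defaults()
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), config_file_keys())
    if (length(bad)) stop("unknown configuration keys: ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  frac <- c("feature_missingness_max", "sample_missingness_max")
  for (k in frac) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(k, " must be a fraction in [0, 1], got: ", cfg[[k]])
    cfg[[k]] <- as.numeric(v)
  }
  pos <- c("tsa_sd_threshold", "outlier_iqr_multiplier", "pc_sd_threshold")
  for (k in pos) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0)
      stop(k, " must be a positive number, got: ", cfg[[k]])
    cfg[[k]] <- as.numeric(v)
  }
  v <- cfg$tree_cut_height
  if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1)
    stop("tree_cut_height must lie in (0, 1], got: ", v)
  if (!cfg$pca_outlier_mode %in% c("leave", "to_na", "winsorize"))
    stop("pca_outlier_mode must be one of leave, to_na, winsorize")
  if (!is.logical(cfg$exclude_derived) || is.na(cfg$exclude_derived))
    stop("exclude_derived must be TRUE or FALSE")
  if (!is.numeric(cfg$rng_seed) || is.na(cfg$rng_seed))
    stop("rng_seed must be an integer")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  structure(cfg, class = "metab_config")
}

#' Read a pipeline parameter file
#'
#' Parses a flat `key=value` parameter file (one pair per line, `#` starts
#' a comment, blank lines ignored). Keys absent from the file keep their
#' defaults; unknown keys and out-of-range values are errors.
#'
#' @param path path to the parameter file.
#' @return a validated `metab_config` list.
#' @seealso [default_config()] for the documented key set.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- config_defaults()
  allowed <- config_file_keys()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed parameter line (expected key=value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% allowed)
      stop("unknown parameter key: '", key, "'")
    cfg[[key]] <- parse_config_value(key, val, cfg[[key]])
  }
  validate_config(cfg)
}

parse_config_value <- function(key, val, default) {
  if (is.logical(default)) {
    out <- toupper(val) %in% c("TRUE", "T", "YES", "1")
    if (!toupper(val) %in% c("TRUE", "T", "YES", "1", "FALSE", "F", "NO", "0"))
      stop("parameter '", key, "' must be TRUE/FALSE, got: ", val)
    return(out)
  }
  if (is.numeric(default)) {
    out <- suppressWarnings(as.numeric(val))
    if (is.na(out)) stop("parameter '", key, "' must be numeric, got: ", val)
    return(out)
  }
  if (!nzchar(val) || toupper(val) == "NA") return(NA_character_)
  val
}

#' @export
print.metab_config <- function(x, ...) {
  cat("metabscreen pipeline configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", k, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}
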