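# Seeded synthetic metabolomics fixture with known ground truth. The
# generator emulates the data properties the pipeline assumes: right-
# skewed (log-normal) abundances, block-correlated feature clusters,
# multiplicative batch shifts, feature- and sample-level missingness,
# presence/absence xenobiotics, derived ratio features, and planted
# outlier values and outlier samples. Everything is reproducible from the
# seed.

#' Generate a synthetic metabolomics dataset with known ground truth
#'
#' Core features are exponentiated correlated Gaussians: within each of
#' `n_blocks` contiguous blocks, latent z-scores share a block factor with
#' correlation `within_block_rho`; marginals are log-normal with log-scale
#' SD drawn from 0.15-0.4 (typical metabolomics CVs). Batch labels are
#' assigned round-robin and each feature x batch cell receives a
#' multiplicative shift (batch 1 is the unshifted reference). Missingness
#' is planted completely at random on alternating features within each
#' block, at a per-feature rate chosen so the overall core missingness
#' equals `feature_missing_rate`; features at even within-block positions
#' stay complete. Planted anomalies:
#' \itemize{
#'   \item `n_highmiss_samples` samples get `sample_missing_boost` of their
#'     non-xenobiotic features set missing (caught by the extreme sample
#'     missingness filter);
#'   \item `n_outlier_samples` samples have all values multiplied by 10 —
#'     a global handling-error signature caught by the TSA filter;
#'   \item `n_pc_outlier_samples` samples have their block-1 representative
#'     feature shifted +12 feature SDs and their block-2 representative
#'     pulled toward zero, an approximately TSA-neutral perturbation that
#'     is extreme on the top principal components (caught by the PC
#'     filter);
#'   \item `n_outlier_cells` single cells (on missingness-carrying
#'     features of otherwise normal samples) set to median + 8 IQR.
#' }
#' Xenobiotic features are present in ~15% of samples (missing otherwise);
#' derived features are ratios of two core parents (one missingness-
#' carrying, one complete, from different blocks), so parent missingness
#' propagates.
#'
#' @param n_samples,n_features dataset dimensions (features include the
#'   xenobiotic and derived columns).
#' @param n_blocks number of correlated feature blocks among core features.
#' @param within_block_rho latent within-block correlation.
#' @param batch_count number of batches.
#' @param batch_shift maximum multiplicative batch shift; per feature x
#'   batch factors are drawn log-uniformly in \[1/batch_shift, batch_shift\].
#' @param feature_missing_rate overall fraction of missing core cells.
#' @param sample_missing_boost missingness fraction planted in designated
#'   high-missingness samples.
#' @param n_outlier_cells,n_outlier_samples,n_pc_outlier_samples,n_highmiss_samples
#'   counts of planted anomalies.
#' @param n_xenobiotics,n_derived counts of special feature classes.
#' @param seed integer seed; identical inputs give identical output.
#' @return list with `matrix` (abundance matrix), `meta` (sample metadata
#'   with `batch` and `run_day`), `annotation` (feature annotation) and
#'   `truth` — the planted ground truth (block assignment, batch
#'   multipliers, planted missing cells, outlier cells, the ids of planted
#'   high-missingness / TSA-outlier / PC-outlier samples, parent map of
#'   derived features, and the representative feature expected per block).
#' @export
generate_fixture <- function(n_samples = 200, n_features = 60, n_blocks = 3,
                             within_block_rho = 0.95, batch_count = 2,
                             batch_shift = 1.25,
                             feature_missing_rate = 0.05,
                             sample_missing_boost = 0.85,
                             n_outlier_cells = 10, n_outlier_samples = 1,
                             n_pc_outlier_samples = 1,
                             n_highmiss_samples = 2,
                             n_xenobiotics = 5, n_derived = 5,
                             seed = 20220204) {
  n_core <- n_features - n_xenobiotics - n_derived
  if (n_core < 2 * n_blocks)
    stop("inconsistent parameters: need at least 2 core features per block")
  if (n_blocks < 1 || within_block_rho < 0 || within_block_rho >= 1)
    stop("inconsistent block parameters")
  if (feature_missing_rate < 0 || feature_missing_rate > 0.4)
    stop("feature_missing_rate must lie in [0, 0.4]")
  n_special <- n_highmiss_samples + n_outlier_samples + n_pc_outlier_samples
  if (n_special + n_outlier_cells > n_samples)
    stop("more planted anomalies than samples")

  with_seed(seed, {
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    core_ids <- sprintf("met_%02d", seq_len(n_core))
    xeno_ids <- if (n_xenobiotics) sprintf("xeno_%02d", seq_len(n_xenobiotics))
                else character()
    derived_ids <- if (n_derived) sprintf("ratio_%02d", seq_len(n_derived))
                   else character()

    block <- sort(rep_len(seq_len(n_blocks), n_core))
    within_pos <- stats::ave(seq_len(n_core), block, FUN = seq_along)
    # odd within-block positions stay complete; even positions carry the
    # planted missingness (keeps complete features balanced across blocks)
    miss_carrier <- within_pos %% 2 == 0

    # latent correlated Gaussians -> log-normal abundances
    zf <- matrix(stats::rnorm(n_samples * n_blocks), n_samples, n_blocks)
    eps <- matrix(stats::rnorm(n_samples * n_core), n_samples, n_core)
    z <- sqrt(within_block_rho) * zf[, block, drop = FALSE] +
      sqrt(1 - within_block_rho) * eps
    mu_f <- stats::runif(n_core, log(10), log(1000))
    sd_f <- stats::runif(n_core, 0.15, 0.40)
    core <- exp(sweep(sweep(z, 2, sd_f, "*"), 2, mu_f, "+"))
    dimnames(core) <- list(sample_ids, core_ids)

    # batch assignment and multiplicative shifts (batch 1 = reference)
    batch <- rep_len(seq_len(batch_count), n_samples)
    mult <- matrix(1, n_core, batch_count)
    if (batch_count > 1)
      mult[, -1] <- exp(stats::runif(n_core * (batch_count - 1),
                                     -log(batch_shift), log(batch_shift)))
    for (b in seq_len(batch_count))
      core[batch == b, ] <- sweep(core[batch == b, , drop = FALSE], 2,
                                  mult[, b], "*")

    # designate special samples (disjoint)
    pool <- sample(n_samples)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    highmiss_idx <- if (n_highmiss_samples) take(n_highmiss_samples) else integer()
    tsa_idx <- if (n_outlier_samples) take(n_outlier_samples) else integer()
    pc_idx <- if (n_pc_outlier_samples) take(n_pc_outlier_samples) else integer()

    # TSA-extreme samples: global multiplicative handling-error signature
    if (length(tsa_idx))
      core[tsa_idx, ] <- core[tsa_idx, , drop = FALSE] * 10

    # PC-outlier samples: shift the expected representative of block 1 far
    # up and pull the block-2 representative toward zero; approximately
    # TSA-neutral but extreme on the leading PCs of the representative set.
    # Representatives are the least-missing feature per cluster with ties
    # broken by column order, i.e. the first complete feature per block.
    rep_expected <- vapply(seq_len(n_blocks), function(b)
      core_ids[which(block == b & !miss_carrier)[1]], character(1))
    if (length(pc_idx)) {
      j1 <- match(rep_expected[1], core_ids)
      j2 <- match(rep_expected[min(2, n_blocks)], core_ids)
      for (i in pc_idx) {
        core[i, j1] <- mean(core[, j1]) + 12 * stats::sd(core[, j1])
        core[i, j2] <- 0.01 * stats::median(core[, j2])
      }
    }

    # planted cell-level outliers on missingness-carrying features of
    # otherwise normal samples: beyond 6 IQR by construction (8 IQR used)
    outlier_cells <- NULL
    if (n_outlier_cells > 0) {
      cell_samples <- take(min(n_outlier_cells, length(pool)))
      carriers <- which(miss_carrier)
      cell_feats <- sample(carriers, length(cell_samples), replace = TRUE)
      for (i in seq_along(cell_samples)) {
        v <- core[, cell_feats[i]]
        core[cell_samples[i], cell_feats[i]] <-
          stats::median(v) + 8 * diff(stats::quantile(v, c(0.25, 0.75)))
      }
      outlier_cells <- data.frame(sample_id = sample_ids[cell_samples],
                                  feature_id = core_ids[cell_feats],
                                  stringsAsFactors = FALSE)
    }

    # random missingness on carrier features; special samples exempt so the
    # planted designs stay clean
    miss_cells <- matrix(FALSE, n_samples, n_core)
    if (feature_missing_rate > 0 && any(miss_carrier)) {
      rate <- feature_missing_rate * n_core / sum(miss_carrier)
      eligible_rows <- setdiff(seq_len(n_samples),
                               c(highmiss_idx, tsa_idx, pc_idx))
      draw <- matrix(stats::runif(length(eligible_rows) * sum(miss_carrier)),
                     length(eligible_rows))
      miss_cells[eligible_rows, miss_carrier] <- draw < rate
    }
    if (!is.null(outlier_cells))     # planted outliers must stay observed
      miss_cells[cbind(match(outlier_cells$sample_id, sample_ids),
                       match(outlier_cells$feature_id, core_ids))] <- FALSE

    # high-missingness samples: sample_missing_boost of core features.
    # The missing set is deterministic — carrier features first, then
    # non-carriers from the last block backwards — so the least-missing
    # feature of each block (the representative-to-be) stays observed.
    if (length(highmiss_idx)) {
      k <- ceiling(sample_missing_boost * n_core)
      ord <- c(which(miss_carrier), rev(which(!miss_carrier)))
      miss_cells[highmiss_idx, ord[seq_len(k)]] <- TRUE
    }
    core[miss_cells] <- NA_real_

    # derived ratio features: one missingness-carrying parent, one complete
    # parent from a different block; NA propagates from parents
    derived <- NULL
    parents <- NULL
    if (n_derived > 0) {
      carriers <- which(miss_carrier)
      completes <- which(!miss_carrier)
      pa <- carriers[((seq_len(n_derived) - 1) %% length(carriers)) + 1]
      pb <- vapply(pa, function(a) {
        cand <- completes[block[completes] != block[a]]
        cand[1]
      }, integer(1))
      derived <- core[, pa, drop = FALSE] / core[, pb, drop = FALSE]
      colnames(derived) <- derived_ids
      parents <- data.frame(derived_id = derived_ids,
                            numerator = core_ids[pa],
                            denominator = core_ids[pb],
                            stringsAsFactors = FALSE)
    }

    # xenobiotics: presence/absence, observed in ~15% of samples
    xeno <- NULL
    if (n_xenobiotics > 0) {
      xeno <- matrix(NA_real_, n_samples, n_xenobiotics,
                     dimnames = list(sample_ids, xeno_ids))
      for (j in seq_len(n_xenobiotics)) {
        present <- stats::runif(n_samples) < 0.15
        xeno[present, j] <- exp(stats::rnorm(sum(present), log(50), 1))
      }
    }

    m <- cbind(core, if (!is.null(xeno)) xeno, if (!is.null(derived)) derived)
    validate_abundance(m)

    meta <- data.frame(sample_id = sample_ids,
                       batch = paste0("B", batch),
                       run_day = paste0("D", rep_len(seq_len(5), n_samples)),
                       stringsAsFactors = FALSE)
    annotation <- feature_annotation(colnames(m),
                                     xenobiotic_ids = xeno_ids,
                                     derived_ids = derived_ids)
    truth <- list(block = stats::setNames(block, core_ids),
                  miss_carrier = stats::setNames(miss_carrier, core_ids),
                  batch_multipliers = mult,
                  missing_cells = which(miss_cells, arr.ind = TRUE),
                  outlier_cells = outlier_cells,
                  highmiss_samples = sample_ids[highmiss_idx],
                  tsa_outlier_samples = sample_ids[tsa_idx],
                  pc_outlier_samples = sample_ids[pc_idx],
                  representatives_expected = rep_expected,
                  derived_parents = parents)
    list(matrix = m, meta = meta, annotation = annotation, truth = truth)
  })
}

#' Write a fixture to delimited text files
#'
#' Emits the abundance matrix, sample metadata, feature annotation and a
#' ready-to-run parameter file in the formats [read_matrix()],
#' [read_sample_metadata()], [read_feature_annotation()] and
#' [read_config()] accept.
#'
#' @param fixture result of [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return named vector of the paths written.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "abundance.tsv"),
             meta = file.path(dir, "sample_metadata.tsv"),
             annotation = file.path(dir, "feature_annotation.tsv"),
             params = file.path(dir, "params.txt"))
  write_matrix(fixture$matrix, paths["matrix"])
  utils::write.table(fixture$meta, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fixture$annotation, paths["annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c("# metabscreen parameter file",
               "project_name=synthetic fixture",
               "platform=synthetic",
               "data_file=abundance.tsv",
               "sample_metadata_file=sample_metadata.tsv",
               "feature_annotation_file=feature_annotation.tsv",
               "batch_normalization_column=batch"),
             paths["params"])
  paths
}
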