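# The ordered exclusion pipeline and its accounting guarantees.

test_that("planted high-missingness samples are removed at the extreme step", {
  fx <- generate_fixture(n_highmiss_samples = 2, seed = 13)
  m <- median_batch_normalize(fx$matrix, fx$meta, "batch")
  res <- suppressWarnings(apply_filter_pipeline(m, fx$annotation,
                                                default_config()))
  step1 <- res$log[res$log$step == 1, ]
  expect_equal(step1$n_removed, 2L)
  expect_setequal(strsplit(step1$removed_ids, ";")[[1]],
                  fx$truth$highmiss_samples)
})

test_that("identity configuration removes nothing and logs all six steps", {
  fx <- generate_fixture(n_samples = 80, n_features = 24, n_blocks = 3,
                         n_highmiss_samples = 0, n_outlier_samples = 0,
                         n_pc_outlier_samples = 0, n_outlier_cells = 0,
                         n_xenobiotics = 2, n_derived = 2, seed = 17)
  cfg <- default_config(sample_missingness_max = 0,
                        feature_missingness_max = 0,
                        tsa_sd_threshold = Inf, pc_sd_threshold = Inf)
  res <- suppressWarnings(apply_filter_pipeline(fx$matrix, fx$annotation, cfg))
  expect_identical(res$matrix, fx$matrix)
  expect_equal(nrow(res$log), 6L)
  expect_true(all(res$log$n_removed == 0))
  expect_true(all(res$log$threshold[3:4] == "disabled"))
})

test_that("per-step removals reconcile with initial and final counts", {
  fx <- generate_fixture(seed = 19)
  m <- median_batch_normalize(fx$matrix, fx$meta, "batch")
  res <- suppressWarnings(apply_filter_pipeline(m, fx$annotation,
                                                default_config()))
  lg <- res$log
  for (ent in c("sample", "feature")) {
    rows <- lg[lg$entity == ent, ]
    init <- if (ent == "sample") nrow(m) else ncol(m)
    final <- if (ent == "sample") nrow(res$matrix) else ncol(res$matrix)
    expect_equal(sum(rows$n_removed), init - final)
    # internal consistency of each row
    expect_equal(rows$n_before - rows$n_removed, rows$n_after)
  }
  # the ids column is consistent with the counts
  n_ids <- vapply(strsplit(lg$removed_ids, ";"),
                  function(x) length(x[nzchar(x)]), integer(1))
  expect_equal(n_ids, lg$n_removed)
})

test_that("xenobiotics survive missingness filtering at any missingness", {
  fx <- generate_fixture(n_xenobiotics = 4, seed = 23)
  xeno <- fx$annotation$feature_id[fx$annotation$is_xenobiotic]
  # planted presence/absence xenobiotics run at ~85% missingness
  expect_true(all(feature_missingness(fx$matrix)[xeno] > 0.5))
  m <- median_batch_normalize(fx$matrix, fx$meta, "batch")
  res <- suppressWarnings(apply_filter_pipeline(m, fx$annotation,
                                                default_config()))
  expect_true(all(xeno %in% colnames(res$matrix)))
  # without annotation the same features are removed as ordinary ones
  res2 <- suppressWarnings(apply_filter_pipeline(m, NULL, default_config()))
  expect_false(any(xeno %in% colnames(res2$matrix)))
})

test_that("a global x10 sample falls at the TSA step, not earlier", {
  fx <- generate_fixture(n_outlier_samples = 1, seed = 29)
  m <- median_batch_normalize(fx$matrix, fx$meta, "batch")
  res <- suppressWarnings(apply_filter_pipeline(m, fx$annotation,
                                                default_config()))
  lg <- res$log
  tsa_id <- fx$truth$tsa_outlier_samples
  expect_true(grepl(tsa_id, lg$removed_ids[lg$step == 5]))
  expect_false(any(grepl(tsa_id, lg$removed_ids[lg$step %in% c(1, 3)])))
})

test_that("loosening a threshold never removes more at that step", {
  fx <- generate_fixture(seed = 37)
  m <- median_batch_normalize(fx$matrix, fx$meta, "batch")
  strict <- suppressWarnings(apply_filter_pipeline(
    m, fx$annotation, default_config(tsa_sd_threshold = 3,
                                     pc_sd_threshold = 3)))
  loose <- suppressWarnings(apply_filter_pipeline(
    m, fx$annotation, default_config(tsa_sd_threshold = 6,
                                     pc_sd_threshold = 6)))
  expect_lte(loose$log$n_removed[5], strict$log$n_removed[5])
})

test_that("an empty result names the offending step", {
  set.seed(1)
  m <- matrix(exp(rnorm(16)), 4, 4,
              dimnames = list(paste0("s", 1:4), paste0("f", 1:4)))
  m[(row(m) + col(m)) %% 2 == 0] <- NA  # every sample and feature 50% missing
  cfg <- default_config(sample_missingness_max = 0.4)
  expect_error(suppressWarnings(apply_filter_pipeline(m, NULL, cfg)),
               "no data remain after step: sample missingness")
})

test_that("rerunning the pipeline on its own output removes nothing more", {
  fx <- generate_fixture(seed = 41)
  m <- median_batch_normalize(fx$matrix, fx$meta, "batch")
  cfg <- default_config()
  r1 <- suppressWarnings(apply_filter_pipeline(m, fx$annotation, cfg))
  r2 <- suppressWarnings(apply_filter_pipeline(r1$matrix, fx$annotation, cfg))
  expect_equal(sum(r2$log$n_removed), 0)
  expect_identical(r2$matrix, r1$matrix)
})
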