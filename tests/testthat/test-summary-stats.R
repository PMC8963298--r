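# Sample- and feature-level quality statistics against hand computations
# and brute-force oracles.

test_that("sample missingness counts missing cells with exclusions", {
  m <- matrix(c(1, NA, 3, 4), 1, 4,
              dimnames = list("s1", paste0("f", 1:4)))
  expect_equal(unname(sample_missingness(m)), 0.25)
  # the missing entry sits in an excluded (xenobiotic-like) feature
  expect_equal(unname(sample_missingness(m, excluded_features = "f2")), 0)
  expect_error(sample_missingness(m, excluded_features = paste0("f", 1:4)),
               "all features excluded")
})

test_that("missingness matches brute-force loops on random matrices", {
  for (seed in c(1, 2, 3)) {
    m <- rand_abundance(20, 10, miss_rate = 0.2, seed = seed)
    expect_equal(sample_missingness(m), oracle_sample_missingness(m),
                 tolerance = 1e-15)
    expect_equal(feature_missingness(m), oracle_feature_missingness(m),
                 tolerance = 1e-15)
    excl <- colnames(m)[1:3]
    expect_equal(sample_missingness(m, excl),
                 oracle_sample_missingness(m, excl), tolerance = 1e-15)
    # sum check: total missing cells agree along both margins
    expect_equal(sum(sample_missingness(m) * ncol(m)),
                 sum(feature_missingness(m) * nrow(m)))
  }
})

test_that("TSA reproduces the worked 3x2 example", {
  m <- cbind(f1 = c(1, 2, 3), f2 = c(2, 4, 6))
  rownames(m) <- paste0("s", 1:3)
  expect_equal(unname(total_sum_abundance(m)), c(0, 2, 4))
})

test_that("TSA handles degenerate and incomplete features", {
  m <- cbind(f1 = c(1, 2, 3), f2 = c(5, 5, 5))
  rownames(m) <- paste0("s", 1:3)
  expect_warning(tsa <- total_sum_abundance(m), "zero-variance")
  expect_equal(unname(tsa), c(0, 1, 2))
  # complete-only TSA ignores a feature containing a missing value
  m2 <- cbind(f1 = c(1, 2, 3), f2 = c(2, NA, 6))
  rownames(m2) <- paste0("s", 1:3)
  expect_equal(unname(total_sum_abundance(m2, complete_only = TRUE)),
               c(0, 1, 2))
  # and is invariant to adding incomplete features
  m3 <- cbind(m2, f3 = c(NA, 1, 9))
  expect_equal(total_sum_abundance(m3, complete_only = TRUE),
               total_sum_abundance(m2, complete_only = TRUE))
})

test_that("TSA matches the brute-force oracle on random matrices", {
  for (seed in 4:6) {
    m <- rand_abundance(20, 10, miss_rate = 0.15, seed = seed)
    set.seed(seed)
    m[, 1:3] <- exp(rnorm(60, 3, 0.5))   # guarantee complete features
    expect_equal(total_sum_abundance(m), oracle_tsa(m), tolerance = 1e-12)
    expect_equal(total_sum_abundance(m, complete_only = TRUE),
                 oracle_tsa(m, complete_only = TRUE), tolerance = 1e-12)
  }
})

test_that("IQR outlier rule follows the hand-computed example", {
  m <- cbind(f1 = c(1:9, 100))
  rownames(m) <- paste0("s", 1:10)
  of <- outlier_flags(m, k = 5)
  # median 5.5, IQR 4.5 (type-7 quantiles); |100 - 5.5| = 94.5 > 22.5
  expect_equal(unname(of$feature_counts), 1L)
  expect_true(of$flags["s10", "f1"])
  expect_false(any(of$flags[1:9, "f1"]))
  # all-equal feature never flags
  m2 <- cbind(f1 = rep(3, 8))
  rownames(m2) <- paste0("s", 1:8)
  expect_equal(sum(outlier_flags(m2, 5)$flags), 0)
})

test_that("outlier flags match brute force and shrink as k grows", {
  for (seed in 7:9) {
    m <- rand_abundance(20, 10, miss_rate = 0.1, seed = seed)
    of <- outlier_flags(m, k = 1)
    orc <- oracle_outlier_counts(m, k = 1)
    expect_equal(unname(of$sample_counts), orc$sample_counts)
    expect_equal(unname(of$feature_counts), orc$feature_counts)
    f2 <- outlier_flags(m, k = 2)$flags
    expect_true(all(of$flags[f2]))   # flags(k=2) subset of flags(k=1)
  }
})

test_that("feature descriptives match hand computation and oracle", {
  m <- cbind(f1 = c(2, 4, 6))
  rownames(m) <- paste0("s", 1:3)
  d <- feature_descriptives(m)
  expect_equal(d$n, 3)
  expect_equal(d$mean, 4)
  expect_equal(d$sd, 2)
  expect_equal(d$cv, 0.5)
  expect_equal(d$skew, 0)
  # symmetric sample: zero skew
  ms <- cbind(f1 = c(-3, -1, 0, 1, 3) + 10)
  rownames(ms) <- paste0("s", 1:5)
  expect_lt(abs(feature_descriptives(ms)$skew), 1e-12)
  # single observation: undefined spread
  m1 <- matrix(c(5, NA), 2, 1, dimnames = list(c("a", "b"), "f1"))
  d1 <- feature_descriptives(m1)
  expect_true(is.na(d1$sd) && is.na(d1$cv) && is.na(d1$skew))
  # random-matrix oracle equality
  m <- rand_abundance(20, 10, miss_rate = 0.15, seed = 10)
  got <- feature_descriptives(m)
  exp <- oracle_descriptives(m)
  expect_equal(as.matrix(got[, c("n", "mean", "sd", "skew", "cv")]),
               exp, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Shapiro W behaves sensibly on known distributions", {
  set.seed(7)
  w <- normality_w(rnorm(500))
  expect_gt(w$w_raw, 0.99)
  set.seed(8)
  w <- normality_w(exp(rnorm(500)))
  expect_gt(w$w_log10, w$w_raw)   # log-normal data normalize under log10
  w <- normality_w(rep(2, 10))
  expect_true(is.na(w$w_raw))
  expect_equal(w$reason_raw, "zero variance")
  expect_true(is.na(normality_w(c(1, 2, 3))$w_raw))  # n < 4
  # > 5000 observations: seeded subsample keeps the result reproducible
  set.seed(9)
  big <- rnorm(6000)
  expect_identical(normality_w(big, seed = 1)$w_raw,
                   normality_w(big, seed = 1)$w_raw)
})

test_that("summary tables carry the documented columns", {
  fx <- generate_fixture(n_samples = 50, n_features = 15, n_blocks = 3,
                         n_xenobiotics = 2, n_derived = 2,
                         n_highmiss_samples = 0, n_outlier_cells = 2,
                         n_outlier_samples = 0, n_pc_outlier_samples = 0,
                         seed = 5)
  cfg <- default_config()
  ids <- eligible_features(fx$matrix, fx$annotation, cfg)
  cl <- cluster_features(fx$matrix, ids, cfg$tree_cut_height)
  xs <- impute_standardize(fx$matrix, cl$representatives)
  pca <- run_pca(xs)
  ss <- suppressWarnings(sample_summary(fx$matrix, fx$annotation, cfg, pca))
  expect_true(all(c("sample_id", "missingness_all", "missingness_excl",
                    "tsa_all", "tsa_complete", "outlier_count", "PC1")
                  %in% names(ss)))
  expect_true(all(ss$missingness_all >= 0 & ss$missingness_all <= 1))
  expect_true(all(ss$outlier_count <= ncol(fx$matrix)))
  fs <- suppressWarnings(feature_summary(fx$matrix, fx$annotation, cl, cfg))
  expect_true(all(c("feature_id", "missingness", "n", "mean", "sd", "skew",
                    "cv", "w_raw", "w_log10", "outlier_count",
                    "independent_features_binary") %in% names(fs)))
  expect_equal(sum(fs$independent_features_binary), cl$k)
  expect_equal(fs$n + fs$missingness * nrow(fx$matrix),
               rep(nrow(fx$matrix), ncol(fx$matrix)), ignore_attr = TRUE)
})
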