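# Feature reduction, PCA, component retention and PC-outlier handling.

test_that("eligibility excludes xenobiotics, high-missing and constant features", {
  set.seed(21)
  m <- matrix(exp(rnorm(40 * 5)), 40, 5,
              dimnames = list(sprintf("s%02d", 1:40), paste0("f", 1:5)))
  m[1:10, 2] <- NA              # 25% missingness -> excluded
  m[, 3] <- 7                   # constant -> excluded
  ann <- feature_annotation(colnames(m), xenobiotic_ids = "f4",
                            derived_ids = "f5")
  # with derived measures excluded only f1 would survive: too few
  expect_error(eligible_features(m, ann, default_config(exclude_derived = TRUE)),
               "fewer than 2")
  ids2 <- eligible_features(m, ann, default_config(exclude_derived = FALSE))
  expect_setequal(ids2, c("f1", "f5"))   # derived retained when configured
  m[1:8, 2] <- exp(rnorm(8))    # back to 20% missingness: boundary retained
  ids3 <- eligible_features(m, ann, default_config(exclude_derived = FALSE))
  expect_true("f2" %in% ids3)
})

test_that("perfect negative correlation clusters together (absolute rho)", {
  x <- seq_len(30) + 0
  m <- cbind(f1 = x, f2 = 100 - x + 0.0)
  m[m < 0] <- 0
  rownames(m) <- sprintf("s%02d", 1:30)
  cl <- cluster_features(m, colnames(m), cut_height = 0.05)
  expect_equal(cl$k, 1L)
  expect_equal(unname(cl$distance["f1", "f2"]), 0)
})

test_that("planted correlation blocks are recovered with one representative each", {
  fx <- generate_fixture(n_samples = 150, n_features = 30, n_blocks = 3,
                         batch_count = 1, n_xenobiotics = 2, n_derived = 2,
                         n_highmiss_samples = 0, n_outlier_samples = 0,
                         n_pc_outlier_samples = 0, n_outlier_cells = 0,
                         seed = 99)
  ids <- eligible_features(fx$matrix, fx$annotation, default_config())
  cl <- cluster_features(fx$matrix, ids, 0.5)
  expect_equal(cl$k, 3L)
  rep_blocks <- fx$truth$block[cl$representatives]
  expect_setequal(unname(rep_blocks), 1:3)
  # every cluster is exactly one block
  expect_equal(length(unique(paste(cl$clusters, fx$truth$block[ids]))), 3L)
  # distance matrix properties
  d <- cl$distance
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # cut at 1.0 merges everything
  expect_equal(cluster_features(fx$matrix, ids, 1.0)$k, 1L)
})

test_that("representatives are the least-missing member, ties by column order", {
  set.seed(3)
  base <- rnorm(50)
  m <- cbind(f1 = base + rnorm(50, 0, 0.01),
             f2 = base + rnorm(50, 0, 0.01),
             f3 = base + rnorm(50, 0, 0.01))
  m <- m - min(m) + 1
  rownames(m) <- sprintf("s%02d", 1:50)
  m[1:5, 1] <- NA                       # f1 most missing
  cl <- cluster_features(m, colnames(m), 0.5)
  expect_equal(cl$k, 1L)
  expect_equal(cl$representatives, "f2")  # f2/f3 tie at 0 -> column order
})

test_that("sparse shared observations get maximal distance with a warning", {
  m <- cbind(f1 = c(1, 2, NA, NA, NA, NA), f2 = c(NA, NA, 1, 3, 2, 5),
             f3 = c(1, 2, 2, 4, 3, 6))
  rownames(m) <- paste0("s", 1:6)
  expect_warning(cl <- cluster_features(m, colnames(m), 0.9),
                 "share < 3 observations")
  expect_equal(unname(cl$distance["f1", "f2"]), 1)
})

test_that("impute_standardize median-imputes then z-transforms", {
  m <- cbind(f1 = c(1, NA, 3), f2 = c(2, 5, 8))
  rownames(m) <- paste0("s", 1:3)
  xs <- impute_standardize(m)
  expect_false(anyNA(xs))
  expect_equal(unname(xs[, "f1"]), c(-1, 0, 1))    # imputed 2, scaled
  expect_equal(unname(xs[, "f2"]), c(-1, 0, 1))
  # complete feature: imputation is the identity
  expect_equal(unname(xs[, "f2"]), unname(scale(m[, "f2"])[, 1]))
  m2 <- cbind(m, f3 = c(NA, NA, NA))
  expect_warning(xs2 <- impute_standardize(m2), "all-missing or constant")
  expect_equal(colnames(xs2), c("f1", "f2"))
})

test_that("PCA satisfies rank-1, centering and isotropic-noise properties", {
  s <- seq_len(20) + 0
  m <- outer(s, c(1, 2, 3))                 # exact rank 1
  dimnames(m) <- list(sprintf("s%02d", 1:20), paste0("f", 1:3))
  p <- run_pca(scale(m))
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-9)
  expect_true(all(abs(colMeans(p$scores)) < 1e-9))
  expect_true(all(diff(p$variance_explained) < 1e-12))
  # isotropic noise: each of 10 components explains about 1/10
  set.seed(12)
  noise <- matrix(rnorm(200 * 10), 200, 10,
                  dimnames = list(sprintf("s%03d", 1:200), paste0("f", 1:10)))
  pn <- run_pca(scale(noise))
  expect_true(all(abs(pn$variance_explained - 0.1) < 0.05))
  # deterministic sign convention: largest loading positive
  for (j in seq_len(ncol(p$rotation)))
    expect_gt(p$rotation[which.max(abs(p$rotation[, j])), j], 0)
})

test_that("acceleration factor follows the second-difference rule", {
  expect_equal(acceleration_factor_n(c(5, 3, 1, 0.5, 0.4, 0.3)), 2L)
  # geometric decay with a single sharp elbow still floors at 2
  expect_equal(acceleration_factor_n(c(10, 1, 0.5, 0.25, 0.12)), 2L)
  expect_error(acceleration_factor_n(c(2, 1)), ">= 3 eigenvalues")
  # brute-force recomputation over random eigenvalue vectors
  set.seed(33)
  for (r in 1:25) {
    e <- sort(rexp(sample(4:12, 1)) + 0.01, decreasing = TRUE)
    p <- length(e)
    best_i <- 0; best_a <- -Inf
    for (i in 2:(p - 1)) {
      a <- e[i + 1] - 2 * e[i] + e[i - 1]
      if (a > best_a + 1e-15) { best_a <- a; best_i <- i }
    }
    expect_equal(acceleration_factor_n(e), max(2L, best_i - 1L))
  }
})

test_that("parallel analysis is seeded and recovers planted factors", {
  # pure noise: hardly any component beats the null
  set.seed(44)
  noise <- scale(matrix(rnorm(100 * 8), 100, 8))
  e <- prcomp(noise)$sdev^2
  n0 <- parallel_analysis_n(e, 100, 8, reps = 60, seed = 9)
  expect_lte(n0, 1)
  expect_identical(parallel_analysis_n(e, 100, 8, reps = 60, seed = 9), n0)
  # three strong planted factors in 500 x 30
  set.seed(45)
  f <- matrix(rnorm(500 * 3), 500, 3)
  load <- matrix(0, 3, 30)
  for (k in 1:3) load[k, (k - 1) * 10 + 1:10] <- 1
  x <- scale(f %*% load + 0.5 * matrix(rnorm(500 * 30), 500, 30))
  ep <- prcomp(x)$sdev^2
  expect_equal(parallel_analysis_n(ep, 500, 30, reps = 60, seed = 10), 3L)
})

test_that("pc_outliers matches a brute-force loop and is monotone", {
  set.seed(55)
  scores <- matrix(rnorm(100 * 4), 100, 4,
                   dimnames = list(sprintf("s%03d", 1:100), NULL))
  scores[7, 2] <- 9            # a clear deviant on PC2
  got <- pc_outliers(scores, 3, 5)
  brute <- character()
  for (i in 1:100) {
    hit <- FALSE
    for (j in 1:3) {
      mu <- mean(scores[, j]); sdj <- sd(scores[, j])
      if (abs(scores[i, j] - mu) > 5 * sdj) hit <- TRUE
    }
    if (hit) brute <- c(brute, rownames(scores)[i])
  }
  expect_identical(sort(got), sort(brute))
  expect_true("s007" %in% got)
  # monotone shrinking in the threshold; infinite threshold flags nothing
  expect_true(all(pc_outliers(scores, 3, 6) %in% got))
  expect_length(pc_outliers(scores, 3, 1e9), 0)
})

test_that("outlier value handling: winsorize, to_na, leave", {
  m <- cbind(f1 = c(1:9, 100))
  rownames(m) <- paste0("s", 1:10)
  fl <- outlier_flags(m, 5)$flags
  expect_equal(unname(handle_outlier_values(m, fl, "winsorize")[10, 1]), 9)
  expect_identical(handle_outlier_values(m, fl, "leave"), m)
  na_m <- handle_outlier_values(m, fl, "to_na")
  expect_true(is.na(na_m[10, 1]))
  # to_na then impute: flagged cell becomes the feature median
  xs <- impute_standardize(na_m)
  imputed <- na_m
  imputed[10, 1] <- median(na_m[1:9, 1])
  expect_equal(unname(xs[, 1]), unname(scale(imputed[, 1])[, 1]))
})

test_that("a sample shifted +10 feature SDs everywhere is a PC outlier", {
  fx <- generate_fixture(n_samples = 200, n_features = 30, n_blocks = 3,
                         batch_count = 1, n_xenobiotics = 2, n_derived = 2,
                         n_highmiss_samples = 0, n_outlier_samples = 0,
                         n_pc_outlier_samples = 0, n_outlier_cells = 0,
                         seed = 77)
  m <- fx$matrix
  sds <- apply(m, 2, sd, na.rm = TRUE)
  m["S001", ] <- colMeans(m, na.rm = TRUE) + 10 * sds
  cfg <- default_config()
  ids <- eligible_features(m, fx$annotation, cfg)
  cl <- cluster_features(m, ids, 0.5)
  xs <- impute_standardize(m, cl$representatives)
  p <- run_pca(xs)
  n <- acceleration_factor_n(p$eigenvalues)
  expect_true("S001" %in% pc_outliers(p$scores, n, 5))
})
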