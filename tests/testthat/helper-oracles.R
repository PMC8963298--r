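# Shared helpers: a seeded random abundance matrix and independent
# brute-force oracles (explicit per-cell loops, no shared code with the
# implementation) used to validate the vectorized statistics.

rand_abundance <- function(n = 20, p = 10, miss_rate = 0.15, seed = 42) {
  set.seed(seed)
  m <- matrix(exp(rnorm(n * p, 3, 0.5)), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  if (miss_rate > 0) m[runif(n * p) < miss_rate] <- NA
  # keep every feature with at least 3 observed values
  for (j in 1:p) {
    obs <- which(!is.na(m[, j]))
    if (length(obs) < 3) m[1:3, j] <- exp(rnorm(3, 3, 0.5))
  }
  m
}

oracle_sample_missingness <- function(m, excluded = character()) {
  keep <- setdiff(colnames(m), excluded)
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    n_miss <- 0
    for (f in keep) if (is.na(m[i, f])) n_miss <- n_miss + 1
    out[i] <- n_miss / length(keep)
  }
  names(out) <- rownames(m)
  out
}

oracle_feature_missingness <- function(m) {
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    n_miss <- 0
    for (i in seq_len(nrow(m))) if (is.na(m[i, j])) n_miss <- n_miss + 1
    out[j] <- n_miss / nrow(m)
  }
  names(out) <- colnames(m)
  out
}

oracle_tsa <- function(m, complete_only = FALSE, excluded = character()) {
  keep <- setdiff(colnames(m), excluded)
  if (complete_only)
    keep <- keep[vapply(keep, function(f) !anyNA(m[, f]), logical(1))]
  keep <- keep[vapply(keep, function(f) {
    v <- m[, f][!is.na(m[, f])]
    length(v) >= 2 && sd(v) > 0
  }, logical(1))]
  z <- m[, keep, drop = FALSE]
  for (f in keep) {
    v <- z[, f]
    z[, f] <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  shift <- abs(min(z, na.rm = TRUE))
  out <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    s <- 0; seen <- 0
    for (f in keep) if (!is.na(z[i, f])) { s <- s + z[i, f] + shift; seen <- seen + 1 }
    out[i] <- if (seen) s else NA_real_
  }
  names(out) <- rownames(m)
  out
}

oracle_outlier_counts <- function(m, k = 5) {
  sc <- integer(nrow(m)); fc <- integer(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j][!is.na(m[, j])]
    med <- median(v)
    iqr <- unname(quantile(v, 0.75, type = 7) - quantile(v, 0.25, type = 7))
    for (i in seq_len(nrow(m))) {
      x <- m[i, j]
      if (!is.na(x) && abs(x - med) > k * iqr) {
        sc[i] <- sc[i] + 1L
        fc[j] <- fc[j] + 1L
      }
    }
  }
  list(sample_counts = sc, feature_counts = fc)
}

oracle_descriptives <- function(m) {
  t(vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j][!is.na(m[, j])]
    n <- length(v)
    mu <- mean(v)
    s <- if (n >= 2) sqrt(sum((v - mu)^2) / (n - 1)) else NA_real_
    sk <- if (n >= 3 && sum((v - mu)^2) > 0) {
      m2 <- sum((v - mu)^2) / n
      m3 <- sum((v - mu)^3) / n
      (m3 / m2^1.5) * sqrt(n * (n - 1)) / (n - 2)
    } else NA_real_
    c(n = n, mean = mu, sd = s, skew = sk,
      cv = if (!is.na(s) && mu != 0) s / mu else NA_real_)
  }, numeric(5)))
}

oracle_eta2 <- function(y, g) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- as.character(g[keep])
  gm <- mean(y)
  ssb <- 0
  for (lev in unique(g)) {
    yl <- y[g == lev]
    ssb <- ssb + length(yl) * (mean(yl) - gm)^2
  }
  ssb / sum((y - gm)^2)
}

demo_path <- function(...) {
  system.file("extdata", "demo", ..., package = "metabscreen")
}
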