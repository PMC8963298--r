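# Power analysis for planned downstream tests, used to illustrate the
# power cost of missing data (smaller effective n). Closed forms via the
# noncentral t and F distributions.

#' Power of a two-sided two-sample t-test
#'
#' Noncentral-t closed form with noncentrality d * sqrt(n1 n2 / (n1 + n2))
#' and n1 + n2 - 2 degrees of freedom; unequal group sizes allowed.
#'
#' @param n1,n2 group sample sizes (>= 2).
#' @param d standardized mean difference (Cohen's d, >= 0); vectorized.
#' @param alpha two-sided significance level.
#' @return power in \[alpha, 1\].
#' @export
power_binary <- function(n1, n2, d, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, all(d >= 0), alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp)
}

#' Power of a general-linear-model F-test
#'
#' Noncentral-F closed form for a regression with `k_predictors` terms and
#' Cohen's f2 effect size: noncentrality f2 * n, with (k, n - k - 1)
#' degrees of freedom.
#'
#' @param n total sample size (> k_predictors + 1); vectorized.
#' @param f2 Cohen's f-squared (>= 0); vectorized.
#' @param alpha significance level.
#' @param k_predictors number of model predictors (default 1).
#' @return power in \[alpha, 1\].
#' @export
power_continuous <- function(n, f2, alpha = 0.05, k_predictors = 1) {
  stopifnot(all(n > k_predictors + 1), all(f2 >= 0), alpha > 0, alpha < 1)
  df1 <- k_predictors
  df2 <- n - k_predictors - 1
  ncp <- f2 * n
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = ncp, lower.tail = FALSE)
}

#' Power curves across observed missingness
#'
#' Evaluates both power calculations over a fixed effect-size grid at
#' effective sample sizes n_eff = `sample_n` * (1 - q), for q at the
#' quantiles of the observed per-feature missingness distribution. This
#' shows the power loss implied by analyzing features with differing
#' degrees of missing data.
#'
#' @param sample_n number of samples in the dataset.
#' @param missingness observed per-feature missingness fractions.
#' @param alpha significance level.
#' @param probs quantile probabilities of the missingness distribution
#'   (default 0, .25, .5, .75, 1).
#' @return data.frame with columns `kind` ("binary" or "continuous"),
#'   `effect`, `miss_quantile`, `missingness`, `n_eff`, `power`; one row
#'   per effect x quantile cell for each kind.
#' @export
power_grid_for_missingness <- function(sample_n, missingness, alpha = 0.05,
                                       probs = c(0, 0.25, 0.5, 0.75, 1)) {
  q <- stats::quantile(missingness[!is.na(missingness)], probs, type = 7)
  n_eff <- pmax(4, round(sample_n * (1 - q)))
  d_grid <- seq(0.1, 1.0, by = 0.1)
  f2_grid <- c(0.005, 0.01, 0.02, 0.05, 0.1, 0.2)
  rows <- list()
  for (i in seq_along(q)) {
    n1 <- floor(n_eff[i] / 2)
    n2 <- n_eff[i] - n1
    rows[[length(rows) + 1]] <- data.frame(
      kind = "binary", effect = d_grid,
      miss_quantile = probs[i], missingness = unname(q[i]),
      n_eff = n_eff[i],
      power = power_binary(n1, n2, d_grid, alpha),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      kind = "continuous", effect = f2_grid,
      miss_quantile = probs[i], missingness = unname(q[i]),
      n_eff = n_eff[i],
      power = power_continuous(n_eff[i], f2_grid, alpha),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
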