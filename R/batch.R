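# Batch-effect quantification: how much variance in sample-level QC
# metrics (missingness, TSA) is attributable to technical batch variables,
# summarized by eta-squared from one-way and multi-term type-II ANOVA.

as_batch_factor <- function(x, name = "batch variable") {
  if (is.numeric(x))
    stop(name, " is continuous; batch variables must be categorical ",
         "(recode or bin it first)")
  f <- droplevels(as.factor(x))
  f
}

#' Univariate eta-squared
#'
#' One-way ANOVA of `outcome` on a categorical `batch` variable;
#' eta-squared is SS_between / SS_total, the proportion of outcome
#' variance explained by the batch.
#'
#' @param outcome numeric vector, one value per sample.
#' @param batch categorical vector of the same length.
#' @return eta-squared in \[0,1\]; NA with a warning when the outcome is
#'   constant.
#' @export
univariate_eta2 <- function(outcome, batch) {
  keep <- !is.na(outcome) & !is.na(batch)
  y <- outcome[keep]
  g <- as_batch_factor(batch[keep])
  if (nlevels(g) < 2) stop("need at least 2 batch groups")
  if (stats::var(y) == 0) {
    warning("constant outcome: eta-squared undefined")
    return(NA_real_)
  }
  tab <- stats::anova(stats::aov(y ~ g))
  ss <- tab[["Sum Sq"]]
  ss[1] / sum(ss)
}

#' Type-II eta-squared per batch term
#'
#' Fits an additive linear model of the outcome on several categorical
#' batch variables and computes, for each term, the type-II sum of squares
#' RSS(model without the term) - RSS(full model), scaled by the total sum
#' of squares. Samples with any missing batch value are dropped listwise.
#' Terms that are completely aliased with earlier ones (e.g. a duplicated
#' variable) are flagged NA with a warning.
#'
#' @param outcome numeric vector, one value per sample.
#' @param batch_variables data.frame of categorical variables (same row
#'   count).
#' @return named numeric vector of eta-squared values, NA for inestimable
#'   terms.
#' @export
type2_eta2 <- function(outcome, batch_variables) {
  stopifnot(is.data.frame(batch_variables),
            nrow(batch_variables) == length(outcome))
  keep <- !is.na(outcome) & stats::complete.cases(batch_variables)
  y <- outcome[keep]
  d <- batch_variables[keep, , drop = FALSE]
  for (j in seq_along(d)) d[[j]] <- as_batch_factor(d[[j]], names(d)[j])
  terms <- names(d)
  dat <- cbind(data.frame(.y = y), d)
  full <- stats::lm(.y ~ ., data = dat)
  ss_total <- sum((y - mean(y))^2)
  if (ss_total == 0) {
    warning("constant outcome: eta-squared undefined")
    return(stats::setNames(rep(NA_real_, length(terms)), terms))
  }
  rss_full <- sum(stats::residuals(full)^2)
  # map aliased (NA) coefficients back to their terms
  asg <- attr(stats::model.matrix(full), "assign")
  coef_na <- is.na(stats::coef(full))
  aliased <- vapply(seq_along(terms), function(i) {
    cols <- which(asg == i)
    length(cols) > 0 && all(coef_na[cols])
  }, logical(1))
  out <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (i in seq_along(terms)) {
    if (aliased[i]) next
    red <- stats::lm(stats::reformulate(terms[-i], response = ".y"),
                     data = dat)
    if (length(terms) == 1)
      red <- stats::lm(.y ~ 1, data = dat)
    ss_term <- sum(stats::residuals(red)^2) - rss_full
    out[i] <- max(0, ss_term) / ss_total
  }
  if (any(aliased))
    warning("aliased term(s) flagged inestimable: ",
            paste(terms[aliased], collapse = ", "))
  out
}

#' Batch-effect summary table
#'
#' For each QC outcome (sample missingness and TSA at complete features)
#' and each batch variable, the univariate eta-squared and group count;
#' plus, per outcome, the multi-term type-II eta-squared with all batch
#' variables entered together.
#'
#' @param sample_stats data.frame from [sample_summary()].
#' @param meta sample metadata data.frame with `sample_id`.
#' @param variables metadata column names to analyze.
#' @return data.frame: `outcome`, `variable`, `n_groups`,
#'   `eta2_univariate`, `eta2_type2`.
#' @export
batch_effects <- function(sample_stats, meta, variables) {
  stopifnot(all(variables %in% names(meta)))
  idx <- match(sample_stats$sample_id, meta$sample_id)
  outcomes <- list(missingness = sample_stats$missingness_excl,
                   tsa_complete = sample_stats$tsa_complete)
  rows <- list()
  for (oname in names(outcomes)) {
    y <- outcomes[[oname]]
    e2_multi <- tryCatch(
      type2_eta2(y, meta[idx, variables, drop = FALSE]),
      warning = function(w) suppressWarnings(
        type2_eta2(y, meta[idx, variables, drop = FALSE])),
      error = function(e) stats::setNames(rep(NA_real_, length(variables)),
                                          variables))
    for (v in variables) {
      g <- meta[[v]][idx]
      e2 <- tryCatch(suppressWarnings(univariate_eta2(y, g)),
                     error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oname, variable = v,
        n_groups = nlevels(droplevels(as.factor(g[!is.na(g)]))),
        eta2_univariate = e2,
        eta2_type2 = unname(e2_multi[v]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
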