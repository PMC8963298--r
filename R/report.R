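# Rendering of the standardized HTML report and the per-feature plot
# document. This module is pure presentation: every number displayed comes
# from summary tables computed elsewhere; nothing is recomputed here
# except cosmetic aids (the seeded k-means coloring of the PC plot).

# Overwrite the embedded creation/modification timestamps of a PDF with a
# fixed same-length placeholder so re-runs are byte-identical. The
# replacement preserves byte offsets, leaving the xref table valid.
scrub_pdf_dates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^(/(Creation|Mod)Date \\(D:)[0-9]{14}\\)",
               "\\100000000000000)", lines, useBytes = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# Render a base plot expression to an inlined <img> tag (base64 PNG), so
# the report is a single self-contained file.
fig_b64 <- function(expr, width = 720, height = 480, res = 96) {
  path <- tempfile(fileext = ".png")
  grDevices::png(path, width = width, height = height, res = res,
                 type = "cairo")
  ok <- tryCatch({ expr; TRUE },
                 error = function(e) FALSE,
                 finally = grDevices::dev.off())
  if (!ok || !file.exists(path)) return(NULL)
  b64 <- jsonlite::base64_enc(readBin(path, "raw", file.size(path)))
  unlink(path)
  sprintf('<img src="data:image/png;base64,%s" alt="figure"/>',
          gsub("\n", "", b64))
}

html_section <- function(id, title, body) {
  if (is.null(body) || !length(body) || !nzchar(paste(body, collapse = "")))
    body <- '<p class="placeholder">not available</p>'
  sprintf('<section id="%s">\n<h2>%s</h2>\n%s\n</section>', id, title,
          paste(body, collapse = "\n"))
}

html_table <- function(d, digits = 4) {
  if (is.null(d) || !nrow(d)) return(NULL)
  fmt <- function(v) {
    if (is.numeric(v)) vapply(v, function(x)
      if (is.na(x)) "NA" else trimws(formatC(x, digits = digits,
                                             format = "g")),
      character(1))
    else as.character(v)
  }
  cells <- vapply(d, fmt, character(nrow(d)))
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = nrow(d))
  head <- paste0("<tr>", paste0("<th>", names(d), "</th>", collapse = ""),
                 "</tr>")
  rows <- apply(cells, 1, function(r)
    paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>"))
  paste0("<table>", head, paste(rows, collapse = ""), "</table>")
}

num_or <- function(x, alt = "n/a") {
  if (is.null(x) || !length(x) || is.na(x)) alt else format(x)
}

#' Render the standardized HTML report
#'
#' Produces a single self-contained HTML file (all figures inlined as
#' base64 PNG) summarizing the run: missingness structure, exclusion
#' summary, feature reduction dendrogram, scree plot with both component-
#' retention estimates, PC plot with a purely cosmetic seeded 4-group
#' k-means coloring, TSA distribution, Shapiro-W histograms, outlier
#' summaries, batch-effect boxplots with eta-squared annotations, power
#' curves and a configuration echo. Missing inputs render as "not
#' available" placeholders rather than failing.
#'
#' @param results list as returned by [run_pipeline()] (fields may be
#'   NULL).
#' @param outpath path of the HTML file to write.
#' @return `outpath`, invisibly.
#' @export
render_report <- function(results, outpath) {
  r <- results
  cfg <- r$config
  secs <- character()

  secs <- c(secs, html_section("header", "Project", paste0(
    "<p>Project: <b>", num_or(cfg$project_name), "</b><br/>",
    "Platform: <b>", num_or(cfg$platform), "</b><br/>",
    "Raw data: <b>",
    if (!is.null(r$raw_matrix))
      paste(nrow(r$raw_matrix), "samples x", ncol(r$raw_matrix), "features")
    else "n/a",
    "</b>; filtered data: <b>",
    if (!is.null(r$filtered_matrix))
      paste(nrow(r$filtered_matrix), "samples x", ncol(r$filtered_matrix),
            "features")
    else "n/a", "</b></p>")))

  secs <- c(secs, html_section("missingness-matrix", "Missingness matrix",
    if (!is.null(r$raw_matrix)) fig_b64({
      na <- t(is.na(r$raw_matrix))[, rev(seq_len(nrow(r$raw_matrix))),
                                   drop = FALSE]
      graphics::image(seq_len(nrow(na)), seq_len(ncol(na)), na + 0,
                      col = c("grey90", "firebrick"), xlab = "features",
                      ylab = "samples", main = "missing entries (red)",
                      useRaster = TRUE)
    })))

  secs <- c(secs, html_section("missingness-distributions",
    "Missingness distributions",
    if (!is.null(r$raw_sample_summary) && !is.null(r$raw_feature_summary))
      fig_b64({
        graphics::par(mfrow = c(1, 2))
        graphics::hist(r$raw_sample_summary$missingness_excl, breaks = 30,
                       col = "steelblue", main = "sample missingness",
                       xlab = "fraction missing")
        graphics::hist(r$raw_feature_summary$missingness, breaks = 30,
                       col = "steelblue", main = "feature missingness",
                       xlab = "fraction missing")
      })))

  secs <- c(secs, html_section("exclusion-summary", "Exclusion summary",
    if (!is.null(r$exclusion_log))
      html_table(r$exclusion_log[, c("step", "name", "entity", "threshold",
                                     "n_before", "n_removed", "n_after")])))

  cl <- r$clustering
  secs <- c(secs, html_section("dendrogram", "Feature reduction dendrogram",
    if (!is.null(cl)) c(fig_b64({
      graphics::plot(cl$hclust, labels = FALSE, hang = -1,
                     main = sprintf("%d features, k = %d clusters",
                                    length(cl$ids), cl$k),
                     xlab = "", sub = "", ylab = "1 - |Spearman rho|")
      graphics::abline(h = cfg$tree_cut_height, col = "red", lty = 2)
      at <- match(cl$representatives, cl$ids[cl$hclust$order])
      graphics::points(at, rep(0, length(at)), pch = 17, col = "blue")
    }, height = 420),
    sprintf("<p>Representative (blue) features: %d — the effective number of features.</p>",
            length(cl$representatives)))))

  pca <- r$pca
  secs <- c(secs, html_section("scree", "Scree plot",
    if (!is.null(pca)) fig_b64({
      ve <- pca$variance_explained
      graphics::barplot(100 * ve, names.arg = seq_along(ve),
                        col = "grey70", xlab = "principal component",
                        ylab = "% variance explained")
      if (!is.null(r$n_accel))
        graphics::abline(v = r$n_accel * 1.2 - 0.5, col = "red", lwd = 2)
      if (!is.null(r$n_parallel) && r$n_parallel >= 1)
        graphics::abline(v = r$n_parallel * 1.2 - 0.5, col = "darkgreen",
                         lwd = 2, lty = 2)
      graphics::legend("topright", lwd = 2, lty = c(1, 2),
                       col = c("red", "darkgreen"),
                       legend = c(paste("acceleration factor:",
                                        num_or(r$n_accel)),
                                  paste("parallel analysis:",
                                        num_or(r$n_parallel))))
    })))

  secs <- c(secs, html_section("pc-plot", "Principal components",
    if (!is.null(pca) && ncol(pca$scores) >= 2) fig_b64({
      sc <- pca$scores[, 1:2]
      km <- with_seed(cfg$rng_seed, stats::kmeans(sc, centers = 4,
                                                  nstart = 5))
      cols <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a")[km$cluster]
      graphics::plot(sc, col = cols, pch = 19, cex = 0.8,
                     xlab = sprintf("PC1 (%.1f%%)",
                                    100 * pca$variance_explained[1]),
                     ylab = sprintf("PC2 (%.1f%%)",
                                    100 * pca$variance_explained[2]),
                     main = sprintf("PCA of %d representative features (k-means coloring is cosmetic)",
                                    ncol(pca$rotation)))
      if (!is.null(r$pc_outlier_ids) && length(r$pc_outlier_ids)) {
        out <- rownames(sc) %in% r$pc_outlier_ids
        graphics::points(sc[out, , drop = FALSE], pch = 1, cex = 2,
                         col = "red", lwd = 2)
      }
    })))

  secs <- c(secs, html_section("tsa", "Total sum abundance",
    if (!is.null(r$raw_sample_summary) &&
        any(!is.na(r$raw_sample_summary$tsa_complete))) fig_b64({
      graphics::hist(r$raw_sample_summary$tsa_complete, breaks = 40,
                     col = "darkseagreen",
                     main = "TSA at complete features", xlab = "TSA")
    })))

  secs <- c(secs, html_section("shapiro", "Normality (Shapiro W)",
    if (!is.null(r$raw_feature_summary)) fig_b64({
      graphics::par(mfrow = c(1, 2))
      graphics::hist(r$raw_feature_summary$w_raw, breaks = 20,
                     col = "thistle", xlim = c(0, 1),
                     main = "W, raw scale", xlab = "W")
      graphics::hist(r$raw_feature_summary$w_log10, breaks = 20,
                     col = "thistle", xlim = c(0, 1),
                     main = "W, log10 scale", xlab = "W")
    })))

  secs <- c(secs, html_section("outliers", "Outlier summary",
    if (!is.null(r$raw_sample_summary)) {
      oc <- r$raw_sample_summary$outlier_count
      fc <- r$raw_feature_summary$outlier_count
      paste0("<p>Outlying data points per sample (min/median/max): ",
             min(oc), " / ", stats::median(oc), " / ", max(oc),
             "; per feature: ",
             if (!is.null(fc)) paste(min(fc), "/", stats::median(fc), "/",
                                     max(fc)) else "n/a", "</p>")
    }))

  be <- r$batch_effects
  secs <- c(secs, html_section("batch", "Batch effects",
    if (!is.null(be) && nrow(be) && !is.null(r$meta)) {
      figs <- html_table(be)
      vars <- unique(be$variable)
      idx <- match(r$raw_sample_summary$sample_id, r$meta$sample_id)
      for (v in vars) {
        e2 <- be$eta2_univariate[be$outcome == "tsa_complete" &
                                   be$variable == v]
        figs <- c(figs, fig_b64({
          graphics::par(mfrow = c(1, 2))
          graphics::boxplot(
            r$raw_sample_summary$missingness_excl ~ r$meta[[v]][idx],
            col = "lightsteelblue", xlab = v, ylab = "sample missingness",
            main = sprintf("missingness ~ %s (eta2 = %s)", v,
                           num_or(signif(be$eta2_univariate[
                             be$outcome == "missingness" &
                               be$variable == v], 3))))
          graphics::boxplot(
            r$raw_sample_summary$tsa_complete ~ r$meta[[v]][idx],
            col = "lightsteelblue", xlab = v, ylab = "TSA (complete)",
            main = sprintf("TSA ~ %s (eta2 = %s)", v,
                           num_or(signif(e2, 3))))
        }, height = 360))
      }
      figs
    }))

  pg <- r$power_grid
  secs <- c(secs, html_section("power", "Power analysis",
    if (!is.null(pg) && nrow(pg)) fig_b64({
      graphics::par(mfrow = c(1, 2))
      for (kind in c("binary", "continuous")) {
        sub <- pg[pg$kind == kind, ]
        qs <- sort(unique(sub$miss_quantile))
        cols <- grDevices::hcl.colors(length(qs), "viridis")
        graphics::plot(NULL, xlim = range(sub$effect), ylim = c(0, 1),
                       xlab = if (kind == "binary") "effect size d"
                              else "effect size f2",
                       ylab = "power",
                       main = sprintf("%s outcome (n = %d)", kind,
                                      max(sub$n_eff)))
        for (i in seq_along(qs)) {
          s <- sub[sub$miss_quantile == qs[i], ]
          graphics::lines(s$effect, s$power, col = cols[i], lwd = 2)
        }
        graphics::legend("bottomright", lwd = 2, col = cols, cex = 0.7,
                         legend = sprintf("missingness q%.2f (n=%d)", qs,
                                          vapply(qs, function(q)
                                            max(sub$n_eff[sub$miss_quantile == q]),
                                            numeric(1))))
      }
    })))

  cfg_show <- cfg[setdiff(names(cfg), NULL)]
  secs <- c(secs, html_section("config", "Configuration echo",
    html_table(data.frame(parameter = names(cfg_show),
                          value = vapply(cfg_show, function(v)
                            paste(format(v), collapse = ","), character(1)),
                          stringsAsFactors = FALSE, row.names = NULL))))

  html <- c("<!DOCTYPE html>",
            "<html><head><meta charset=\"utf-8\"/>",
            "<title>metabscreen report</title>",
            "<style>body{font-family:sans-serif;max-width:1000px;margin:auto}",
            "table{border-collapse:collapse}td,th{border:1px solid #ccc;padding:3px 8px}",
            ".placeholder{color:#888;font-style:italic}</style></head><body>",
            "<h1>metabscreen pre-analysis data report</h1>",
            secs, "</body></html>")
  writeLines(html, outpath)
  invisible(outpath)
}

#' Render the per-feature plot document
#'
#' Writes a multipage PDF with one page per feature: an index-ordered
#' scatter plot with flagged outlier values marked, a histogram of the
#' same values and a panel of selected summary statistics. All-missing
#' features get a placeholder page.
#'
#' @param matrix samples x features abundance matrix.
#' @param feature_stats data.frame from [feature_summary()].
#' @param outpath path of the PDF to write.
#' @param k IQR multiplier used to mark outlying points (default 5).
#' @return number of pages written, invisibly.
#' @export
render_feature_document <- function(matrix, feature_stats, outpath, k = 5) {
  validate_abundance(matrix)
  flags <- outlier_flags(matrix, k)$flags
  grDevices::pdf(outpath, width = 9, height = 4.5, onefile = TRUE)
  on.exit({
    grDevices::dev.off()
    scrub_pdf_dates(outpath)
  })
  for (j in seq_len(ncol(matrix))) {
    fid <- colnames(matrix)[j]
    v <- matrix[, j]
    st <- feature_stats[feature_stats$feature_id == fid, , drop = FALSE]
    if (all(is.na(v))) {
      graphics::plot.new()
      graphics::title(main = fid)
      graphics::text(0.5, 0.5, "all values missing")
      next
    }
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
    cols <- ifelse(flags[, j], "red", "grey30")
    graphics::plot(seq_along(v), v, col = cols, pch = 19, cex = 0.7,
                   xlab = "sample index", ylab = "abundance", main = fid)
    graphics::hist(v[!is.na(v)], breaks = 30, col = "grey80",
                   main = "", xlab = "abundance")
    if (nrow(st)) {
      lab <- sprintf(
        "n=%s  miss=%s  mean=%s  sd=%s\nskew=%s  W=%s  W(log10)=%s  outliers=%s",
        st$n, signif(st$missingness, 3), signif(st$mean, 4),
        signif(st$sd, 4), signif(st$skew, 3), signif(st$w_raw, 3),
        signif(st$w_log10, 3), st$outlier_count)
      graphics::mtext(lab, side = 3, line = -0.5, cex = 0.7)
    }
  }
  invisible(ncol(matrix))
}
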