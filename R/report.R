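#' Per-variant overlap statistics table
#'
#' Summarizes subject-level overlaps per variant with the five cohort
#' statistics — mean, SD, median, minimum, maximum — reported in
#' percent.
#'
#' @param overlaps data.frame with columns `subject`, `variant`,
#'   `overlap` (in `[0, 1]`, `NA` for undefined).
#' @return A data.frame with columns `variant`, `mean_pct`, `sd_pct`,
#'   `median_pct`, `min_pct`, `max_pct`, `n`.
#' @export
overlap_stats <- function(overlaps) {
  stopifnot(all(c("subject", "variant", "overlap") %in% names(overlaps)))
  rows <- lapply(unique(overlaps$variant), function(v) {
    o <- overlaps$overlap[overlaps$variant == v]
    o <- o[!is.na(o)]
    data.frame(variant = v,
               mean_pct = 100 * mean(o),
               sd_pct = 100 * sd(o),
               median_pct = 100 * median(o),
               min_pct = 100 * min(o),
               max_pct = 100 * max(o),
               n = length(o))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the full robustness report
#'
#' Aggregates the study's result artifacts from a feature matrix and a
#' subject-level overlap table: per-variant overlap statistics, the
#' per-feature per-variant ICC table (sorted descending per variant for
#' curve plotting), counts of features above the agreement thresholds,
#' the cross-variant robustness ranking, and ICC distributions split by
#' feature category (intensity vs texture). Optionally serializes
#' everything as CSV + JSON (and diagnostic plots) into a directory.
#'
#' @param features a `feature_matrix` (see [extract_feature_matrix()]).
#' @param overlaps data.frame `subject`/`variant`/`overlap` rows
#'   (see [overlap_stats()]); may be `NULL` to skip overlap tables.
#' @param reference_label reference variant name; default
#'   `"reference"`.
#' @param thresholds ICC thresholds; default `c(0.6, 0.7, 0.8, 0.9)`.
#' @param out_dir if non-`NULL`, directory to serialize the report into.
#' @param plots write PDF plots (ICC curves with the 0.7 crossing
#'   marked, overlap histograms, category boxplots) when serializing.
#' @return An object of class `robustness_report`: list with
#'   `overlap_stats`, `icc_table`, `icc_curves`, `threshold_counts`,
#'   `ranking`, `category_distributions`, `config`.
#' @export
build_report <- function(features, overlaps = NULL,
                         reference_label = "reference",
                         thresholds = c(0.6, 0.7, 0.8, 0.9),
                         out_dir = NULL, plots = FALSE) {
  icc_table <- feature_icc_table(features, reference_label)
  counts <- threshold_counts(icc_table, thresholds)
  ranking <- rank_features(icc_table)
  curves <- lapply(split(icc_table, icc_table$variant), function(sub) {
    sub <- sub[!sub$undefined & !is.na(sub$icc), ]
    sub[order(-sub$icc, sub$feature), c("feature", "category", "icc")]
  })
  catdist <- icc_table[!icc_table$undefined & !is.na(icc_table$icc),
                       c("variant", "category", "icc")]
  rep <- structure(list(
    overlap_stats = if (!is.null(overlaps)) overlap_stats(overlaps) else NULL,
    icc_table = icc_table,
    icc_curves = curves,
    threshold_counts = counts,
    ranking = ranking,
    category_distributions = catdist,
    config = list(reference_label = reference_label,
                  thresholds = thresholds,
                  bank_size = nrow(feature_bank()))),
    class = "robustness_report")
  if (!is.null(out_dir)) write_report(rep, out_dir, overlaps = overlaps,
                                      plots = plots)
  rep
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  if (!is.null(x$overlap_stats)) {
    cat("  overlap (%% of reference):\n")
    print(x$overlap_stats, digits = 4)
  }
  cat("  features above thresholds:\n")
  print(x$threshold_counts)
  invisible(x)
}

#' Serialize a robustness report
#'
#' Writes `overlap_stats.csv`, `icc_table.csv`, `threshold_counts.csv`,
#' `ranking.csv`, a `summary.json`, and (optionally) `plots.pdf` into
#' `out_dir`.
#'
#' @param report a `robustness_report`.
#' @param out_dir output directory (created if absent).
#' @param overlaps optional subject-level overlap rows, serialized as
#'   `overlaps.csv`.
#' @param plots write `plots.pdf`.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, overlaps = NULL, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$overlap_stats))
    write.csv(report$overlap_stats,
              file.path(out_dir, "overlap_stats.csv"), row.names = FALSE)
  if (!is.null(overlaps))
    write.csv(overlaps, file.path(out_dir, "overlaps.csv"),
              row.names = FALSE)
  write.csv(report$icc_table, file.path(out_dir, "icc_table.csv"),
            row.names = FALSE)
  write.csv(report$threshold_counts,
            file.path(out_dir, "threshold_counts.csv"), row.names = FALSE)
  write.csv(report$ranking, file.path(out_dir, "ranking.csv"),
            row.names = FALSE)
  summary <- list(
    config = report$config,
    threshold_counts = report$threshold_counts,
    overlap_stats = report$overlap_stats,
    top_features = head(report$ranking$feature, 10))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (plots) plot_report(report, file.path(out_dir, "plots.pdf"),
                         overlaps = overlaps)
  invisible(out_dir)
}

#' @rdname write_report
#' @param path PDF path for the diagnostic plots.
#' @export
plot_report <- function(report, path, overlaps = NULL) {
  grDevices::pdf(path, width = 8, height = 6)
  on.exit(grDevices::dev.off(), add = TRUE)
  # ICC curves, features sorted descending, 0.7 crossing marked
  curves <- report$icc_curves
  if (length(curves)) {
    graphics::plot(NULL, xlim = c(1, max(vapply(curves, nrow, 1L))),
                   ylim = c(0, 1), xlab = "feature rank (per variant)",
                   ylab = "ICC (A-1)", main = "Feature agreement curves")
    cols <- grDevices::rainbow(length(curves))
    for (i in seq_along(curves)) {
      cv <- curves[[i]]
      graphics::lines(seq_len(nrow(cv)), cv$icc, col = cols[i])
      cross <- sum(cv$icc > 0.7)
      if (cross > 0)
        graphics::points(cross, cv$icc[cross], pch = 19, col = cols[i])
    }
    graphics::abline(h = 0.7, lty = 2, col = "grey40")
    graphics::legend("bottomleft", legend = names(curves), col = cols,
                     lty = 1, cex = 0.7)
  }
  if (!is.null(overlaps)) {
    for (v in unique(overlaps$variant)) {
      o <- overlaps$overlap[overlaps$variant == v]
      graphics::hist(100 * o[!is.na(o)], breaks = 20,
                     main = paste("Overlap with reference:", v),
                     xlab = "overlap (%)", xlim = c(0, 100))
    }
  }
  cd <- report$category_distributions
  if (nrow(cd)) {
    for (categ in unique(cd$category)) {
      sub <- cd[cd$category == categ, ]
      graphics::boxplot(icc ~ variant, data = sub,
                        main = paste("ICC distribution:", categ),
                        ylab = "ICC (A-1)", las = 2, cex.axis = 0.7)
      graphics::abline(h = 0.7, lty = 2, col = "grey40")
    }
  }
  invisible(path)
}
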