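#' Multi-VOI overlap (intersection over union)
#'
#' Agreement between k VOIs on a shared grid: the ratio of the voxel
#' count of their intersection to that of their union,
#' `O_k = |VOI_1 n ... n VOI_k| / |VOI_1 u ... u VOI_k|`. The ratio is
#' an exact integer-count quotient, lies in `[0, 1]`, is invariant
#' under permutation of the inputs, and equals 1 iff all VOIs are
#' identical (given a non-empty union).
#'
#' @param vois list of two or more [voi_mask()]s on identical grids.
#' @return An object of class `overlap_result` with `o` (the ratio),
#'   `k`, `n_intersection`, `n_union`, and `undefined` (`TRUE` when the
#'   union is empty, in which case `o` is `NA`).
#' @examples
#' a <- voi_mask(array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
#' b <- voi_mask(array(c(rep(FALSE, 2), rep(TRUE, 4), FALSE, FALSE),
#'                     c(2, 2, 2)))
#' overlap(list(a, b))$o  # 2 / 6
#' @export
overlap <- function(vois) {
  stopifnot(is.list(vois), length(vois) >= 2L)
  for (v in vois) stopifnot(inherits(v, "voi_mask"))
  for (v in vois[-1]) check_geometry(v, vois[[1]], what = "overlap input")
  inter <- vois[[1]]$voxels
  uni <- vois[[1]]$voxels
  for (v in vois[-1]) {
    inter <- inter & v$voxels
    uni <- uni | v$voxels
  }
  n_int <- sum(inter)
  n_uni <- sum(uni)
  structure(list(
    o = if (n_uni > 0) n_int / n_uni else NA_real_,
    k = length(vois),
    n_intersection = n_int,
    n_union = n_uni,
    undefined = n_uni == 0),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("<overlap> O_", x$k, " = ",
      if (x$undefined) "undefined (empty union)" else format(x$o),
      " (", x$n_intersection, "/", x$n_union, " voxels)\n", sep = "")
  invisible(x)
}

#' Intraclass correlation, two-way absolute agreement (A-1)
#'
#' The single-measure absolute-agreement ICC from a two-way crossed
#' layout (also called criterion-referenced reliability): rows are
#' observations (subjects), columns are measurement methods
#' (segmentations). With mean squares for rows `MS_R`, columns `MS_C`
#' and error `MS_E` from the standard two-way decomposition,
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' Unlike the consistency ICC, systematic column shifts (a biased
#' segmentation method) lower the value. Rows containing any missing
#' cell are dropped first (complete-case).
#'
#' @param data numeric n x k matrix (or data.frame), n subjects by k
#'   measurement columns; `NA` cells trigger row dropping.
#' @return An object of class `icc_result`: `icc`, `ms_r`, `ms_c`,
#'   `ms_e`, `n`, `k`, `undefined` and `reason`. A fully constant
#'   matrix has no variance to apportion and is undefined-flagged
#'   (0/0), never reported as agreement.
#' @examples
#' m <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2)
#' icc_a1(m)$icc  # (40/3) / (40/3 + 1)
#' @export
icc_a1 <- function(data) {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("need k >= 2 measurement columns")
  complete <- stats::complete.cases(m)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L)
    stop("need n >= 2 complete rows after complete-case filtering, got ", n)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_r <- k * sum((row_means - grand)^2)
  ss_c <- n * sum((col_means - grand)^2)
  ss_t <- sum((m - grand)^2)
  ss_e <- max(0, ss_t - ss_r - ss_c)
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (ss_t == 0 || denom == 0) {
    return(structure(list(icc = NA_real_, ms_r = ms_r, ms_c = ms_c,
                          ms_e = ms_e, n = n, k = k, undefined = TRUE,
                          reason = "no variance in the measurements (0/0)"),
                     class = "icc_result"))
  }
  structure(list(icc = (ms_r - ms_e) / denom, ms_r = ms_r, ms_c = ms_c,
                 ms_e = ms_e, n = n, k = k, undefined = FALSE,
                 reason = NA_character_),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc A-1> ",
      if (x$undefined) paste0("undefined: ", x$reason) else format(x$icc),
      "  (n = ", x$n, ", k = ", x$k, ")\n", sep = "")
  invisible(x)
}

#' Per-feature, per-variant ICC table
#'
#' For every feature and every variant, computes the A-1 ICC on the
#' n x 2 matrix pairing the reference column with that variant's column
#' (the analysis unit of the robustness study: each variant is compared
#' with the reference separately). Complete-case filtering is applied
#' per feature, so a subject missing one variant only shrinks n for
#' that variant's comparisons.
#'
#' @param features a `feature_matrix` from [extract_feature_matrix()].
#' @param reference_label the variant name of the reference column.
#' @param variant_labels variants to compare against the reference;
#'   default all non-reference variants present.
#' @return A data.frame with columns `feature`, `category`, `variant`,
#'   `icc`, `n_used`, `undefined`, `reason`.
#' @export
feature_icc_table <- function(features, reference_label = "reference",
                              variant_labels = NULL) {
  stopifnot(is.data.frame(features))
  bank <- feature_bank()
  fnames <- intersect(bank$name, names(features))
  if (!length(fnames)) stop("no feature columns found in the matrix")
  if (is.null(variant_labels))
    variant_labels <- setdiff(unique(features$variant), reference_label)
  if (!reference_label %in% features$variant)
    stop("reference label '", reference_label, "' absent from the matrix")
  ref <- features[features$variant == reference_label, , drop = FALSE]
  out <- list()
  for (vlab in variant_labels) {
    var <- features[features$variant == vlab, , drop = FALSE]
    common <- intersect(ref$subject, var$subject)
    rr <- ref[match(common, ref$subject), , drop = FALSE]
    vv <- var[match(common, var$subject), , drop = FALSE]
    for (f in fnames) {
      m <- cbind(rr[[f]], vv[[f]])
      ok <- stats::complete.cases(m)
      cat_f <- bank$category[bank$name == f]
      if (sum(ok) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          feature = f, category = cat_f, variant = vlab, icc = NA_real_,
          n_used = sum(ok), undefined = TRUE,
          reason = "fewer than 2 complete subject rows")
        next
      }
      r <- icc_a1(m[ok, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        feature = f, category = cat_f, variant = vlab, icc = r$icc,
        n_used = r$n, undefined = r$undefined, reason = r$reason)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count features above agreement thresholds
#'
#' For each variant, counts the features whose ICC strictly exceeds
#' each threshold (the conventional reading of "ICC > 0.7 = excellent
#' agreement"). Undefined ICCs are never counted. Counts are reported
#' against the full bank size as `x/94`-style fractions.
#'
#' @param icc_table output of [feature_icc_table()].
#' @param thresholds ascending thresholds; default
#'   `c(0.6, 0.7, 0.8, 0.9)`.
#' @param bank_size denominator for reporting; default the full bank.
#' @return A data.frame with columns `variant`, `threshold`, `count`,
#'   `bank_size`, `label` (e.g. `"84/94"`). Counts are monotone
#'   nonincreasing in the threshold.
#' @export
threshold_counts <- function(icc_table, thresholds = c(0.6, 0.7, 0.8, 0.9),
                             bank_size = nrow(feature_bank())) {
  stopifnot(all(diff(thresholds) > 0))
  out <- expand.grid(variant = unique(icc_table$variant),
                     threshold = thresholds, stringsAsFactors = FALSE)
  out$count <- mapply(function(v, t) {
    sub <- icc_table[icc_table$variant == v & !icc_table$undefined, ]
    sum(sub$icc > t, na.rm = TRUE)
  }, out$variant, out$threshold)
  out$bank_size <- bank_size
  out$label <- sprintf("%d/%d", out$count, bank_size)
  out
}

#' Rank features by robustness across variants
#'
#' Orders features by mean ICC across all variants (the analogue of a
#' most-robust-features list): ties are broken by the minimum ICC
#' across variants, then by feature name, so the ranking is
#' deterministic. A feature undefined in any variant ranks below every
#' fully-defined feature.
#'
#' @param icc_table output of [feature_icc_table()].
#' @return A data.frame with columns `rank`, `feature`, `category`,
#'   `mean_icc`, `min_icc`, `n_variants`, `fully_defined`.
#' @export
rank_features <- function(icc_table) {
  feats <- unique(icc_table$feature)
  rows <- lapply(feats, function(f) {
    sub <- icc_table[icc_table$feature == f, ]
    defined <- !sub$undefined & !is.na(sub$icc)
    data.frame(
      feature = f,
      category = sub$category[1],
      mean_icc = if (any(defined)) mean(sub$icc[defined]) else NA_real_,
      min_icc = if (any(defined)) min(sub$icc[defined]) else NA_real_,
      n_variants = nrow(sub),
      fully_defined = all(defined))
  })
  out <- do.call(rbind, rows)
  # fully-defined features first, then mean desc, min desc, name asc
  ord <- order(!out$fully_defined,
               -ifelse(is.na(out$mean_icc), -Inf, out$mean_icc),
               -ifelse(is.na(out$min_icc), -Inf, out$min_icc),
               out$feature)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "feature", "category", "mean_icc", "min_icc",
          "n_variants", "fully_defined")]
}
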