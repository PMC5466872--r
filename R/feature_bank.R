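#' The default 94-feature intensity + texture bank
#'
#' Registry of the default feature bank: 19 first-order (intensity)
#' features plus five texture families — 24 co-occurrence (GLCM),
#' 16 run-length (GLRLM), 16 size-zone (GLSZM), 14 dependence (GLDM)
#' and 5 neighbourhood gray-tone difference (NGTDM) statistics — for a
#' total of 94 named features. Shape and margin features are
#' deliberately absent: digital biopsies do not delineate the tumour
#' boundary, so boundary-derived features are meaningless for them.
#'
#' @param families character subset of
#'   `c("first_order", "glcm", "glrlm", "glszm", "gldm", "ngtdm")`.
#' @return A data.frame with columns `name`, `family` and `category`
#'   (`"intensity"` for first-order, `"texture"` otherwise).
#' @examples
#' nrow(feature_bank())  # 94
#' table(feature_bank()$category)
#' @export
feature_bank <- function(families = c("first_order", "glcm", "glrlm",
                                      "glszm", "gldm", "ngtdm")) {
  families <- match.arg(families, several.ok = TRUE)
  all <- list(
    first_order = data.frame(name = .FIRST_ORDER_NAMES,
                             family = "first_order",
                             category = "intensity"),
    glcm = data.frame(name = .GLCM_NAMES, family = "glcm",
                      category = "texture"),
    glrlm = data.frame(name = .GLRLM_NAMES, family = "glrlm",
                       category = "texture"),
    glszm = data.frame(name = .GLSZM_NAMES, family = "glszm",
                       category = "texture"),
    gldm = data.frame(name = .GLDM_NAMES, family = "gldm",
                      category = "texture"),
    ngtdm = data.frame(name = .NGTDM_NAMES, family = "ngtdm",
                       category = "texture"))
  out <- do.call(rbind, all[families])
  rownames(out) <- NULL
  out
}

#' Extract the full feature vector of a VOI
#'
#' Runs every family of the feature bank on a volume restricted to a
#' mask: first-order statistics on the raw intensities, texture
#' statistics on the quantized levels. Features that cannot be computed
#' (for instance texture on a single-voxel mask, which has no voxel
#' pairs) are returned as `NA` and flagged in the `undefined`
#' attribute — they are never silently zero, so they propagate as
#' missing into concordance analyses.
#'
#' @param volume a [volume_grid()].
#' @param mask a non-empty [voi_mask()] on the same grid.
#' @param n_levels gray levels for quantization (default 32).
#' @param families families to compute; default all six.
#' @return An object of class `feature_vector`: a named numeric vector
#'   in the registry order with attributes `undefined` (named logical),
#'   `category`, `variant` (the mask label) and `config`.
#' @export
extract_all <- function(volume, mask, n_levels = 32L,
                        families = c("first_order", "glcm", "glrlm",
                                     "glszm", "gldm", "ngtdm")) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "voi_mask"))
  check_geometry(mask, volume)
  if (!any(mask$voxels)) stop("empty mask: no features to extract")
  families <- match.arg(families, several.ok = TRUE)
  bank <- feature_bank(families)
  parts <- list()
  if ("first_order" %in% families)
    parts$first_order <- first_order_features(volume, mask, n_levels)
  tex <- setdiff(families, "first_order")
  if (length(tex)) {
    qv <- quantize(volume, mask, n_levels)
    fns <- list(glcm = glcm_features, glrlm = glrlm_features,
                glszm = glszm_features, gldm = gldm_features,
                ngtdm = ngtdm_features)
    for (fam in tex) parts[[fam]] <- fns[[fam]](qv)
  }
  undef <- unlist(lapply(parts, function(p) {
    u <- attr(p, "undefined")
    if (is.null(u)) setNames(rep(FALSE, length(p)), names(p)) else u
  }))
  vals <- unlist(lapply(parts, function(p) {
    attributes(p)[c("undefined", "reason")] <- NULL
    p
  }))
  names(vals) <- sub("^[a-z_]+?\\.", "", names(vals))
  names(undef) <- sub("^[a-z_]+?\\.", "", names(undef))
  vals <- vals[bank$name]
  undef <- undef[bank$name]
  undef[is.na(undef)] <- FALSE
  names(undef) <- bank$name
  structure(vals,
            undefined = undef,
            category = setNames(bank$category, bank$name),
            variant = mask$label,
            config = list(n_levels = as.integer(n_levels),
                          families = families),
            class = c("feature_vector", "numeric"))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector '", attr(x, "variant"), "'> ", length(x),
      " features (", sum(attr(x, "undefined")), " undefined)\n", sep = "")
  invisible(x)
}

#' Extract features for a cohort of subjects and variants
#'
#' Builds the subjects x variants x features matrix consumed by the
#' concordance statistics: one row per subject-variant pair, one column
#' per feature, plus `subject` and `variant` identifier columns.
#' Undefined features are `NA` in the feature columns and `TRUE` in the
#' companion `und_<feature>` columns.
#'
#' @param subjects named list; each element holds a `volume`
#'   ([volume_grid()]) and a named list `masks` of [voi_mask()]s
#'   (reference, biopsy, morphological variants ...).
#' @param n_levels gray levels for quantization.
#' @return A data.frame of class `feature_matrix`.
#' @export
extract_feature_matrix <- function(subjects, n_levels = 32L) {
  rows <- list()
  for (sid in names(subjects)) {
    subj <- subjects[[sid]]
    for (vlab in names(subj$masks)) {
      m <- subj$masks[[vlab]]
      if (!any(m$voxels)) {
        # emptied variant (e.g. erosion of a thin biopsy): all features
        # missing for this subject-variant pair
        fv <- setNames(rep(NA_real_, nrow(feature_bank())),
                       feature_bank()$name)
        undef <- setNames(rep(TRUE, length(fv)), names(fv))
      } else {
        f <- extract_all(subj$volume, m, n_levels = n_levels)
        fv <- as.numeric(f)
        names(fv) <- names(f)
        undef <- attr(f, "undefined")
      }
      row <- data.frame(subject = sid, variant = vlab,
                        t(fv), check.names = FALSE)
      und <- as.data.frame(t(undef))
      names(und) <- paste0("und_", names(undef))
      rows[[length(rows) + 1L]] <- cbind(row, und)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_matrix", "data.frame")
  out
}

#' Read or write a feature matrix
#'
#' The serialized layout is one record per subject-variant pair with 94
#' feature fields and companion `und_` flags; the format (CSV or JSON)
#' follows the file extension.
#'
#' @param fm a `feature_matrix` (from [extract_feature_matrix()]).
#' @param path `.csv` or `.json` path.
#' @return `write_feature_matrix()`: `path`, invisibly;
#'   `read_feature_matrix()`: the `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  if (grepl("\\.json$", tolower(path)))
    jsonlite::write_json(fm, path, dataframe = "rows", na = "null",
                         digits = NA)
  else
    write.csv(fm, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  out <- if (grepl("\\.json$", tolower(path)))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    read.csv(path, check.names = FALSE)
  out <- as.data.frame(out, check.names = FALSE)
  class(out) <- c("feature_matrix", "data.frame")
  out
}
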