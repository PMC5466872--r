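# Texture families over a quantized VOI. All matrix accumulation is in
# compiled code; the statistics are computed here on small L x L (or
# L x maxlen) matrices. Direction set: the 13 unique 3-D voxel
# directions at Chebyshev distance 1 (up to negation); per-direction
# statistics are averaged unweighted over the directions that contain
# at least one valid voxel pair.

texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  # keep one of each +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(v) v[match(TRUE, v != 0)] > 0)
  g <- g[keep, , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

.GLCM_NAMES <- paste0("glcm_", c(
  "autocorrelation", "joint_average", "cluster_prominence", "cluster_shade",
  "cluster_tendency", "contrast", "correlation", "difference_average",
  "difference_entropy", "difference_variance", "joint_energy",
  "joint_entropy", "imc1", "imc2", "idm", "idmn", "id", "idn",
  "inverse_variance", "maximum_probability", "sum_average", "sum_entropy",
  "sum_variance", "sum_squares"))

.GLRLM_NAMES <- paste0("glrlm_", c(
  "short_run_emphasis", "long_run_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "run_length_nonuniformity",
  "run_length_nonuniformity_normalized", "run_percentage",
  "gray_level_variance", "run_variance", "run_entropy",
  "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
  "short_run_low_gray_level_emphasis", "short_run_high_gray_level_emphasis",
  "long_run_low_gray_level_emphasis", "long_run_high_gray_level_emphasis"))

.GLSZM_NAMES <- paste0("glszm_", c(
  "small_area_emphasis", "large_area_emphasis", "gray_level_nonuniformity",
  "gray_level_nonuniformity_normalized", "size_zone_nonuniformity",
  "size_zone_nonuniformity_normalized", "zone_percentage",
  "gray_level_variance", "zone_variance", "zone_entropy",
  "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
  "small_area_low_gray_level_emphasis",
  "small_area_high_gray_level_emphasis",
  "large_area_low_gray_level_emphasis",
  "large_area_high_gray_level_emphasis"))

.GLDM_NAMES <- paste0("gldm_", c(
  "small_dependence_emphasis", "large_dependence_emphasis",
  "gray_level_nonuniformity", "dependence_nonuniformity",
  "dependence_nonuniformity_normalized", "gray_level_variance",
  "dependence_variance", "dependence_entropy", "low_gray_level_emphasis",
  "high_gray_level_emphasis", "small_dependence_low_gray_level_emphasis",
  "small_dependence_high_gray_level_emphasis",
  "large_dependence_low_gray_level_emphasis",
  "large_dependence_high_gray_level_emphasis"))

.NGTDM_NAMES <- paste0("ngtdm_", c(
  "coarseness", "contrast", "busyness", "complexity", "strength"))

undefined_features <- function(names, reason) {
  out <- setNames(rep(NA_real_, length(names)), names)
  attr(out, "undefined") <- setNames(rep(TRUE, length(names)), names)
  attr(out, "reason") <- reason
  out
}

# statistics of one symmetric normalized co-occurrence matrix
glcm_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(P)                       # == py by symmetry
  mu <- sum(seq_len(L) * px)
  sigma2 <- sum((seq_len(L) - mu)^2 * px)
  # diagonal-band marginals
  ksum <- 2:(2 * L)
  p_plus <- vapply(ksum, function(k) sum(P[(i + j) == k]), numeric(1))
  kdif <- 0:(L - 1)
  p_minus <- vapply(kdif, function(k) sum(P[abs(i - j) == k]), numeric(1))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  HX <- ent(px)
  HXY <- ent(as.vector(P))
  pxpy <- outer(px, px)
  pos <- P > 0 & pxpy > 0
  HXY1 <- -sum(P[pos] * log2(pxpy[pos]))
  HXY2 <- ent(as.vector(pxpy))
  da <- sum(kdif * p_minus)
  sa <- sum(ksum * p_plus)
  autoc <- sum(i * j * P)
  offd <- abs(i - j) > 0
  c(glcm_autocorrelation = autoc,
    glcm_joint_average = mu,
    glcm_cluster_prominence = sum((i + j - 2 * mu)^4 * P),
    glcm_cluster_shade = sum((i + j - 2 * mu)^3 * P),
    glcm_cluster_tendency = sum((i + j - 2 * mu)^2 * P),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = if (sigma2 > 0) (autoc - mu^2) / sigma2 else 1,
    glcm_difference_average = da,
    glcm_difference_entropy = ent(p_minus),
    glcm_difference_variance = sum((kdif - da)^2 * p_minus),
    glcm_joint_energy = sum(P^2),
    glcm_joint_entropy = HXY,
    glcm_imc1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    glcm_imc2 = sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY)))),
    glcm_idm = sum(P / (1 + (i - j)^2)),
    glcm_idmn = sum(P / (1 + (i - j)^2 / L^2)),
    glcm_id = sum(P / (1 + abs(i - j))),
    glcm_idn = sum(P / (1 + abs(i - j) / L)),
    glcm_inverse_variance = sum(P[offd] / (i - j)[offd]^2),
    glcm_maximum_probability = max(P),
    glcm_sum_average = sa,
    glcm_sum_entropy = ent(p_plus),
    glcm_sum_variance = sum((ksum - sa)^2 * p_plus),
    glcm_sum_squares = sum((i - mu)^2 * P))
}

#' Gray-level co-occurrence features
#'
#' Builds one symmetric, normalized co-occurrence matrix per direction
#' (13 unique 3-D directions at voxel distance 1; only voxel pairs with
#' both members inside the mask are counted), computes 24 Haralick-
#' derived statistics per direction, and averages each statistic over
#' the directions that contain at least one pair. The maximal
#' correlation coefficient is not part of the set (numerically unstable
#' on small VOIs).
#'
#' @param qvoi a [quantize()] result.
#' @param directions integer n x 3 matrix of voxel offsets; default the
#'   13 canonical directions.
#' @return Named numeric vector of 24 features; when the VOI contains no
#'   valid voxel pair in any direction the values are `NA` with an
#'   `undefined` attribute.
#' @export
glcm_features <- function(qvoi, directions = texture_directions()) {
  stopifnot(inherits(qvoi, "quantized_voi"))
  lev <- array(as.integer(qvoi$levels), qvoi$dim)
  per_dir <- list()
  for (d in seq_len(nrow(directions))) {
    cnt <- .glcm_counts_cpp(lev, qvoi$dim, qvoi$n_levels,
                            directions[d, ])
    cnt <- cnt + t(cnt)  # symmetrize
    if (sum(cnt) == 0) next
    per_dir[[length(per_dir) + 1L]] <- glcm_stats(cnt / sum(cnt))
  }
  if (!length(per_dir))
    return(undefined_features(.GLCM_NAMES, "no in-mask voxel pairs"))
  out <- Reduce(`+`, per_dir) / length(per_dir)
  out[.GLCM_NAMES]
}

# Statistics shared by the run-length, size-zone and dependence
# families, computed from a sparse triplet form (i = gray level,
# j = run length / zone size / dependence, n = cell count) so that a
# single very large zone never forces a dense level x size matrix.
# np = in-mask voxel count. Duplicate (i, j) cells are aggregated first
# (the entropy term requires true cell probabilities).
rl_sz_stats <- function(i, j, n, np, names) {
  key <- paste(i, j, sep = "_")
  first <- !duplicated(key)
  n <- as.vector(rowsum(as.numeric(n), key, reorder = FALSE))
  i <- as.numeric(i[first]); j <- as.numeric(j[first])
  ns <- sum(n)
  p <- n / ns
  gl <- as.vector(rowsum(n, i))   # gray-level marginal
  sz <- as.vector(rowsum(n, j))   # size/length marginal
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  vals <- c(
    sum(n / j^2) / ns,
    sum(n * j^2) / ns,
    sum(gl^2) / ns,
    sum(gl^2) / ns^2,
    sum(sz^2) / ns,
    sum(sz^2) / ns^2,
    ns / np,
    sum(p * (i - mu_i)^2),
    sum(p * (j - mu_j)^2),
    -sum(p * log2(p)),
    sum(n / i^2) / ns,
    sum(n * i^2) / ns,
    sum(n / (i^2 * j^2)) / ns,
    sum(n * i^2 / j^2) / ns,
    sum(n * j^2 / i^2) / ns,
    sum(n * i^2 * j^2) / ns)
  setNames(vals, names)
}

mat_to_triplets <- function(M) {
  nz <- which(M > 0, arr.ind = TRUE)
  list(i = nz[, 1], j = nz[, 2], n = M[nz])
}

#' Gray-level run-length features
#'
#' Runs are maximal collinear segments of equal quantized level lying
#' entirely inside the mask, accumulated per direction (same 13
#' directions as [glcm_features()]); 16 standard run-length statistics
#' are averaged unweighted over directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(qvoi, directions = texture_directions()) {
  stopifnot(inherits(qvoi, "quantized_voi"))
  if (qvoi$n_voxels < 2L)
    return(undefined_features(.GLRLM_NAMES, "fewer than 2 in-mask voxels"))
  lev <- array(as.integer(qvoi$levels), qvoi$dim)
  per_dir <- lapply(seq_len(nrow(directions)), function(d) {
    M <- .glrlm_counts_cpp(lev, qvoi$dim, qvoi$n_levels, directions[d, ])
    tr <- mat_to_triplets(M)
    rl_sz_stats(tr$i, tr$j, tr$n, qvoi$n_voxels, .GLRLM_NAMES)
  })
  out <- Reduce(`+`, per_dir) / length(per_dir)
  out[.GLRLM_NAMES]
}

#' Size-zone, dependence, and neighbourhood gray-tone features
#'
#' The three higher-order families completing the texture bank:
#' \describe{
#'   \item{GLSZM}{zones are 26-connected components of equal quantized
#'     level; 16 statistics of the level x size matrix.}
#'   \item{GLDM}{dependence of a voxel is 1 plus the number of in-mask
#'     26-neighbours with the same level (`alpha = 0` tolerance);
#'     14 statistics of the level x dependence matrix.}
#'   \item{NGTDM}{per-level counts and summed absolute deviations from
#'     the mean neighbour tone give coarseness, contrast, busyness,
#'     complexity and strength. Voxels with no in-mask neighbour do not
#'     contribute; a perfectly homogeneous VOI has zero summed
#'     deviation, and its coarseness is capped at 1e6.}
#' }
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 + 14 + 5 = 35 features.
#' @export
higher_order_texture_features <- function(qvoi) {
  c(glszm_features(qvoi), gldm_features(qvoi), ngtdm_features(qvoi))
}

#' @rdname higher_order_texture_features
#' @export
glszm_features <- function(qvoi) {
  stopifnot(inherits(qvoi, "quantized_voi"))
  if (qvoi$n_voxels < 2L)
    return(undefined_features(.GLSZM_NAMES, "fewer than 2 in-mask voxels"))
  lev <- array(as.integer(qvoi$levels), qvoi$dim)
  labs <- .label_components_cpp(lev, qvoi$dim, TRUE)
  zl <- zone_table(lev, labs)
  rl_sz_stats(zl$level, zl$size, rep(1, nrow(zl)), qvoi$n_voxels,
              .GLSZM_NAMES)
}

zone_table <- function(lev, labs) {
  fg <- labs > 0L
  size <- tabulate(labs[fg])
  level <- lev[fg][match(seq_along(size), labs[fg])]
  data.frame(level = level, size = size)
}

#' @rdname higher_order_texture_features
#' @export
gldm_features <- function(qvoi) {
  stopifnot(inherits(qvoi, "quantized_voi"))
  if (qvoi$n_voxels < 2L)
    return(undefined_features(.GLDM_NAMES, "fewer than 2 in-mask voxels"))
  lev <- array(as.integer(qvoi$levels), qvoi$dim)
  ld <- .gldm_counts_cpp(lev, qvoi$dim, 0L)
  s <- rl_sz_stats(ld[, 1], ld[, 2], rep(1, nrow(ld)), qvoi$n_voxels,
                   .GLDM_NAMES_FULL)
  s[.GLDM_NAMES]
}

# rl_sz_stats emits 16 entries; the dependence family keeps 14 of them
# (run-percentage and run-variance analogues are dropped: every voxel
# contributes exactly one dependence entry, so the percentage is
# identically 1; dependence variance IS kept, zone-percentage analogue
# is not). Map by position.
.GLDM_NAMES_FULL <- c(
  "gldm_small_dependence_emphasis", "gldm_large_dependence_emphasis",
  "gldm_gray_level_nonuniformity", "gldm_gray_level_nonuniformity_norm_drop",
  "gldm_dependence_nonuniformity", "gldm_dependence_nonuniformity_normalized",
  "gldm_percentage_drop", "gldm_gray_level_variance",
  "gldm_dependence_variance", "gldm_dependence_entropy",
  "gldm_low_gray_level_emphasis", "gldm_high_gray_level_emphasis",
  "gldm_small_dependence_low_gray_level_emphasis",
  "gldm_small_dependence_high_gray_level_emphasis",
  "gldm_large_dependence_low_gray_level_emphasis",
  "gldm_large_dependence_high_gray_level_emphasis")

#' @rdname higher_order_texture_features
#' @export
ngtdm_features <- function(qvoi) {
  stopifnot(inherits(qvoi, "quantized_voi"))
  if (qvoi$n_voxels < 2L)
    return(undefined_features(.NGTDM_NAMES, "fewer than 2 in-mask voxels"))
  lev <- array(as.integer(qvoi$levels), qvoi$dim)
  ns <- .ngtdm_counts_cpp(lev, qvoi$dim, qvoi$n_levels)
  n_i <- ns[, 1]; s_i <- ns[, 2]
  nvp <- sum(n_i)
  if (nvp == 0)
    return(undefined_features(.NGTDM_NAMES, "no voxel has in-mask neighbours"))
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  lv <- seq_along(p_i)
  denom_coarse <- sum(p_i * s_i)
  coarseness <- if (denom_coarse > 0) 1 / denom_coarse else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i[act], p_i[act]) *
           outer(lv[act], lv[act], `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0
  ipi <- lv[act] * p_i[act]
  denom_busy <- sum(abs(outer(ipi, ipi, `-`)))
  busyness <- if (denom_busy > 0) sum(p_i * s_i) / denom_busy else 0
  pis <- p_i[act] * s_i[act]
  complexity <- sum(abs(outer(lv[act], lv[act], `-`)) *
                      outer(pis, pis, `+`) /
                      outer(p_i[act], p_i[act], `+`)) / nvp
  strength <- if (sum(s_i) > 0) {
    sum(outer(p_i[act], p_i[act], `+`) *
          outer(lv[act], lv[act], `-`)^2) / sum(s_i)
  } else 0
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
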