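# Quantization, first-order statistics and the five texture families,
# checked against hand computations and exhaustive enumeration oracles.

make_voi <- function(values, dims = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dims)) dims <- c(length(values), 1, 1)
  v <- volume_grid(array(values, dims), spacing = spacing)
  m <- voi_mask(array(TRUE, dims), spacing = spacing)
  list(v = v, m = m)
}

test_that("quantization maps the in-mask range onto 1..L", {
  # constant region: everything level 1
  x <- make_voi(rep(5, 8), c(2, 2, 2))
  q <- quantize(x$v, x$m, 32)
  expect_true(all(q$levels[x$m$voxels] == 1))
  # 0..31 with L = 32: identity mapping
  x <- make_voi(0:31, c(32, 1, 1))
  q <- quantize(x$v, x$m, 32)
  expect_equal(as.vector(q$levels), 0:31 + 1)
  # min -100, max 100, L = 2: sign split with max -> 2
  vals <- c(-100, -50, -1, 0, 1, 99, 100, -100)
  x <- make_voi(vals, c(8, 1, 1))
  q <- quantize(x$v, x$m, 2)
  expect_equal(as.vector(q$levels), ifelse(vals < 0, 1, 2))
  # outside-mask voxels are level 0
  m2 <- voi_mask(array(c(TRUE, FALSE), c(8, 1, 1)))
  q2 <- quantize(x$v, m2, 4)
  expect_true(all(q2$levels[!m2$voxels] == 0))
  expect_true(all(q2$levels[m2$voxels] >= 1))
})

test_that("first-order features match hand-computed values", {
  x <- make_voi(c(1, 2, 3, 4), c(4, 1, 1))
  f <- first_order_features(x$v, x$m)
  expect_equal(unname(f["fo_mean"]), 2.5)
  expect_equal(unname(f["fo_variance"]), 1.25)  # population convention
  expect_equal(unname(f["fo_energy"]), 30)
  expect_equal(unname(f["fo_skewness"]), 0)
  expect_equal(unname(f["fo_root_mean_square"]), sqrt(30 / 4))
  expect_equal(unname(f["fo_median"]), 2.5)
  expect_equal(unname(f["fo_range"]), 3)
  # voxel volume 2 mm^3 scales total energy only
  y <- make_voi(c(1, 2, 3, 4), c(4, 1, 1), spacing = c(1, 1, 2))
  g <- first_order_features(y$v, y$m)
  expect_equal(unname(g["fo_total_energy"]), 60)
  expect_equal(unname(g["fo_energy"]), 30)
})

test_that("constant regions use the zero-variance conventions", {
  x <- make_voi(rep(7, 27), c(3, 3, 3))
  f <- first_order_features(x$v, x$m)
  expect_equal(unname(f["fo_mean"]), 7)
  expect_equal(unname(f["fo_standard_deviation"]), 0)
  expect_equal(unname(f["fo_range"]), 0)
  expect_equal(unname(f["fo_skewness"]), 0)
  expect_equal(unname(f["fo_kurtosis"]), 0)
  expect_equal(unname(f["fo_entropy"]), 0)
  expect_equal(unname(f["fo_uniformity"]), 1)
})

test_that("co-occurrence features on degenerate patterns are exact", {
  # constant region: single-cell matrix
  x <- make_voi(rep(3, 27), c(3, 3, 3))
  q <- quantize(x$v, x$m, 8)
  f <- glcm_features(q)
  expect_equal(unname(f["glcm_joint_energy"]), 1)
  expect_equal(unname(f["glcm_joint_entropy"]), 0)
  expect_equal(unname(f["glcm_contrast"]), 0)
  expect_equal(unname(f["glcm_maximum_probability"]), 1)
  # 1-D alternating two-level pattern along x, single axial direction
  x <- make_voi(rep(c(0, 10), 4), c(8, 1, 1))
  q <- quantize(x$v, x$m, 2)
  f1 <- glcm_features(q, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(f1["glcm_contrast"]), 1.0)
  expect_equal(unname(f1["glcm_joint_energy"]), 0.5)
})

test_that("run-length features on degenerate patterns are exact", {
  # constant 1x1xN line, direction along it: one run of length N
  n <- 6
  x <- make_voi(rep(2, n), c(1, 1, n))
  q <- quantize(x$v, x$m, 4)
  f <- glrlm_features(q, directions = matrix(c(0L, 0L, 1L), 1))
  expect_equal(unname(f["glrlm_long_run_emphasis"]), n^2)
  expect_equal(unname(f["glrlm_run_percentage"]), 1 / n)
  expect_equal(unname(f["glrlm_short_run_emphasis"]), 1 / n^2)
  # alternating pattern: all runs have length 1
  x <- make_voi(rep(c(0, 10), 4), c(8, 1, 1))
  q <- quantize(x$v, x$m, 2)
  f <- glrlm_features(q, directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(unname(f["glrlm_short_run_emphasis"]), 1)
  expect_equal(unname(f["glrlm_long_run_emphasis"]), 1)
})

test_that("size-zone and gray-tone features on degenerate inputs", {
  # constant region: one zone spanning the mask
  x <- make_voi(rep(1, 27), c(3, 3, 3))
  q <- quantize(x$v, x$m, 8)
  f <- glszm_features(q)
  expect_equal(unname(f["glszm_size_zone_nonuniformity_normalized"]), 1)
  expect_equal(unname(f["glszm_zone_percentage"]), 1 / 27)
  g <- ngtdm_features(q)
  expect_equal(unname(g["ngtdm_contrast"]), 0)
  # two disjoint single-voxel zones of different levels
  vals <- array(0, c(5, 1, 1))
  vals[c(1, 5)] <- c(-50, 50)
  v <- volume_grid(vals)
  m <- voi_mask(array(c(TRUE, FALSE, FALSE, FALSE, TRUE), c(5, 1, 1)))
  q2 <- quantize(v, m, 4)
  f2 <- glszm_features(q2)
  expect_equal(unname(f2["glszm_zone_percentage"]), 2 / 2)  # 2 zones / 2 voxels
  expect_equal(unname(f2["glszm_small_area_emphasis"]), 1)
})

test_that("all texture families equal their brute-force oracles", {
  withr::local_seed(77)
  dirs <- texture_directions()
  for (rep in 1:10) {
    dims <- sample(3:6, 3, replace = TRUE)
    L <- sample(c(3, 4, 6), 1)
    v <- rand_volume(dims)
    m <- rand_mask(dims, p = runif(1, 0.4, 0.9))
    if (mask_count(m) < 2) next
    q <- quantize(v, m, L)
    lev <- q$levels

    # GLCM: per-direction matrices and averaged statistics
    per_dir <- list()
    for (d in seq_len(nrow(dirs))) {
      P <- oracle_glcm_matrix(lev, L, dirs[d, ])
      if (!is.null(P)) per_dir[[length(per_dir) + 1L]] <- P
    }
    got <- glcm_features(q)
    # oracle statistics via direct definition sums on each matrix
    o_contrast <- mean(vapply(per_dir, function(P) {
      s <- 0
      for (a in 1:L) for (b in 1:L) s <- s + (a - b)^2 * P[a, b]
      s
    }, numeric(1)))
    expect_equal(unname(got["glcm_contrast"]), o_contrast,
                 tolerance = 1e-9)
    o_energy <- mean(vapply(per_dir, function(P) sum(P^2), numeric(1)))
    expect_equal(unname(got["glcm_joint_energy"]), o_energy,
                 tolerance = 1e-9)
    o_autoc <- mean(vapply(per_dir, function(P) {
      s <- 0
      for (a in 1:L) for (b in 1:L) s <- s + a * b * P[a, b]
      s
    }, numeric(1)))
    expect_equal(unname(got["glcm_autocorrelation"]), o_autoc,
                 tolerance = 1e-9)

    # GLRLM: compare matrices per direction, then two statistics
    got_rl <- glrlm_features(q)
    o_sre <- o_lre <- numeric(0)
    for (d in seq_len(nrow(dirs))) {
      M <- oracle_glrlm_matrix(lev, L, dirs[d, ])
      Mi <- digibiopsy:::.glrlm_counts_cpp(
        array(as.integer(lev), dims), dims, L, dirs[d, ])
      expect_equal(M[, seq_len(ncol(Mi))], unname(as.matrix(Mi)))
      jj <- matrix(seq_len(ncol(M)), nrow(M), ncol(M), byrow = TRUE)
      o_sre <- c(o_sre, sum(M / jj^2) / sum(M))
      o_lre <- c(o_lre, sum(M * jj^2) / sum(M))
      # runs partition the in-mask voxels
      expect_equal(sum(M * jj), mask_count(m))
    }
    expect_equal(unname(got_rl["glrlm_short_run_emphasis"]), mean(o_sre),
                 tolerance = 1e-9)
    expect_equal(unname(got_rl["glrlm_long_run_emphasis"]), mean(o_lre),
                 tolerance = 1e-9)

    # GLSZM: zone list against flood-fill oracle
    zo <- oracle_zones(lev)
    expect_equal(sum(zo[, "size"]), mask_count(m))
    got_sz <- glszm_features(q)
    nz <- nrow(zo)
    expect_equal(unname(got_sz["glszm_zone_percentage"]),
                 nz / mask_count(m), tolerance = 1e-12)
    expect_equal(unname(got_sz["glszm_small_area_emphasis"]),
                 sum(1 / zo[, "size"]^2) / nz, tolerance = 1e-9)
    expect_equal(unname(got_sz["glszm_large_area_emphasis"]),
                 sum(zo[, "size"]^2) / nz, tolerance = 1e-9)

    # GLDM: dependence list against the voxelwise oracle
    od <- oracle_gldm(lev)
    got_dm <- gldm_features(q)
    expect_equal(unname(got_dm["gldm_small_dependence_emphasis"]),
                 sum(1 / od[, 2]^2) / nrow(od), tolerance = 1e-9)
    expect_equal(unname(got_dm["gldm_large_dependence_emphasis"]),
                 sum(od[, 2]^2) / nrow(od), tolerance = 1e-9)
    expect_equal(unname(got_dm["gldm_high_gray_level_emphasis"]),
                 sum(od[, 1]^2) / nrow(od), tolerance = 1e-9)

    # NGTDM accumulators against the voxelwise oracle
    on <- oracle_ngtdm(lev, L)
    got_ng <- ngtdm_features(q)
    nvp <- sum(on[, 1])
    p_i <- on[, 1] / nvp
    expect_equal(unname(got_ng["ngtdm_coarseness"]),
                 1 / sum(p_i * on[, 2]), tolerance = 1e-9)
  }
})

test_that("the default bank has 94 stably-ordered features", {
  bank <- feature_bank()
  expect_equal(nrow(bank), 94)
  expect_equal(sum(bank$category == "intensity"), 19)
  expect_equal(sum(bank$category == "texture"), 75)
  expect_equal(as.vector(table(bank$family)[c("first_order", "glcm",
                                              "glrlm", "glszm", "gldm",
                                              "ngtdm")]),
               c(19, 24, 16, 16, 14, 5))
  withr::local_seed(5)
  v <- rand_volume(c(5, 5, 5))
  m <- rand_mask(c(5, 5, 5), 0.7)
  f1 <- extract_all(v, m)
  f2 <- extract_all(v, m)
  expect_identical(names(f1), bank$name)
  expect_identical(as.numeric(f1), as.numeric(f2))  # deterministic
})

test_that("single-voxel masks define intensity but flag texture", {
  v <- rand_volume(c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  f <- extract_all(v, voi_mask(m))
  undef <- attr(f, "undefined")
  cats <- attr(f, "category")
  expect_false(any(undef[cats == "intensity"]))
  expect_true(all(undef[cats == "texture"]))
  expect_true(all(is.na(f[cats == "texture"])))
  expect_equal(unname(f["fo_standard_deviation"]), 0)
})

test_that("features are translation invariant and mask isolated", {
  withr::local_seed(21)
  v <- rand_volume(c(6, 6, 6), spacing = c(0.8, 0.8, 2))
  m <- rand_mask(c(6, 6, 6), 0.6, spacing = c(0.8, 0.8, 2))
  f0 <- extract_all(v, m)
  # shift the grid origin: nothing changes
  v2 <- v; v2$origin <- c(100, -50, 3)
  m2 <- m; m2$origin <- c(100, -50, 3)
  expect_identical(as.numeric(extract_all(v2, m2)), as.numeric(f0))
  # randomize voxels outside the mask: nothing changes
  v3 <- v
  v3$voxels[!m$voxels] <- rnorm(sum(!m$voxels), 500, 300)
  expect_identical(as.numeric(extract_all(v3, m)), as.numeric(f0))
})

test_that("intensity shifts move location features and spare texture", {
  withr::local_seed(22)
  v <- rand_volume(c(6, 6, 6))
  m <- rand_mask(c(6, 6, 6), 0.7)
  f0 <- extract_all(v, m)
  shift <- 150
  v2 <- v; v2$voxels <- v$voxels + shift
  f1 <- extract_all(v2, m)
  for (nm in c("fo_mean", "fo_median", "fo_minimum", "fo_maximum",
               "fo_percentile10", "fo_percentile90")) {
    expect_equal(unname(f1[nm]), unname(f0[nm]) + shift, tolerance = 1e-9)
  }
  keep <- c("fo_variance", "fo_standard_deviation", "fo_skewness",
            "fo_kurtosis", "fo_range", "fo_interquartile_range",
            "fo_entropy", "fo_uniformity",
            names(f0)[attr(f0, "category") == "texture"])
  expect_equal(as.numeric(f1[keep]), as.numeric(f0[keep]),
               tolerance = 1e-9)
})

test_that("co-occurrence matrices are symmetric and normalized", {
  withr::local_seed(30)
  dirs <- texture_directions()
  expect_equal(nrow(dirs), 13)
  v <- rand_volume(c(5, 5, 5))
  m <- rand_mask(c(5, 5, 5), 0.8)
  q <- quantize(v, m, 5)
  lev <- array(as.integer(q$levels), q$dim)
  for (d in seq_len(nrow(dirs))) {
    cnt <- digibiopsy:::.glcm_counts_cpp(lev, q$dim, 5L, dirs[d, ])
    P <- cnt + t(cnt)
    if (sum(P) == 0) next
    P <- P / sum(P)
    expect_equal(P, t(P))
    expect_equal(sum(P), 1)
  }
})
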