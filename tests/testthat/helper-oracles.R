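# Brute-force reference implementations used as independent oracles.
# They apply the mathematical definitions literally (explicit loops over
# voxels, pairs, runs, zones) and share no code with the package paths
# they check.

rand_mask <- function(dims, p = 0.5, spacing = c(1, 1, 1)) {
  voi_mask(array(runif(prod(dims)) < p, dims), spacing = spacing)
}

rand_volume <- function(dims, spacing = c(1, 1, 1)) {
  volume_grid(array(rnorm(prod(dims), 0, 100), dims), spacing = spacing)
}

# --- morphology -------------------------------------------------------

oracle_erode <- function(mask, offsets) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (!mask[x, y, z]) next
    keep <- TRUE
    for (o in seq_len(nrow(offsets))) {
      xx <- x + offsets[o, 1]; yy <- y + offsets[o, 2]
      zz <- z + offsets[o, 3]
      inside <- xx >= 1 && xx <= dims[1] && yy >= 1 && yy <= dims[2] &&
        zz >= 1 && zz <= dims[3]
      if (!inside || !mask[xx, yy, zz]) { keep <- FALSE; break }
    }
    out[x, y, z] <- keep
  }
  out
}

oracle_dilate <- function(mask, offsets) {
  dims <- dim(mask)
  out <- array(FALSE, dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    hit <- FALSE
    for (o in seq_len(nrow(offsets))) {
      xx <- x + offsets[o, 1]; yy <- y + offsets[o, 2]
      zz <- z + offsets[o, 3]
      inside <- xx >= 1 && xx <= dims[1] && yy >= 1 && yy <= dims[2] &&
        zz >= 1 && zz <= dims[3]
      if (inside && mask[xx, yy, zz]) { hit <- TRUE; break }
    }
    out[x, y, z] <- hit
  }
  out
}

# --- texture matrices -------------------------------------------------

all_directions_13 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(v) v[which(v != 0)[1]] > 0)
  unname(g[keep, ])
}

# symmetric normalized GLCM by explicit enumeration of ordered pairs
oracle_glcm_matrix <- function(lev, L, d) {
  dims <- dim(lev)
  M <- matrix(0, L, L)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lev[x, y, z]
    if (a == 0) next
    for (s in c(1, -1)) {
      xx <- x + s * d[1]; yy <- y + s * d[2]; zz <- z + s * d[3]
      if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
            zz < 1 || zz > dims[3]) next
      b <- lev[xx, yy, zz]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1
    }
  }
  if (sum(M) == 0) return(NULL)
  M / sum(M)
}

# run-length counts by walking every maximal line in the direction
oracle_glrlm_matrix <- function(lev, L, d) {
  dims <- dim(lev)
  M <- matrix(0, L, max(dims))
  starts <- which(array(TRUE, dims), arr.ind = TRUE)
  for (r in seq_len(nrow(starts))) {
    p <- starts[r, ]
    prev <- p - d
    prev_in <- all(prev >= 1) && all(prev <= dims)
    a <- lev[p[1], p[2], p[3]]
    if (a == 0) next
    if (prev_in && lev[prev[1], prev[2], prev[3]] == a) next
    len <- 0
    q <- p
    while (all(q >= 1) && all(q <= dims) && lev[q[1], q[2], q[3]] == a) {
      len <- len + 1
      q <- q + d
    }
    M[a, len] <- M[a, len] + 1
  }
  M
}

# equal-level 26-connected zones by repeated flood fill
oracle_zones <- function(lev) {
  dims <- dim(lev)
  seen <- array(FALSE, dims)
  zones <- list()
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    if (seen[p[1], p[2], p[3]]) next
    a <- lev[p[1], p[2], p[3]]
    queue <- list(p)
    seen[p[1], p[2], p[3]] <- TRUE
    size <- 0
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        v <- q + c(dx, dy, dz)
        if (any(v < 1) || any(v > dims)) next
        if (seen[v[1], v[2], v[3]]) next
        if (lev[v[1], v[2], v[3]] != a) next
        seen[v[1], v[2], v[3]] <- TRUE
        queue[[length(queue) + 1L]] <- v
      }
    }
    zones[[length(zones) + 1L]] <- c(level = a, size = size)
  }
  do.call(rbind, zones)
}

# per-voxel dependence (1 + same-level in-mask 26-neighbours)
oracle_gldm <- function(lev) {
  dims <- dim(lev)
  out <- NULL
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    a <- lev[p[1], p[2], p[3]]
    dep <- 1
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      v <- p + c(dx, dy, dz)
      if (any(v < 1) || any(v > dims)) next
      if (lev[v[1], v[2], v[3]] == a) dep <- dep + 1
    }
    out <- rbind(out, c(a, dep))
  }
  out
}

# NGTDM accumulators: n_i and s_i per level
oracle_ngtdm <- function(lev, L) {
  dims <- dim(lev)
  n_i <- numeric(L); s_i <- numeric(L)
  idx <- which(lev > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    a <- lev[p[1], p[2], p[3]]
    nb <- c()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      v <- p + c(dx, dy, dz)
      if (any(v < 1) || any(v > dims)) next
      b <- lev[v[1], v[2], v[3]]
      if (b > 0) nb <- c(nb, b)
    }
    if (!length(nb)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  cbind(n_i, s_i)
}

# --- ICC --------------------------------------------------------------

# explicit sum-of-squares two-way decomposition, composed per the A-1
# definition; written independently of the package implementation
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ss_rows <- 0
  for (i in 1:n) ss_rows <- ss_rows + (mean(m[i, ]) - g)^2
  ss_rows <- k * ss_rows
  ss_cols <- 0
  for (j in 1:k) ss_cols <- ss_cols + (mean(m[, j]) - g)^2
  ss_cols <- n * ss_cols
  ss_tot <- sum((m - g)^2)
  ms_r <- ss_rows / (n - 1)
  ms_c <- ss_cols / (k - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

# textbook route through R's two-way ANOVA
aov_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   row = factor(rep(1:n, k)),
                   col = factor(rep(1:k, each = n)))
  tab <- summary(stats::aov(y ~ row + col, data = df))[[1]]
  ms_r <- tab["row", "Mean Sq"]
  ms_c <- tab["col", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

# small in-memory cohort for report/CLI tests
toy_cohort <- function(n_subjects = 3, seed = 11, volume_cm3 = 1.5,
                       spacing = c(1, 1, 1)) {
  subjects <- list()
  for (i in seq_len(n_subjects)) {
    ph <- generate_phantom(phantom_spec(target_volume_cm3 = volume_cm3,
                                        spacing = spacing,
                                        seed = seed + i))
    subjects[[sprintf("s%02d", i)]] <- ph
  }
  subjects
}

# --- full per-family statistic oracles --------------------------------
# Direct-definition scalar implementations (explicit loops over matrix
# cells), matching the pinned conventions: log base 2 with 0*log(0)=0,
# IDMN/IDN normalized by L, correlation 1 for zero variance.

o_log2 <- function(p) ifelse(p > 0, log2(p), 0)

oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  px <- numeric(L)
  for (a in 1:L) for (b in 1:L) px[a] <- px[a] + P[a, b]
  mu <- sum((1:L) * px)
  s2 <- sum(((1:L) - mu)^2 * px)
  pplus <- numeric(2 * L); pminus <- numeric(L)
  for (a in 1:L) for (b in 1:L) {
    pplus[a + b] <- pplus[a + b] + P[a, b]
    pminus[abs(a - b) + 1] <- pminus[abs(a - b) + 1] + P[a, b]
  }
  acc <- cp <- cs <- ct <- con <- je <- jh <- idm <- idmn <- id <-
    idn <- iv <- ssq <- 0
  hxy1 <- hxy2 <- 0
  for (a in 1:L) for (b in 1:L) {
    p <- P[a, b]
    acc <- acc + a * b * p
    cp <- cp + (a + b - 2 * mu)^4 * p
    cs <- cs + (a + b - 2 * mu)^3 * p
    ct <- ct + (a + b - 2 * mu)^2 * p
    con <- con + (a - b)^2 * p
    je <- je + p^2
    jh <- jh - p * o_log2(p)
    idm <- idm + p / (1 + (a - b)^2)
    idmn <- idmn + p / (1 + (a - b)^2 / L^2)
    id <- id + p / (1 + abs(a - b))
    idn <- idn + p / (1 + abs(a - b) / L)
    if (a != b) iv <- iv + p / (a - b)^2
    ssq <- ssq + (a - mu)^2 * p
    hxy1 <- hxy1 - p * o_log2(px[a] * px[b])
    hxy2 <- hxy2 - px[a] * px[b] * o_log2(px[a] * px[b])
  }
  hx <- -sum(px * o_log2(px))
  da <- sum((0:(L - 1)) * pminus)
  sa <- sum((1:(2 * L)) * pplus)
  c(glcm_autocorrelation = acc,
    glcm_joint_average = mu,
    glcm_cluster_prominence = cp,
    glcm_cluster_shade = cs,
    glcm_cluster_tendency = ct,
    glcm_contrast = con,
    glcm_correlation = if (s2 > 0) (acc - mu^2) / s2 else 1,
    glcm_difference_average = da,
    glcm_difference_entropy = -sum(pminus * o_log2(pminus)),
    glcm_difference_variance = sum(((0:(L - 1)) - da)^2 * pminus),
    glcm_joint_energy = je,
    glcm_joint_entropy = jh,
    glcm_imc1 = if (hx > 0) (jh - hxy1) / hx else 0,
    glcm_imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - jh)))),
    glcm_idm = idm,
    glcm_idmn = idmn,
    glcm_id = id,
    glcm_idn = idn,
    glcm_inverse_variance = iv,
    glcm_maximum_probability = max(P),
    glcm_sum_average = sa,
    glcm_sum_entropy = -sum(pplus * o_log2(pplus)),
    glcm_sum_variance = sum(((1:(2 * L)) - sa)^2 * pplus),
    glcm_sum_squares = ssq)
}

# shared direct-definition statistics of a (level, size, count) list
oracle_rlsz_stats <- function(i, j, n, np, names) {
  # aggregate duplicate (level, size) cells so p is a cell probability
  key <- paste(i, j)
  agg <- tapply(n, key, sum)
  ij <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  i <- as.numeric(ij[, 1]); j <- as.numeric(ij[, 2])
  n <- as.numeric(agg)
  ns <- sum(n)
  gl <- tapply(n, i, sum)
  sz <- tapply(n, j, sum)
  p <- n / ns
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  vals <- c(sum(n / j^2) / ns,
            sum(n * j^2) / ns,
            sum(gl^2) / ns,
            sum(gl^2) / ns^2,
            sum(sz^2) / ns,
            sum(sz^2) / ns^2,
            ns / np,
            sum(p * (i - mu_i)^2),
            sum(p * (j - mu_j)^2),
            -sum(p * o_log2(p)),
            sum(n / i^2) / ns,
            sum(n * i^2) / ns,
            sum(n / (i^2 * j^2)) / ns,
            sum(n * i^2 / j^2) / ns,
            sum(n * j^2 / i^2) / ns,
            sum(n * i^2 * j^2) / ns)
  setNames(vals, names)
}

oracle_glrlm_stats <- function(M, np) {
  nz <- which(M > 0, arr.ind = TRUE)
  oracle_rlsz_stats(nz[, 1], nz[, 2], M[nz], np,
                    digibiopsy:::.GLRLM_NAMES)
}

oracle_glszm_stats <- function(zones, np) {
  oracle_rlsz_stats(zones[, "level"], zones[, "size"],
                    rep(1, nrow(zones)), np, digibiopsy:::.GLSZM_NAMES)
}

oracle_gldm_stats <- function(deps, np) {
  full <- oracle_rlsz_stats(deps[, 1], deps[, 2], rep(1, nrow(deps)), np,
                            digibiopsy:::.GLDM_NAMES_FULL)
  full[digibiopsy:::.GLDM_NAMES]
}

oracle_ngtdm_stats <- function(acc, L) {
  n_i <- acc[, 1]; s_i <- acc[, 2]
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  coarse_den <- sum(p_i * s_i)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength_num <- 0
  for (a in act) for (b in act) {
    contrast <- contrast + p_i[a] * p_i[b] * (a - b)^2
    strength_num <- strength_num + (p_i[a] + p_i[b]) * (a - b)^2
    complexity <- complexity + abs(a - b) *
      (p_i[a] * s_i[a] + p_i[b] * s_i[b]) / (p_i[a] + p_i[b])
  }
  for (a in act) for (b in act)
    busy_den <- busy_den + abs(a * p_i[a] - b * p_i[b])
  c(ngtdm_coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    ngtdm_contrast = if (ngp > 1)
      contrast / (ngp * (ngp - 1)) * sum(s_i) / nvp else 0,
    ngtdm_busyness = if (busy_den > 0) sum(p_i * s_i) / busy_den else 0,
    ngtdm_complexity = complexity / nvp,
    ngtdm_strength = if (sum(s_i) > 0) strength_num / sum(s_i) else 0)
}
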