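# Synthetic CT nodule phantoms. The generator emulates the cohort the
# method was designed for: lung nodules of 0.37-306 cm^3 on anisotropic
# grids (thin in-plane spacing, slice thickness up to 3 mm), soft-tissue
# nodule intensities over an air-density background, with a smoothed
# random field providing controllable texture heterogeneity and a
# lobulated (non-convex) boundary so erosion/closing paths are
# exercised. Every output is a pure function of its spec, seed
# included.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# splitmix-style chaining: derive stream `index` from a master seed,
# keeping results in 32-bit integer range
derive_seed <- function(seed, index) {
  x <- (as.numeric(seed) * 2654435761 + as.numeric(index) * 40503 +
          12345) %% 2147483647
  as.integer(x)
}

#' Phantom specification
#'
#' Parameters of one synthetic nodule phantom. Defaults describe a
#' mid-sized solid nodule: 10 cm^3 (the geometric middle of the
#' 0.37-306 cm^3 cohort range), 0.7 x 0.7 x 2.5 mm voxels, air-like
#' background around -850 HU and a soft-tissue nodule texture field
#' with mean 0 HU, SD 80 HU and 3 mm correlation length.
#'
#' @param target_volume_cm3 nodule volume in cm^3.
#' @param spacing voxel spacing in mm.
#' @param lobulation boundary perturbation amplitude (fraction of the
#'   radius; 0 gives a smooth ellipsoid).
#' @param background_mean,background_sd background HU model.
#' @param nodule_mean,nodule_sd in-nodule HU model.
#' @param correlation_mm Gaussian correlation length of the nodule
#'   texture field, in mm.
#' @param chest_wall add a high-density slab along the +x face.
#' @param padding_mm empty margin kept around the nodule so the
#'   morphological sweep (up to twice the largest radius) never reaches
#'   the lattice boundary.
#' @param seed integer seed; fully determines the phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(target_volume_cm3 = 10, spacing = c(0.7, 0.7, 2.5),
                         lobulation = 0.15, background_mean = -850,
                         background_sd = 40, nodule_mean = 0,
                         nodule_sd = 80, correlation_mm = 3,
                         chest_wall = FALSE, padding_mm = 6, seed = 1L) {
  stopifnot(target_volume_cm3 > 0, all(spacing > 0), lobulation >= 0,
            nodule_sd >= 0, correlation_mm > 0, padding_mm >= 0)
  structure(list(target_volume_cm3 = target_volume_cm3,
                 spacing = as.numeric(spacing), lobulation = lobulation,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 nodule_mean = nodule_mean, nodule_sd = nodule_sd,
                 correlation_mm = correlation_mm, chest_wall = chest_wall,
                 padding_mm = padding_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Gaussian smoothing of a 3-D field by FFT, sigma in mm per axis
smooth_field <- function(x, spacing, sigma_mm) {
  dims <- dim(x)
  kern1 <- function(n, dx) {
    # circular distance so the kernel wraps cleanly
    d <- pmin(0:(n - 1), n - (0:(n - 1))) * dx
    k <- exp(-0.5 * (d / sigma_mm)^2)
    k / sum(k)
  }
  kx <- kern1(dims[1], spacing[1])
  ky <- kern1(dims[2], spacing[2])
  kz <- kern1(dims[3], spacing[3])
  kern <- outer(outer(kx, ky), kz)
  dim(kern) <- dims
  out <- Re(fft(fft(x) * fft(kern), inverse = TRUE)) / prod(dims)
  array(out, dims)
}

#' Generate a synthetic nodule phantom
#'
#' Builds a CT-like volume and its ground-truth reference mask. The
#' nodule support is a lobulated ellipsoid whose voxel count is matched
#' to the volume target by thresholding the normalized radial
#' coordinate (so the realized volume is within one voxel of the
#' target, well inside the 5% contract). Intensities are an air-like
#' noisy background with the in-mask voxels replaced by a smoothed
#' random field rescaled to the target mean/SD; increasing the field's
#' correlation length makes the nodule texture coarser.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` ([volume_grid()]), `mask`
#'   ([voi_mask()], label `"reference"`) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    voxvol <- prod(spec$spacing)
    target_n <- max(8L, round(spec$target_volume_cm3 * 1000 / voxvol))
    # base radius of the equivalent sphere, mm
    r0 <- (3 * spec$target_volume_cm3 * 1000 / (4 * pi))^(1 / 3)
    # mild random anisotropy of the ellipsoid axes
    ax <- exp(runif(3, -0.2, 0.2))
    ax <- ax / prod(ax)^(1 / 3) * r0
    half_mm <- ax * (1 + spec$lobulation) + spec$padding_mm
    dims <- pmax(2L * ceiling(half_mm / spec$spacing) + 1L, 8L)
    if (any(dims > 1024L))
      stop("nodule of ", spec$target_volume_cm3,
           " cm^3 cannot fit with the required padding at this spacing")
    centre <- (dims + 1) / 2
    cx <- (seq_len(dims[1]) - centre[1]) * spec$spacing[1]
    cy <- (seq_len(dims[2]) - centre[2]) * spec$spacing[2]
    cz <- (seq_len(dims[3]) - centre[3]) * spec$spacing[3]
    X <- array(rep(cx, times = dims[2] * dims[3]), dims)
    Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
    Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
    rho <- sqrt((X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2)
    # lobulation: low-order angular modulation of the radius
    az <- atan2(Y, X)
    pol <- atan2(sqrt(X^2 + Y^2), Z)
    co <- runif(6, -1, 1)
    pert <- spec$lobulation * (
      co[1] * sin(2 * az) * sin(pol) + co[2] * cos(3 * az) * sin(pol)^2 +
        co[3] * cos(2 * pol) + co[4] * sin(az) * cos(pol) +
        co[5] * cos(2 * az) * sin(2 * pol) + co[6] * sin(3 * pol)) / 3
    rho_eff <- rho / pmax(1 + pert, 0.2)
    cutoff <- sort(as.vector(rho_eff), partial = target_n)[target_n]
    mask_arr <- rho_eff <= cutoff
    # intensity model
    vol <- array(rnorm(prod(dims), spec$background_mean,
                       spec$background_sd), dims)
    texture <- smooth_field(array(rnorm(prod(dims)), dims), spec$spacing,
                            spec$correlation_mm)
    tx <- texture[mask_arr]
    tsd <- sd(tx)
    if (!is.finite(tsd) || tsd == 0) tsd <- 1
    vol[mask_arr] <- (tx - mean(tx)) / tsd * spec$nodule_sd +
      spec$nodule_mean
    if (spec$chest_wall) {
      wall <- X > max(cx) - 2 * spec$spacing[1] - 1e-9
      vol[wall] <- rnorm(sum(wall), 40, 20)
    }
    volume <- volume_grid(vol, spacing = spec$spacing)
    mask <- voi_mask(mask_arr, spacing = spec$spacing, label = "reference")
    list(volume = volume, mask = mask, spec = spec)
  })
}

#' Digital-biopsy specification
#'
#' Parameters of the painted-biopsy simulator. The model mimics how a
#' human reader paints a rough contiguous sub-region over consecutive
#' cross-sections: a contiguous axial slab of slices, an inward margin
#' carved from the in-plane boundary (readers stay away from the edge
#' they are not asked to delineate), and per-slice jitter of that
#' margin. The margin is calibrated per subject by bisection so the
#' realized overlap with the reference hits `target_overlap`; the
#' default target 0.74 reproduces the regime of human-painted biopsies
#' that cover about three quarters of the tumour.
#'
#' @param slab_fraction fraction of the tumour-bearing slices painted
#'   (contiguous).
#' @param jitter relative per-slice variation of the inward margin.
#' @param containment keep the biopsy inside the reference; when
#'   `FALSE`, per-slice in-plane translation jitter may cross the
#'   boundary.
#' @param target_overlap desired overlap with the reference.
#' @param tolerance acceptable deviation from the target per subject.
#' @param seed integer seed.
#' @return A list of class `biopsy_spec`.
#' @export
biopsy_spec <- function(slab_fraction = 0.9, jitter = 0.25,
                        containment = TRUE, target_overlap = 0.74,
                        tolerance = 0.02, seed = 1L) {
  stopifnot(slab_fraction > 0, slab_fraction <= 1, jitter >= 0,
            jitter < 1, target_overlap > 0, target_overlap <= 1,
            tolerance >= 0)
  structure(list(slab_fraction = slab_fraction, jitter = jitter,
                 containment = containment,
                 target_overlap = target_overlap, tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "biopsy_spec")
}

#' Simulate a painted digital biopsy
#'
#' Carves a contiguous (26-connected) sub-region out of a reference
#' segmentation according to a [biopsy_spec()]: pick the contiguous
#' axial slab of slices with the largest tumour area, compute each
#' slice's in-plane Euclidean distance to the boundary (in mm), and
#' keep voxels deeper than a per-slice jittered margin. The global
#' margin is found by bisection so the realized overlap with the
#' reference matches the spec target; an unreachable target (the slab
#' alone caps the overlap) is an error stating the feasible range.
#'
#' @param reference non-empty reference [voi_mask()].
#' @param spec a [biopsy_spec()].
#' @return A [voi_mask()] labelled `"biopsy"`, with attributes
#'   `achieved_overlap` and `margin_mm`.
#' @export
simulate_biopsy <- function(reference, spec = biopsy_spec()) {
  stopifnot(inherits(reference, "voi_mask"), inherits(spec, "biopsy_spec"))
  if (!any(reference$voxels)) stop("empty reference mask")
  with_seed(spec$seed, {
    dims <- dim(reference$voxels)
    zs <- which(apply(reference$voxels, 3, any))
    n_keep <- max(1L, round(spec$slab_fraction * length(zs)))
    areas <- apply(reference$voxels, 3, sum)
    # contiguous slab (within the tumour-bearing range) of maximal area
    starts <- zs[seq_len(length(zs) - n_keep + 1L)]
    slab_sum <- vapply(starts, function(s) sum(areas[s:(s + n_keep - 1L)]),
                       numeric(1))
    s0 <- starts[which.max(slab_sum)]
    slab <- s0:(s0 + n_keep - 1L)
    jit <- 1 + runif(length(slab), -spec$jitter, spec$jitter)
    shift <- if (spec$containment) NULL else
      matrix(sample(-1:1, 2 * length(slab), replace = TRUE), ncol = 2)
    # per-slice in-plane distance (mm) to outside the reference
    edt <- lapply(slab, function(z)
      .edt2d_cpp(reference$voxels[, , z], reference$spacing[1],
                 reference$spacing[2]))
    n_ref <- sum(reference$voxels)

    carve <- function(margin) {
      out <- array(FALSE, dims)
      for (si in seq_along(slab)) {
        keep <- edt[[si]] > margin * jit[si]
        if (!is.null(shift)) {
          kk <- array(FALSE, dim(keep))
          sx <- shift[si, 1]; sy <- shift[si, 2]
          xs <- seq_len(dims[1] - abs(sx))
          ys <- seq_len(dims[2] - abs(sy))
          kk[xs + max(sx, 0), ys + max(sy, 0)] <-
            keep[xs + max(-sx, 0), ys + max(-sy, 0)]
          keep <- kk
        }
        out[, , slab[si]] <- keep
      }
      if (!any(out)) return(list(mask = out, o = 0))
      # keep the largest 26-connected component (contiguity contract)
      labs <- .label_components_cpp(array(as.integer(out), dims), dims,
                                    FALSE)
      main <- which.max(tabulate(labs[labs > 0L]))
      out <- array(labs == main, dims)
      n_int <- sum(out & reference$voxels)
      n_uni <- n_ref + sum(out) - n_int
      list(mask = out, o = n_int / n_uni)
    }

    hi_margin <- max(vapply(edt, max, numeric(1)))
    o_max <- carve(0)$o
    if (spec$target_overlap > o_max + spec$tolerance)
      stop(sprintf(
        "target overlap %.3f unreachable: feasible range is [0, %.3f] with slab_fraction %.2f",
        spec$target_overlap, o_max, spec$slab_fraction))
    lo <- 0; hi <- hi_margin
    best <- carve(0)
    best_margin <- 0
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      cur <- carve(mid)
      if (abs(cur$o - spec$target_overlap) <
            abs(best$o - spec$target_overlap)) {
        best <- cur; best_margin <- mid
      }
      if (cur$o > spec$target_overlap) lo <- mid else hi <- mid
    }
    out <- voi_mask(best$mask, spacing = reference$spacing,
                    origin = reference$origin, label = "biopsy")
    attr(out, "achieved_overlap") <- best$o
    attr(out, "margin_mm") <- best_margin
    out
  })
}

#' Generate a phantom cohort on disk
#'
#' Writes `n` phantoms (volume + reference mask + simulated biopsy as
#' NIfTI files) with per-subject seeds chained deterministically from
#' the cohort seed, nodule volumes log-uniform over `volume_range_cm3`,
#' and slice thickness log-uniform over `slice_range_mm`. A JSON
#' manifest records paths, seeds, specs and the achieved biopsy
#' overlaps. Subjects whose biopsy target is unreachable under the slab
#' constraint are calibrated to their feasible maximum and flagged in
#' the manifest.
#'
#' @param n number of subjects.
#' @param out_dir output directory.
#' @param seed master cohort seed.
#' @param volume_range_cm3 nodule volume range, cm^3.
#' @param slice_range_mm slice thickness range, mm.
#' @param phantom_template a [phantom_spec()] supplying the remaining
#'   phantom parameters.
#' @param biopsy_template a [biopsy_spec()] supplying the biopsy
#'   parameters.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
generate_cohort <- function(n, out_dir, seed = 1L,
                            volume_range_cm3 = c(0.37, 306),
                            slice_range_mm = c(1.25, 3),
                            phantom_template = phantom_spec(),
                            biopsy_template = biopsy_spec()) {
  stopifnot(n >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("subj%03d", i)
    s_seed <- derive_seed(seed, 3L * i)
    vol_cm3 <- with_seed(derive_seed(seed, 3L * i + 1L), {
      exp(runif(1, log(volume_range_cm3[1]), log(volume_range_cm3[2])))
    })
    sl <- with_seed(derive_seed(seed, 3L * i + 2L), {
      c(runif(1, 0.6, 0.9),
        exp(runif(1, log(slice_range_mm[1]), log(slice_range_mm[2]))))
    })
    pspec <- phantom_template
    pspec$target_volume_cm3 <- vol_cm3
    pspec$spacing <- c(sl[1], sl[1], sl[2])
    pspec$seed <- s_seed
    ph <- generate_phantom(pspec)
    bspec <- biopsy_template
    bspec$seed <- derive_seed(s_seed, 7L)
    biopsy <- tryCatch(simulate_biopsy(ph$mask, bspec), error = function(e) {
      # small nodules: the slab alone can cap the overlap below target;
      # fall back to the feasible maximum
      b2 <- bspec
      b2$target_overlap <- 1
      b2$tolerance <- 1
      simulate_biopsy(ph$mask, b2)
    })
    vol_path <- file.path(out_dir, paste0(sid, "_volume.nii.gz"))
    ref_path <- file.path(out_dir, paste0(sid, "_reference.nii.gz"))
    bio_path <- file.path(out_dir, paste0(sid, "_biopsy.nii.gz"))
    write_volume(ph$volume, vol_path)
    write_mask(ph$mask, ref_path)
    write_mask(biopsy, bio_path)
    subjects[[sid]] <- list(
      id = sid, seed = s_seed, volume_cm3 = vol_cm3,
      spacing = pspec$spacing,
      achieved_overlap = attr(biopsy, "achieved_overlap"),
      margin_mm = attr(biopsy, "margin_mm"),
      target_missed = abs(attr(biopsy, "achieved_overlap") -
                            biopsy_template$target_overlap) >
        biopsy_template$tolerance,
      paths = list(volume = basename(vol_path),
                   reference = basename(ref_path),
                   biopsy = basename(bio_path)))
  }
  manifest <- list(n = n, seed = as.integer(seed),
                   volume_range_cm3 = volume_range_cm3,
                   slice_range_mm = slice_range_mm,
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort manifest
#'
#' @param out_dir cohort directory containing `manifest.json`.
#' @return The manifest list; subject paths are resolved to absolute
#'   paths.
#' @export
read_cohort_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = FALSE)
  for (sid in names(manifest$subjects)) {
    p <- manifest$subjects[[sid]]$paths
    manifest$subjects[[sid]]$paths <- lapply(p, function(f)
      file.path(out_dir, f))
  }
  manifest
}
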