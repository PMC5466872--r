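#' Grid-aware CT-like volume
#'
#' A `volume_grid` couples a 3-D array of scalar intensities (Hounsfield
#' units for CT) with its physical geometry: per-axis voxel spacing in mm
#' and the physical position of voxel (1,1,1). The internal axis order is
#' (x, y, z) with z the slice axis; readers convert file conventions to
#' this order. Indexing follows R's 1-based convention at the interface.
#'
#' @param voxels numeric 3-D array of intensities; all values finite.
#' @param spacing numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin numeric length-3, physical position (mm) of voxel (1,1,1).
#' @return An object of class `volume_grid` with elements `voxels`,
#'   `spacing`, `origin` and `axes` (the order tag, always `"xyz"`).
#' @examples
#' vol <- volume_grid(array(rnorm(8 * 8 * 4), c(8, 8, 4)),
#'                    spacing = c(0.7, 0.7, 2.5))
#' voxel_volume(vol)  # mm^3
#' @export
volume_grid <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("expected 3-D volume, got ", length(dim(voxels)), "-D data")
  if (any(dim(voxels) < 1L)) stop("all lattice dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(!is.finite(voxels))) stop("voxel intensities must be finite")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axes = "xyz"),
            class = "volume_grid")
}

#' Binary volume-of-interest mask
#'
#' A `voi_mask` is a binary lattice on the same physical grid as a
#' [volume_grid()]: a reference segmentation, a digital biopsy, or a
#' morphological variant of one. Empty masks are representable; downstream
#' consumers flag rather than silently accept them.
#'
#' @param voxels logical (or 0/1) 3-D array.
#' @param spacing,origin grid geometry, as in [volume_grid()].
#' @param label free-text variant name, e.g. `"reference"` or
#'   `"erosion_1.0mm"`.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     label = "mask") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("expected 3-D mask, got ", length(dim(voxels)), "-D data")
  if (is.numeric(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("numeric mask values must be 0 or 1")
    voxels <- array(voxels != 0, dim(voxels))
  }
  if (!is.logical(voxels)) stop("mask voxels must be logical or 0/1")
  if (anyNA(voxels)) stop("mask voxels must not be NA")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 axes = "xyz", label = as.character(label)[1]),
            class = "voi_mask")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing (", paste(format(x$spacing), collapse = ", "),
      ") mm\n", sep = "")
  invisible(x)
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask '", x$label, "'> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " in mask, spacing (",
      paste(format(x$spacing), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' @rdname volume_grid
#' @param x a `volume_grid` or `voi_mask`.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Number of in-mask voxels
#' @param mask a [voi_mask()].
#' @return integer count of `TRUE` voxels.
#' @export
mask_count <- function(mask) sum(mask$voxels)

# Geometry equality within header round-off tolerance; shape must match
# exactly. Used wherever a mask is paired with a grid.
same_geometry <- function(a, b, tol = .GEOM_TOL) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

check_geometry <- function(a, b, what = "mask") {
  if (!same_geometry(a, b))
    stop(sprintf(
      "%s geometry mismatch: shape (%s) spacing (%s) origin (%s) vs shape (%s) spacing (%s) origin (%s)",
      what,
      paste(dim(a$voxels), collapse = ","),
      paste(format(a$spacing), collapse = ","),
      paste(format(a$origin), collapse = ","),
      paste(dim(b$voxels), collapse = ","),
      paste(format(b$spacing), collapse = ","),
      paste(format(b$origin), collapse = ",")))
  invisible(TRUE)
}

#' Physical coordinate of a voxel
#'
#' Maps 1-based voxel indices (i, j, k) to physical mm coordinates under
#' the internal (x, y, z) convention:
#' `origin + (i - 1, j - 1, k - 1) * spacing`.
#'
#' @param grid a `volume_grid` or `voi_mask`.
#' @param ijk integer length-3 voxel index (1-based) or an n x 3 matrix.
#' @return numeric coordinates in mm (length 3 or n x 3).
#' @export
voxel_to_physical <- function(grid, ijk) {
  if (is.matrix(ijk))
    sweep(sweep(ijk - 1, 2, grid$spacing, "*"), 2, grid$origin, "+")
  else
    grid$origin + (as.numeric(ijk) - 1) * grid$spacing
}

detect_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(tolower(format), c("nifti", "nrrd")))
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) "nrrd"
  else if (grepl("\\.nii(\\.gz)?$", lower)) "nifti"
  else stop("cannot infer format from extension of '", path,
            "'; pass format = \"nifti\" or \"nrrd\"")
}

read_raw_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- detect_format(path, format)
  if (format == "nifti") {
    img <- RNifti::readNifti(path)
    dims <- dim(img)
    if (length(dims) != 3L)
      stop("expected 3-D volume, got ", length(dims), "-D data in ", path)
    pix <- RNifti::pixdim(img)
    if (length(pix) < 3L || any(!is.finite(pix[1:3])) || any(pix[1:3] <= 0))
      stop("missing or non-positive spacing in NIfTI header field 'pixdim' of ",
           path)
    # physical origin from the sform/qform translation, magnitude only:
    # the internal convention keeps axis order (x, y, z)
    xf <- try(RNifti::xform(img), silent = TRUE)
    origin <- c(0, 0, 0)
    if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4, 4)))
      origin <- abs(xf[1:3, 4])
    list(voxels = array(as.numeric(img), dims), spacing = as.numeric(pix[1:3]),
         origin = as.numeric(origin))
  } else {
    read_nrrd(path)
  }
}

#' Read a 3-D scalar volume
#'
#' Reads NIfTI-1 (`.nii`, `.nii.gz`) or NRRD (`.nrrd`) volumes into a
#' [volume_grid()]. Spacing is taken from the file header and never
#' defaulted silently: a missing or zero spacing is a hard error naming
#' the header field.
#'
#' @param path file path.
#' @param format `"nifti"`, `"nrrd"`, or `NULL` to infer from the
#'   extension.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, format = NULL) {
  raw <- read_raw_volume(path, format)
  volume_grid(raw$voxels, spacing = raw$spacing, origin = raw$origin)
}

#' Read a binary VOI mask
#'
#' Reads a mask and checks its geometry against a reference grid: shape
#' must match exactly; spacing and origin within 1e-3 mm absolute
#' tolerance (header round-off). Values must be 0/1 unless `label_value`
#' selects one label from a multi-label file.
#'
#' @param path file path.
#' @param reference_grid the [volume_grid()] the mask annotates.
#' @param format as in [read_volume()].
#' @param label_value for multi-label files, the value mapped to `TRUE`.
#' @param label variant name recorded on the mask.
#' @return A [voi_mask()] carrying the reference grid's geometry.
#' @export
read_mask <- function(path, reference_grid = NULL, format = NULL,
                      label_value = NULL, label = NULL) {
  raw <- read_raw_volume(path, format)
  vals <- unique(as.vector(raw$voxels))
  if (is.null(label_value)) {
    if (!all(vals %in% c(0, 1)))
      stop("multi-label mask file (values: ",
           paste(sort(vals), collapse = ", "),
           "); pass label_value to select one label")
    vox <- raw$voxels != 0
  } else {
    vox <- raw$voxels == label_value
  }
  m <- voi_mask(array(vox, dim(raw$voxels)), spacing = raw$spacing,
                origin = raw$origin,
                label = if (is.null(label)) basename(path) else label)
  if (!is.null(reference_grid)) {
    check_geometry(m, reference_grid, what = paste0("mask '", path, "'"))
    # adopt the reference geometry exactly (differences are round-off)
    m$spacing <- reference_grid$spacing
    m$origin <- reference_grid$origin
  }
  m
}

#' Write a volume or mask
#'
#' Masks are written as unsigned 8-bit with values \{0, 1\}; volumes as
#' 64-bit float. Round-trips through
#' [read_volume()] / [read_mask()] preserve voxels exactly and geometry
#' within representation precision.
#'
#' @param x a [volume_grid()] or [voi_mask()].
#' @param path destination path; extension selects the format unless
#'   `format` is given.
#' @param format `"nifti"`, `"nrrd"`, or `NULL` to infer.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, format = NULL) {
  format <- detect_format(path, format)
  is_mask <- inherits(x, "voi_mask")
  vox <- if (is_mask) array(as.integer(x$voxels), dim(x$voxels)) else x$voxels
  if (format == "nifti") {
    img <- RNifti::asNifti(vox)
    RNifti::pixdim(img) <- x$spacing
    xf <- diag(c(x$spacing, 1))
    xf[1:3, 4] <- x$origin
    RNifti::sform(img) <- structure(xf, code = 2L)
    RNifti::qform(img) <- structure(xf, code = 2L)
    img <- RNifti::asNifti(
      img, datatype = if (is_mask) "uint8" else "double")
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(vox, path, spacing = x$spacing, origin = x$origin,
               type = if (is_mask) "uint8" else "double")
  }
  invisible(path)
}

#' @rdname write_volume
#' @param mask a [voi_mask()].
#' @export
write_mask <- function(mask, path, format = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  write_volume(mask, path, format)
}
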