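#' Spherical structuring element in physical units
#'
#' Discretizes a sphere of radius `radius_mm` on a voxel grid with the
#' given spacing: an integer offset is included iff the voxel-center to
#' voxel-center displacement has Euclidean norm (in mm) at most the
#' radius. On anisotropic grids the element adapts its shape — with a
#' 2.5 mm slice thickness a 1.5 mm "sphere" is a flat in-plane disc.
#' The element always contains the zero offset and is centrally
#' symmetric.
#'
#' @param radius_mm positive radius in mm.
#' @param spacing per-axis voxel size in mm (3 positive values).
#' @return An object of class `struct_element` with an integer offset
#'   matrix (`offsets`, n x 3), `radius_mm` and `spacing`.
#' @examples
#' make_spherical_element(1.0, c(1, 1, 1))    # centre + 6 face neighbours
#' make_spherical_element(1.5, c(0.7, 0.7, 2.5))  # flat disc
#' @export
make_spherical_element <- function(radius_mm, spacing) {
  stopifnot(length(radius_mm) == 1L, is.finite(radius_mm), radius_mm > 0)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(is.finite(spacing)), all(spacing > 0))
  reach <- floor(radius_mm / spacing)
  grid <- expand.grid(dx = -reach[1]:reach[1],
                      dy = -reach[2]:reach[2],
                      dz = -reach[3]:reach[3])
  d <- sqrt((grid$dx * spacing[1])^2 + (grid$dy * spacing[2])^2 +
              (grid$dz * spacing[3])^2)
  off <- as.matrix(grid[d <= radius_mm + 1e-12, , drop = FALSE])
  dimnames(off) <- NULL
  storage.mode(off) <- "integer"
  structure(list(offsets = off, radius_mm = radius_mm, spacing = spacing),
            class = "struct_element")
}

#' @export
print.struct_element <- function(x, ...) {
  cat("<struct_element> radius ", x$radius_mm, " mm on spacing (",
      paste(format(x$spacing), collapse = ", "), ") mm: ",
      nrow(x$offsets), " offsets\n", sep = "")
  invisible(x)
}

check_element_spacing <- function(mask, element) {
  if (any(abs(element$spacing - mask$spacing) > .GEOM_TOL))
    stop("structuring element built for spacing (",
         paste(format(element$spacing), collapse = ", "),
         ") applied to mask with spacing (",
         paste(format(mask$spacing), collapse = ", "), ")")
  invisible(TRUE)
}

#' Binary erosion, dilation, and erosion-with-closing
#'
#' `erode()` keeps a voxel iff every element offset from it lands inside
#' the mask; voxels beyond the lattice count as background, so the result
#' is always a subset of the input. `dilate()` keeps a voxel iff any
#' offset lands inside the mask; growth is unconstrained (aggressive
#' readers may paint past the tumour border) and clipped only by the
#' lattice. `erode_with_closing()` follows the erosion with a
#' morphological closing (dilation then erosion) using the same element,
#' reconnecting regions that the erosion would otherwise split.
#'
#' @param mask a [voi_mask()].
#' @param element a [make_spherical_element()] built for the mask's
#'   spacing.
#' @return A [voi_mask()] with a derived label and attribute `empty`
#'   set if the result has no voxels.
#' @export
erode <- function(mask, element) {
  check_element_spacing(mask, element)
  out <- mask
  out$voxels <- array(
    .erode_cpp(as.vector(mask$voxels), dim(mask$voxels), element$offsets),
    dim(mask$voxels))
  out$label <- paste0(mask$label, "+erode")
  attr(out, "empty") <- !any(out$voxels)
  out
}

#' @rdname erode
#' @export
dilate <- function(mask, element) {
  check_element_spacing(mask, element)
  out <- mask
  out$voxels <- array(
    .dilate_cpp(as.vector(mask$voxels), dim(mask$voxels), element$offsets),
    dim(mask$voxels))
  out$label <- paste0(mask$label, "+dilate")
  attr(out, "empty") <- !any(out$voxels)
  out
}

#' @rdname erode
#' @export
erode_with_closing <- function(mask, element) {
  eroded <- erode(mask, element)
  closed <- erode(dilate(eroded, element), element)
  closed$label <- paste0(mask$label, "+erode_close")
  attr(closed, "empty") <- !any(closed$voxels)
  attr(closed, "n_components") <- n_components(closed)
  closed
}

#' 26-connected components of a mask
#'
#' @param mask a [voi_mask()].
#' @return `n_components()`: the number of 26-connected foreground
#'   components; `label_components()`: an integer array of component
#'   labels (0 = background).
#' @export
label_components <- function(mask) {
  array(.label_components_cpp(array(as.integer(mask$voxels),
                                    dim(mask$voxels)),
                              dim(mask$voxels), FALSE),
        dim(mask$voxels))
}

#' @rdname label_components
#' @export
n_components <- function(mask) max(label_components(mask), 0L)

#' Simulate conservative and aggressive readers
#'
#' Builds the morphological variant set around a digital biopsy: the
#' original, one erosion-with-closing per radius (conservative readers)
#' and one unconstrained dilation per radius (aggressive readers). The
#' defaults, radii 0.5/1.0/1.5 mm, give 3 erosions and 3 dilations —
#' 7 variants in total. Erosions that empty the mask are carried with a
#' flag, never dropped.
#'
#' @param biopsy a [voi_mask()].
#' @param radii_mm ascending positive radii in mm; default
#'   `c(0.5, 1.0, 1.5)`.
#' @return An object of class `variant_set`: a named list of
#'   [voi_mask()]s (`original`, `erosion_{r}mm`, `dilation_{r}mm`) with
#'   a `provenance` attribute recording radii, emptiness and
#'   post-erosion component counts.
#' @export
simulate_readers <- function(biopsy, radii_mm = c(0.5, 1.0, 1.5)) {
  stopifnot(inherits(biopsy, "voi_mask"))
  if (length(radii_mm)) {
    stopifnot(all(radii_mm > 0), !is.unsorted(radii_mm))
  }
  variants <- list()
  orig <- biopsy
  orig$label <- "original"
  variants[["original"]] <- orig
  prov <- list(radii_mm = as.numeric(radii_mm), empty = character(0),
               n_components = list())
  for (r in radii_mm) {
    el <- make_spherical_element(r, biopsy$spacing)
    lab <- sprintf("erosion_%.1fmm", r)
    v <- erode_with_closing(biopsy, el)
    v$label <- lab
    if (isTRUE(attr(v, "empty"))) prov$empty <- c(prov$empty, lab)
    prov$n_components[[lab]] <- attr(v, "n_components")
    variants[[lab]] <- v
  }
  for (r in radii_mm) {
    el <- make_spherical_element(r, biopsy$spacing)
    lab <- sprintf("dilation_%.1fmm", r)
    v <- dilate(biopsy, el)
    v$label <- lab
    variants[[lab]] <- v
  }
  structure(variants, class = "variant_set", provenance = prov)
}

#' @export
print.variant_set <- function(x, ...) {
  cat("<variant_set> ", length(x), " variants: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize variant-set provenance
#'
#' Writes the labels, generating radii, emptiness flags and component
#' counts of a [simulate_readers()] result as JSON.
#'
#' @param variants a `variant_set`.
#' @param path destination JSON path.
#' @return `path`, invisibly.
#' @export
write_variant_provenance <- function(variants, path) {
  prov <- attr(variants, "provenance")
  prov$labels <- names(variants)
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
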