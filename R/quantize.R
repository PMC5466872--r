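#' Gray-level quantization of a VOI
#'
#' Discretizes in-mask intensities into `n_levels` equal-width bins
#' spanning the in-mask range:
#' `level = 1 + floor((x - min) / (max - min) * L)`, with the maximum
#' mapped to level `L`. A constant region maps every voxel to level 1.
#' All texture families operate on the quantized levels.
#'
#' @param volume a [volume_grid()].
#' @param mask a non-empty [voi_mask()] on the same grid.
#' @param n_levels integer number of gray levels (>= 2); default 32.
#' @return An object of class `quantized_voi`: `levels` (integer array,
#'   0 outside the mask, 1..L inside), `n_levels`, `bin_edges` (HU),
#'   `dim`, `spacing`, and the in-mask voxel count `n_voxels`.
#' @export
quantize <- function(volume, mask, n_levels = 32L) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "voi_mask"))
  check_geometry(mask, volume)
  n_levels <- as.integer(n_levels)
  stopifnot(n_levels >= 2L)
  inmask <- mask$voxels
  if (!any(inmask)) stop("cannot quantize an empty mask")
  x <- volume$voxels[inmask]
  lo <- min(x); hi <- max(x)
  lev <- array(0L, dim(inmask))
  if (hi == lo) {
    lev[inmask] <- 1L
    edges <- c(lo, lo)
  } else {
    l <- 1L + as.integer(floor((x - lo) / (hi - lo) * n_levels))
    l[l > n_levels] <- n_levels  # x == max
    lev[inmask] <- l
    edges <- seq(lo, hi, length.out = n_levels + 1L)
  }
  structure(list(levels = lev, n_levels = n_levels, bin_edges = edges,
                 dim = dim(inmask), spacing = mask$spacing,
                 n_voxels = sum(inmask)),
            class = "quantized_voi")
}

#' @export
print.quantized_voi <- function(x, ...) {
  cat("<quantized_voi> ", x$n_voxels, " voxels in ", x$n_levels,
      " levels\n", sep = "")
  invisible(x)
}
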