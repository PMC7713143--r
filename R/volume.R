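#' Calibrated micro-CT volume
#'
#' A 3-D scalar field of mineral density in mgHA/ccm together with its voxel
#' pitch. The bone long axis is, by convention, the third image axis; slices
#' are the planes perpendicular to it. Voxel indices are 1-based; the centre
#' of voxel `i` along an axis with pitch `p` sits at `(i - 0.5) * p` mm.
#'
#' @param values 3-D numeric array of densities (mgHA/ccm).
#' @param pitch Voxel pitch in mm; a single number (isotropic) or length 3.
#' @return An object of class `calibrated_volume` with fields `values` and
#'   `pitch` (always length 3).
#' @export
calibrated_volume <- function(values, pitch) {
  if (length(dim(values)) != 3L)
    stopf("`values` must be a 3-D array, got %d dims", length(dim(values)))
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (length(pitch) != 3L || any(!is.finite(pitch)) || any(pitch <= 0))
    stopf("`pitch` must be 1 or 3 positive finite numbers (mm)")
  if (any(!is.finite(values)))
    stopf("densities must be finite")
  structure(list(values = values, pitch = as.numeric(pitch), axis = 3L),
            class = "calibrated_volume")
}

#' @export
print.calibrated_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("calibrated_volume: %d x %d x %d voxels, pitch %s mm\n",
              d[1], d[2], d[3], paste(signif(x$pitch, 4), collapse = " x ")))
  cat(sprintf("  density range [%.1f, %.1f] mgHA/ccm\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.calibrated_volume <- function(x) dim(x$values)

# mm extent of the scanned field along each axis
scan_extent <- function(volume) dim(volume$values) * volume$pitch
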