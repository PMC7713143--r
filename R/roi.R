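#' Estimate the bone long axis
#'
#' The per-slice bone centroids are computed first; the axis direction is
#' the principal direction (first singular vector) of the centroid track,
#' which follows the shaft exactly even where the scan truncates the bone
#' obliquely at the field-of-view ends. The direction is oriented so its
#' component along the third image axis is positive (proximal-to-distal by
#' convention); for slices without bone the centroid track is interpolated
#' from neighbouring bone-bearing slices.
#'
#' @param masks A [segmentation_masks()] with a non-empty bone label.
#' @return A `bone_axis` object: `point` (mm), `direction` (unit vector),
#'   `centroids` (n_slices x 2 matrix, mm, in-plane).
#' @export
estimate_bone_axis <- function(masks) {
  stopifnot(inherits(masks, "segmentation_masks"))
  bone <- seg_mask(masks, "bone")
  if (!any(bone)) stopf("bone mask is empty; cannot estimate an axis")
  d <- dim(bone)
  p <- masks$pitch
  idx <- which(bone, arr.ind = TRUE)
  coords <- cbind((idx[, 1] - 0.5) * p[1], (idx[, 2] - 0.5) * p[2],
                  (idx[, 3] - 0.5) * p[3])
  ctr <- colMeans(coords)

  cen <- matrix(NA_real_, d[3], 2)
  for (k in unique(idx[, 3])) {
    sel <- idx[, 3] == k
    cen[k, ] <- c(mean(coords[sel, 1]), mean(coords[sel, 2]))
  }
  have <- which(!is.na(cen[, 1]))
  track <- cbind(cen[have, , drop = FALSE], (have - 0.5) * p[3])
  sv <- svd(sweep(track, 2, colMeans(track)), nu = 0, nv = 3)
  dir <- sv$v[, 1]
  if (dir[3] < 0) dir <- -dir
  for (j in 1:2)
    cen[, j] <- stats::approx(have, cen[have, j], xout = seq_len(d[3]),
                              rule = 2)$y
  structure(list(point = ctr, direction = dir / sqrt(sum(dir^2)),
                 centroids = cen, pitch = p),
            class = "bone_axis")
}

#' @export
print.bone_axis <- function(x, ...) {
  cat(sprintf("bone_axis: direction (%.4f, %.4f, %.4f), through (%.1f, %.1f, %.1f) mm\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$point[1], x$point[2], x$point[3]))
  invisible(x)
}

#' Define an analysis region of interest
#'
#' An ROI is an axial slab along the bone axis, `[start, end)` in mm, with an
#' optional cis half-space normal (unit vector in the slice plane, positive
#' side = cis = plate side).
#'
#' @param kind `"whole_bone"` or `"gap"`.
#' @param axial_bounds Numeric length 2, half-open `[start, end)` interval in
#'   mm along the third image axis.
#' @param cis_normal In-plane unit normal of the cis half-space.
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(kind, axial_bounds, cis_normal = c(1, 0, 0)) {
  kind <- match.arg(kind, c("whole_bone", "gap"))
  if (length(axial_bounds) != 2L || diff(axial_bounds) <= 0)
    stopf("axial_bounds must be an increasing length-2 interval (mm)")
  nrm <- sqrt(sum(cis_normal^2))
  if (!is.finite(nrm) || nrm < 1e-12) stopf("degenerate cis normal")
  structure(list(kind = kind, axial_bounds = as.numeric(axial_bounds),
                 cis_normal = cis_normal / nrm),
            class = "roi_spec")
}

#' Gap region of interest from screw geometry
#'
#' The gap ROI is the sample volume between the proximal and distal screw
#' adjacent to the osteotomy gap: its axial bounds run from the innermost
#' proximal screw to the innermost distal screw. Screw positions come from
#' configuration or phantom truth, not from image detection (implants are
#' explanted before scanning).
#'
#' @param screw_positions Axial screw positions, mm.
#' @param gap_bounds Axial interval (mm) of the osteotomy gap; the two
#'   innermost screws must straddle it.
#' @param cis_normal Passed to [roi_spec()].
#' @return An `roi_spec` of kind `"gap"`.
#' @export
define_gap_roi <- function(screw_positions, gap_bounds,
                           cis_normal = c(1, 0, 0)) {
  prox <- screw_positions[screw_positions <= gap_bounds[1]]
  dist <- screw_positions[screw_positions >= gap_bounds[2]]
  if (!length(prox) || !length(dist))
    stopf("screws must straddle the gap: found %d proximal, %d distal",
          length(prox), length(dist))
  bounds <- c(max(prox), min(dist))
  if (bounds[1] > gap_bounds[1] || bounds[2] < gap_bounds[2])
    stopf("gap ROI (%g, %g) does not contain the gap (%g, %g)",
          bounds[1], bounds[2], gap_bounds[1], gap_bounds[2])
  roi_spec("gap", bounds, cis_normal)
}

#' Whole-bone region of interest (sample volume under the plate)
#'
#' @param volume A [calibrated_volume()] (defines the scanned extent).
#' @param plate_extent Axial span (mm) of the plate, from configuration or
#'   phantom truth.
#' @param cis_normal Passed to [roi_spec()].
#' @return An `roi_spec` of kind `"whole_bone"`.
#' @export
define_whole_bone_roi <- function(volume, plate_extent,
                                  cis_normal = c(1, 0, 0)) {
  ext <- scan_extent(volume)[3]
  if (plate_extent[1] < 0 || plate_extent[2] > ext + 1e-9)
    stopf("plate extent (%g, %g) outside scanned extent [0, %g] mm",
          plate_extent[1], plate_extent[2], ext)
  roi_spec("whole_bone", plate_extent, cis_normal)
}

# Logical slice selector for an ROI: voxel-centre z in [start, end).
roi_slice_sel <- function(roi, n_slices, pitch_z) {
  zs <- voxel_centers(n_slices, pitch_z)
  zs >= roi$axial_bounds[1] & zs < roi$axial_bounds[2]
}

# Restrict a logical mask to an ROI slab.
apply_roi <- function(mask, roi, pitch) {
  sel <- roi_slice_sel(roi, dim(mask)[3], pitch[3])
  out <- mask
  out[, , !sel] <- FALSE
  out
}

#' Split a voxel mask into cis and trans half-spaces
#'
#' The cut plane passes through the per-slice bone centroid (robust to bone
#' curvature) with the given in-plane normal; voxels with positive signed
#' distance are cis (plate side), the rest trans. The two halves partition
#' the input mask exactly.
#'
#' @param mask Logical 3-D array.
#' @param axis A [estimate_bone_axis()] result (supplies per-slice centroids
#'   and the long-axis direction).
#' @param cis_normal In-plane unit normal pointing toward the plate; must be
#'   perpendicular to the bone axis within 5 degrees.
#' @return List with logical arrays `cis` and `trans`.
#' @export
split_cis_trans <- function(mask, axis, cis_normal = c(1, 0, 0)) {
  stopifnot(inherits(axis, "bone_axis"), is.logical(mask))
  nrm <- sqrt(sum(cis_normal^2))
  if (!is.finite(nrm) || nrm < 1e-12) stopf("degenerate cis normal")
  cis_normal <- cis_normal / nrm
  ang <- abs(90 - acos(abs(sum(cis_normal * axis$direction))) * 180 / pi)
  if (ang > 5)
    stopf("cis normal deviates %.1f deg from the plane normal to the bone axis",
          ang)
  d <- dim(mask)
  p <- axis$pitch
  xs <- voxel_centers(d[1], p[1])
  ys <- voxel_centers(d[2], p[2])
  cis <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    if (!any(mask[, , k])) next
    sd_plane <- outer(xs - axis$centroids[k, 1], rep(1, d[2])) * cis_normal[1] +
      outer(rep(1, d[1]), ys - axis$centroids[k, 2]) * cis_normal[2]
    cis[, , k] <- mask[, , k] & sd_plane > 0
  }
  list(cis = cis, trans = mask & !cis)
}
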