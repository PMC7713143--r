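# Segmentation label codes: a segmentation is one integer array in which
# every voxel carries exactly one label, so masks are disjoint and tile the
# volume by construction.
SEG_LABELS <- c(background = 0L, callus = 1L, bone = 2L, metal = 3L)

#' Segmentation masks
#'
#' Mutually exclusive voxel label sets for background, callus, bone and
#' (optionally) metal, stored as a single integer label array together with
#' the thresholds that produced it.
#'
#' @param labels Integer 3-D array coded as `callusmorph:::SEG_LABELS`.
#' @param pitch Voxel pitch, mm (length 3 or 1).
#' @param thresholds Named numeric: `callus_low`, `bone_high` (mgHA/ccm).
#' @param metal_threshold Metal cut used, or `NA`.
#' @return `segmentation_masks` object.
#' @export
segmentation_masks <- function(labels, pitch, thresholds,
                               metal_threshold = NA_real_) {
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  stopifnot(length(dim(labels)) == 3L, length(pitch) == 3L)
  structure(list(labels = labels, pitch = as.numeric(pitch),
                 thresholds = thresholds, metal_threshold = metal_threshold),
            class = "segmentation_masks")
}

#' Extract one label's logical mask
#'
#' @param masks A `segmentation_masks` object.
#' @param label One of `"background"`, `"callus"`, `"bone"`, `"metal"`.
#' @return Logical 3-D array.
#' @export
seg_mask <- function(masks, label) {
  stopifnot(inherits(masks, "segmentation_masks"))
  label <- match.arg(label, names(SEG_LABELS))
  masks$labels == SEG_LABELS[[label]]
}

#' @export
print.segmentation_masks <- function(x, ...) {
  counts <- tabulate(x$labels + 1L, nbins = 4L)
  names(counts) <- names(SEG_LABELS)
  voxvol <- prod(x$pitch) / 1000
  cat("segmentation_masks (thresholds:",
      sprintf("callus [%g, %g], bone > %g mgHA/ccm)\n",
              x$thresholds[["callus_low"]], x$thresholds[["bone_high"]],
              x$thresholds[["bone_high"]]))
  print(data.frame(label = names(counts), voxels = counts,
                   volume_ccm = round(counts * voxvol, 4), row.names = NULL))
  invisible(x)
}

#' Gaussian denoising of a calibrated volume
#'
#' Separable discrete Gaussian smoothing in voxel units, applied before
#' thresholding to stabilize labels. Density statistics downstream are
#' computed on the raw volume, so the filter never biases reported
#' densities. `sigma = 0` returns the input unchanged. Near the volume
#' border the truncated kernel is renormalized, so constant fields are
#' preserved everywhere.
#'
#' @param volume A [calibrated_volume()].
#' @param sigma Gaussian SD in voxels (>= 0).
#' @param support Half-width of the kernel support in voxels; defaults to
#'   `ceiling(3 * sigma)`.
#' @return A smoothed [calibrated_volume()].
#' @export
denoise <- function(volume, sigma = 0.4, support = NULL) {
  stopifnot(inherits(volume, "calibrated_volume"))
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(volume)
  support <- as.integer(support %||% ceiling(3 * sigma))
  off <- -support:support
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)

  vals <- volume$values
  norm <- array(1, dim(vals))
  for (axis in 1:3) {
    acc <- array(0, dim(vals))
    nacc <- array(0, dim(vals))
    for (i in seq_along(off)) {
      sh <- c(0L, 0L, 0L)
      sh[axis] <- off[i]
      acc <- acc + w[i] * shift_array(vals, sh, 0)
      nacc <- nacc + w[i] * shift_array(norm, sh, 0)
    }
    vals <- acc
    norm_axis <- nacc
    # renormalize truncated kernel at the two borders of this axis
    vals <- vals / norm_axis
  }
  calibrated_volume(vals, volume$pitch)
}

#' Dual density-threshold segmentation into bone, callus and background
#'
#' Voxels strictly above `bone_high` are native (or highly mineralized) bone;
#' voxels in the closed band `[callus_low, bone_high]` are callus; voxels
#' below are background. The band edges follow the convention that ties at
#' `bone_high` belong to callus. An optional metal cut removes very dense
#' voxels from the bone label.
#'
#' @param volume A [calibrated_volume()] (typically after [denoise()]).
#' @param callus_low,bone_high Density thresholds, mgHA/ccm (defaults
#'   250 and 1000).
#' @param metal_threshold If not `NA`, voxels >= this density are labelled
#'   metal rather than bone (default `NA`: no metal cut; screws are removed
#'   before scanning in the in-vivo workflow, but phantoms may include them).
#' @return A [segmentation_masks()] object.
#' @export
segment <- function(volume, callus_low = 250, bone_high = 1000,
                    metal_threshold = NA_real_) {
  stopifnot(inherits(volume, "calibrated_volume"))
  if (callus_low >= bone_high)
    stopf("callus_low (%g) must be < bone_high (%g)", callus_low, bone_high)
  v <- volume$values
  labels <- array(SEG_LABELS[["background"]], dim(v))
  labels[v >= callus_low & v <= bone_high] <- SEG_LABELS[["callus"]]
  labels[v > bone_high] <- SEG_LABELS[["bone"]]
  if (!is.na(metal_threshold))
    labels[v >= metal_threshold] <- SEG_LABELS[["metal"]]
  segmentation_masks(labels, volume$pitch,
                     c(callus_low = callus_low, bone_high = bone_high),
                     metal_threshold)
}

#' Morphological refinement of segmentation masks
#'
#' Per-label opening then closing with digital-ball structuring elements,
#' followed by removal of connected components smaller than `min_component`
#' voxels. Where closing makes labels collide, precedence bone > callus
#' restores disjointness; voxels freed by refinement return to background.
#'
#' @param masks A [segmentation_masks()].
#' @param opening_radius,closing_radius Ball radii in voxels (0 = skip).
#' @param min_component Minimum connected-component size in voxels
#'   (1 = keep everything). Default 27 (a 3x3x3 block).
#' @param connectivity Component connectivity, 6 or 26.
#' @return Refined [segmentation_masks()].
#' @export
refine_masks <- function(masks, opening_radius = 1, closing_radius = 1,
                         min_component = 27, connectivity = 6) {
  stopifnot(inherits(masks, "segmentation_masks"))
  if (opening_radius < 0 || closing_radius < 0) stopf("radii must be >= 0")
  out <- array(SEG_LABELS[["background"]], dim(masks$labels))
  for (label in c("callus", "metal", "bone")) {   # bone last: precedence
    m <- seg_mask(masks, label)
    if (!any(m)) next
    m <- open3d(m, opening_radius)
    m <- close3d(m, closing_radius)
    m <- filter_small_components(m, min_component, connectivity)
    out[m] <- SEG_LABELS[[label]]
  }
  segmentation_masks(out, masks$pitch, masks$thresholds,
                     masks$metal_threshold)
}

#' Native cortical envelope from intact slices
#'
#' Builds a per-slice model of the expected periosteal boundary of the
#' native cortex: in slices at least `standoff` mm away from the osteotomy
#' gap the bone label is taken as native, its periosteal contour is sampled
#' as the maximum radius in angular bins around the slice centroid, and both
#' centroid and radial profile are interpolated linearly across the
#' gap-adjacent region.
#'
#' @param masks A [segmentation_masks()].
#' @param gap_bounds Axial interval (mm) of the osteotomy gap.
#' @param standoff Distance (mm) from the gap beyond which slices are
#'   treated as intact native bone (default 5).
#' @param n_bins Number of angular bins for the radial contour.
#' @return A `native_envelope` object: per-slice centroids (mm) and radial
#'   profiles (mm, slices x bins).
#' @export
build_native_envelope <- function(masks, gap_bounds, standoff = 5,
                                  n_bins = 36) {
  stopifnot(inherits(masks, "segmentation_masks"))
  d <- dim(masks$labels)
  p <- masks$pitch
  zs <- voxel_centers(d[3], p[3])
  bone <- seg_mask(masks, "bone")
  bone_slices <- which(apply(bone, 3, any))
  intact <- bone_slices[zs[bone_slices] <= gap_bounds[1] - standoff |
                          zs[bone_slices] >= gap_bounds[2] + standoff]
  if (length(intact) < 2L)
    stopf("fewer than two intact slices beyond %g mm standoff", standoff)

  xs <- voxel_centers(d[1], p[1])
  ys <- voxel_centers(d[2], p[2])
  radii <- matrix(NA_real_, d[3], n_bins)
  cen <- matrix(NA_real_, d[3], 2)
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  for (k in intact) {
    idx <- which(bone[, , k], arr.ind = TRUE)
    px <- xs[idx[, 1]]; py <- ys[idx[, 2]]
    cx <- mean(px); cy <- mean(py)
    ang <- atan2(py - cy, px - cx)
    r <- sqrt((px - cx)^2 + (py - cy)^2)
    bin <- cut(ang, breaks, labels = FALSE, include.lowest = TRUE)
    prof <- rep(NA_real_, n_bins)
    agg <- tapply(r, bin, max)
    prof[as.integer(names(agg))] <- agg
    if (anyNA(prof)) {   # fill empty angular bins by circular interpolation
      ok <- which(!is.na(prof))
      prof <- stats::approx(c(ok - n_bins, ok, ok + n_bins),
                            rep(prof[ok], 3), xout = seq_len(n_bins),
                            rule = 2)$y
    }
    radii[k, ] <- prof
    cen[k, ] <- c(cx, cy)
  }
  # interpolate across non-intact (gap-region) slices
  all_k <- seq_len(d[3])
  for (j in seq_len(n_bins))
    radii[, j] <- stats::approx(intact, radii[intact, j], xout = all_k,
                                rule = 2)$y
  for (j in 1:2)
    cen[, j] <- stats::approx(intact, cen[intact, j], xout = all_k,
                              rule = 2)$y
  structure(list(radii = radii, centroids = cen, n_bins = n_bins,
                 intact_slices = intact, gap_bounds = gap_bounds,
                 standoff = standoff),
            class = "native_envelope")
}

#' Slice-wise reassignment of highly mineralized (mature) callus
#'
#' Mature callus can exceed the bone threshold, so density thresholding
#' alone would count it as cortical bone. Slice by slice, bone-labelled
#' voxels lying outside the native cortical envelope (the expected
#' periosteal boundary interpolated across the gap from intact slices) are
#' relabelled as callus. Bone + callus volume is conserved exactly.
#'
#' @param masks A [segmentation_masks()].
#' @param envelope A [build_native_envelope()] result covering every
#'   bone-bearing slice.
#' @param tolerance Radial slack (mm) added to the envelope before a voxel
#'   counts as outside it; defaults to one in-plane voxel diagonal.
#' @return The masks with an attribute `n_reassigned` giving the voxel count
#'   moved from bone to callus.
#' @export
reassign_mature_callus <- function(masks, envelope, tolerance = NULL) {
  stopifnot(inherits(masks, "segmentation_masks"),
            inherits(envelope, "native_envelope"))
  d <- dim(masks$labels)
  p <- masks$pitch
  tolerance <- tolerance %||% sqrt(p[1]^2 + p[2]^2)
  bone <- seg_mask(masks, "bone")
  bone_slices <- which(apply(bone, 3, any))
  if (any(is.na(envelope$radii[bone_slices, ])))
    stopf("native envelope does not cover every bone-bearing slice")
  xs <- voxel_centers(d[1], p[1])
  ys <- voxel_centers(d[2], p[2])
  breaks <- seq(-pi, pi, length.out = envelope$n_bins + 1L)
  labels <- masks$labels
  n_re <- 0L
  for (k in bone_slices) {
    idx <- which(bone[, , k], arr.ind = TRUE)
    px <- xs[idx[, 1]]; py <- ys[idx[, 2]]
    cx <- envelope$centroids[k, 1]; cy <- envelope$centroids[k, 2]
    r <- sqrt((px - cx)^2 + (py - cy)^2)
    bin <- cut(atan2(py - cy, px - cx), breaks, labels = FALSE,
               include.lowest = TRUE)
    outside <- r > envelope$radii[k, bin] + tolerance
    if (any(outside)) {
      flat <- (k - 1L) * d[1] * d[2] + (idx[outside, 2] - 1L) * d[1] +
        idx[outside, 1]
      labels[flat] <- SEG_LABELS[["callus"]]
      n_re <- n_re + sum(outside)
    }
  }
  out <- segmentation_masks(labels, p, masks$thresholds,
                            masks$metal_threshold)
  attr(out, "n_reassigned") <- n_re
  out
}
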