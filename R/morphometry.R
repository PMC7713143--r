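#' Volume of a voxel mask in ccm
#'
#' @param mask Logical array (or integer voxel count).
#' @param pitch Voxel pitch, mm (length 1 or 3).
#' @return Volume in ccm (cm^3): voxel count x voxel volume / 1000.
#' @export
compute_volume <- function(mask, pitch) {
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  if (any(pitch <= 0)) stopf("pitch must be > 0")
  n <- if (is.array(mask) || is.logical(mask)) sum(mask) else mask
  n * prod(pitch) / 1000
}

#' Mean mineral density over a mask
#'
#' Arithmetic mean of raw voxel densities over the mask. Densities are taken
#' from the unfiltered volume: smoothing stabilizes labels but must not bias
#' density statistics.
#'
#' @param volume A [calibrated_volume()] (raw values).
#' @param mask Logical array, non-empty.
#' @return Mean density, mgHA/ccm.
#' @export
compute_density <- function(volume, mask) {
  stopifnot(inherits(volume, "calibrated_volume"))
  if (!any(mask)) stopf("mask is empty: density undefined")
  mean(volume$values[mask])
}

#' Per-slice polar moment of inertia profile
#'
#' For each slice perpendicular to the bone long axis, the polar moment of
#' inertia of the included labels about the slice centroid:
#' `J = sum((x - xbar)^2 + (y - ybar)^2) * a` over included voxels, with `a`
#' the in-plane voxel area (mm^2) and `(xbar, ybar)` the centroid of the
#' included voxels in that slice. Positions are reported as percent of the
#' scan length; slices with no included voxels record `J = 0`.
#'
#' @param masks A [segmentation_masks()].
#' @param include Labels entering the section (default bone + callus, since
#'   periosteal callus drives torsional rigidity differences; configurable).
#' @param roi Optional [roi_spec()] restricting the profile axially.
#' @return data.frame with `slice`, `position_pct`, `pmoi_mm4`.
#' @export
pmoi_profile <- function(masks, include = c("bone", "callus"), roi = NULL) {
  stopifnot(inherits(masks, "segmentation_masks"))
  include_codes <- SEG_LABELS[match.arg(include, names(SEG_LABELS),
                                        several.ok = TRUE)]
  d <- dim(masks$labels)
  p <- masks$pitch
  a <- p[1] * p[2]
  m <- array(masks$labels %in% include_codes, d)
  if (!is.null(roi)) m <- apply_roi(m, roi, p)
  xs <- voxel_centers(d[1], p[1])
  ys <- voxel_centers(d[2], p[2])
  J <- numeric(d[3])
  for (k in seq_len(d[3])) {
    sl <- m[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    px <- xs[idx[, 1]]; py <- ys[idx[, 2]]
    J[k] <- sum((px - mean(px))^2 + (py - mean(py))^2) * a
  }
  zs <- voxel_centers(d[3], p[3])
  data.frame(slice = seq_len(d[3]),
             position_pct = 100 * zs / (d[3] * p[3]),
             pmoi_mm4 = J)
}

#' Morphometric summary of one sample in one region of interest
#'
#' Computes the imaging outcome variables for an ROI: callus and bone volume
#' (ccm), their mean densities (mgHA/ccm, raw values), the cis/trans callus
#' split and the pMOI profile. Densities of empty masks are reported as `NA`
#' (missing), never 0.
#'
#' @param volume Raw [calibrated_volume()].
#' @param masks A [segmentation_masks()] on the same grid.
#' @param axis A [estimate_bone_axis()] result.
#' @param roi An [roi_spec()].
#' @param pmoi_include Labels entering the pMOI section.
#' @return A `morphometry_result`: a one-row data.frame with attributes
#'   `roi` and `pmoi_profile`.
#' @export
summarize_sample <- function(volume, masks, axis, roi,
                             pmoi_include = c("bone", "callus")) {
  stopifnot(inherits(volume, "calibrated_volume"),
            inherits(masks, "segmentation_masks"),
            inherits(roi, "roi_spec"))
  if (!all(dim(volume$values) == dim(masks$labels)))
    stopf("volume and masks are on different grids")
  p <- masks$pitch
  callus <- apply_roi(seg_mask(masks, "callus"), roi, p)
  bone <- apply_roi(seg_mask(masks, "bone"), roi, p)
  halves <- split_cis_trans(callus, axis, roi$cis_normal)
  res <- data.frame(
    roi = roi$kind,
    callus_volume = compute_volume(callus, p),
    callus_density = if (any(callus)) compute_density(volume, callus)
                     else NA_real_,
    bone_volume = compute_volume(bone, p),
    bone_density = if (any(bone)) compute_density(volume, bone) else NA_real_,
    cis_callus_volume = compute_volume(halves$cis, p),
    trans_callus_volume = compute_volume(halves$trans, p),
    stringsAsFactors = FALSE)
  attr(res, "roi") <- roi
  attr(res, "pmoi_profile") <- pmoi_profile(masks, pmoi_include, roi)
  class(res) <- c("morphometry_result", "data.frame")
  res
}

#' Plot a pMOI profile
#'
#' @param x data.frame from [pmoi_profile()] (or a list of them, named by
#'   group).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_pmoi_profile <- function(x, ...) {
  if (is.data.frame(x)) x <- list(profile = x)
  ys <- sapply(x, `[[`, "pmoi_mm4")
  graphics::matplot(x[[1]]$position_pct, ys, type = "l", lty = 1,
                    xlab = "position along scan [%]",
                    ylab = expression(pMOI ~ "[mm"^4 * "]"), ...)
  if (length(x) > 1)
    graphics::legend("topright", legend = names(x), lty = 1,
                     col = seq_along(x))
  invisible(NULL)
}
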