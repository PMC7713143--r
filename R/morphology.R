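# 3-D binary morphology with digital-ball structuring elements, implemented
# as vectorized shift-AND / shift-OR over the ball's integer offsets.
# Out-of-volume voxels count as background for dilation and as foreground
# for erosion (objects are assumed to continue beyond the scanned field).

dilate3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- ball_offsets(radius)
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_array(mask, offs[i, ], FALSE)
  out
}

erode3d <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- ball_offsets(radius)
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_array(mask, offs[i, ], TRUE)
  out
}

open3d <- function(mask, radius) dilate3d(erode3d(mask, radius), radius)
close3d <- function(mask, radius) erode3d(dilate3d(mask, radius), radius)

#' Label connected components of a 3-D mask
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6 (face) or 26 (face, edge, corner) neighbourhood.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 6) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  lab <- cc_label_3d(as.logical(mask), as.integer(dim(mask)),
                     as.integer(connectivity))
  array(lab, dim(mask))
}

# Drop connected components smaller than min_voxels.
filter_small_components <- function(mask, min_voxels, connectivity = 6) {
  if (min_voxels <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_voxels)
  array(lab %in% keep & lab > 0L, dim(mask))
}
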