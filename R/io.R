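#' Write / read calibrated volumes
#'
#' NIfTI (.nii / .nii.gz) with the voxel pitch carried in the header, or a
#' TIFF stack (one 32-bit float image per slice) with a JSON sidecar holding
#' the pitch.
#'
#' @param volume A [calibrated_volume()] (or, for masks, an integer label
#'   array wrapped in one).
#' @param path Output path. `.nii`/`.nii.gz` selects NIfTI; a directory
#'   selects a TIFF stack (requires the `tiff` package).
#' @return `read_volume()` returns a [calibrated_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "calibrated_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$values)
    RNifti::pixdim(img) <- volume$pitch
    RNifti::writeNifti(img, path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("the 'tiff' package is required for TIFF stacks")
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    d <- dim(volume$values)
    for (k in seq_len(d[3]))
      tiff::writeTIFF(volume$values[, , k] / 4000,
                      file.path(path, sprintf("slice_%04d.tif", k)),
                      bits.per.sample = 32L)
    jsonlite::write_json(list(pitch_mm = volume$pitch, n_slices = d[3],
                              scale_mgHA = 4000),
                         file.path(path, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    calibrated_volume(array(as.numeric(img), dim(img)),
                      RNifti::pixdim(img)[1:3])
  } else {
    meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                                simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "^slice_\\d+\\.tif$",
                             full.names = TRUE))
    slices <- lapply(files, function(f) tiff::readTIFF(f) * meta$scale_mgHA)
    vals <- array(unlist(slices), c(dim(slices[[1]]), length(slices)))
    calibrated_volume(vals, meta$pitch_mm)
  }
}

#' Write segmentation masks as an unsigned 8-bit label volume
#'
#' @param masks A [segmentation_masks()].
#' @param path NIfTI output path.
#' @export
write_masks <- function(masks, path) {
  stopifnot(inherits(masks, "segmentation_masks"))
  img <- RNifti::asNifti(masks$labels)
  RNifti::pixdim(img) <- masks$pitch
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Write phantom truth bookkeeping as JSON
#'
#' Stores the exact compartment volumes and densities, gap bounds and screw
#' geometry (the label field itself is written separately with
#' [write_masks()] semantics if needed).
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param path JSON output path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(
    list(true_volumes_ccm = as.list(truth$true_volumes),
         true_densities_mgHA_ccm = as.list(truth$true_densities),
         cis_halfspace_normal = truth$cis_halfspace_normal,
         gap_bounds_mm = truth$gap_bounds,
         screw_axial_positions_mm = truth$screw_axial_positions,
         plate_extent_mm = truth$plate_extent,
         pitch_mm = truth$pitch),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
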