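#' Read and write volumes in the NIfTI standard
#'
#' Visitation maps and ROI label volumes can be exchanged with standard
#' neuroimaging tools as NIfTI files; voxel size is carried in the header.
#'
#' @param map A [visitation_map].
#' @param file Path to a `.nii` / `.nii.gz` file.
#' @return `write_visitation_nifti()` returns `file` invisibly;
#'   `read_volume_nifti()` returns a numeric array with attribute
#'   `voxel_size`.
#' @export
write_visitation_nifti <- function(map, file) {
  stopifnot(inherits(map, "visitation_map"))
  img <- RNifti::asNifti(map$counts)
  RNifti::pixdim(img) <- map$voxel_size
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_visitation_nifti
#' @param labels Integer array of ROI labels (0 = background).
#' @param voxel_size Voxel edge lengths in mm.
#' @export
write_roi_nifti <- function(labels, file, voxel_size = 1) {
  img <- RNifti::asNifti(labels)
  RNifti::pixdim(img) <- rep_len(voxel_size, 3)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' @rdname write_visitation_nifti
#' @export
read_volume_nifti <- function(file) {
  img <- RNifti::readNifti(file)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}
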