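#' Read a volume or label map from NIfTI
#'
#' Voxel spacing is taken from the NIfTI pixdim header.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [VoxelGrid-class].
#' @export
readVoxelGrid <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    petradStop("petrad_geometry_mismatch", "expected a 3-D NIfTI volume")
  voxelGrid(arr, spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname readVoxelGrid
#' @param reader,role metadata attached to the returned mask, see [roiMask()].
#' @return `readRoiMask`: an [RoiMask-class]; nonzero voxels are inside.
#' @export
readRoiMask <- function(path, reader = "none", role = "tumor") {
  vg <- readVoxelGrid(path)
  roiMask(gridData(vg) != 0, spacing = spacing(vg),
          reader = reader, role = role)
}

#' Write a volume or mask as NIfTI
#'
#' Spacing is stored in the pixdim header; masks are written as uint8 label
#' maps (1 inside, 0 outside).
#'
#' @param x a [VoxelGrid-class] or [RoiMask-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeNiftiVolume <- function(x, path) {
  if (is(x, "RoiMask")) {
    arr <- array(as.integer(maskArray(x)), dim = dim(maskArray(x)))
    sp <- spacing(x)
    datatype <- "uint8"
  } else {
    arr <- gridData(x)
    sp <- spacing(x)
    datatype <- "float"
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
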