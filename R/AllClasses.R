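#' @import methods
NULL

#' VoxelGrid: a 3-D scalar volume with anisotropic voxel spacing
#'
#' Container for a PET (SUV-valued) or CT (HU-valued) volume. Spacing is in
#' millimetres per axis; the physical volume of one voxel is
#' `prod(spacing(x))` cubic millimetres.
#'
#' @slot data numeric 3-D array of voxel values.
#' @slot spacing numeric length-3 vector, voxel size in mm along each axis.
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(data = "array", spacing = "numeric"))

setValidity("VoxelGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "'data' must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive finite values (mm)")
  if (length(msg)) msg else TRUE
})

#' RoiMask: a binary region-of-interest mask aligned to a VoxelGrid
#'
#' @slot mask logical 3-D array; `TRUE` marks voxels inside the region.
#' @slot spacing numeric length-3 voxel spacing in mm (must match the grid
#'   the mask is used with).
#' @slot reader character scalar identifying the reader ("reader1",
#'   "reader2", or "none" for machine-generated masks).
#' @slot role character scalar: "liver", "tumor" or "exclusion".
#' @exportClass RoiMask
setClass("RoiMask",
  representation(mask = "array", spacing = "numeric",
                 reader = "character", role = "character"))

setValidity("RoiMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "'mask' must be a logical 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be three positive values (mm)")
  if (length(object@reader) != 1L)
    msg <- c(msg, "'reader' must be a single string")
  if (length(object@role) != 1L ||
      !object@role %in% c("liver", "tumor", "exclusion"))
    msg <- c(msg, "'role' must be one of 'liver', 'tumor', 'exclusion'")
  if (length(msg)) msg else TRUE
})

#' SegmentationResult: PERCIST-thresholded tumour label map
#'
#' @slot threshold_suv numeric, the SUV threshold applied.
#' @slot tumor_mask a [RoiMask-class] with the segmented voxels.
#' @slot n_components integer, number of 26-connected components kept.
#' @slot total_mtv_ml numeric, metabolic tumour volume in millilitres.
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  representation(threshold_suv = "numeric", tumor_mask = "RoiMask",
                 n_components = "integer", total_mtv_ml = "numeric"))

#' Construct a VoxelGrid
#'
#' @param data numeric 3-D array (SUV for PET, HU for CT).
#' @param spacing numeric length-3 voxel size in mm.
#' @return A [VoxelGrid-class] object.
#' @examples
#' vg <- voxelGrid(array(1, dim = c(4, 4, 4)), spacing = c(4, 4, 4))
#' spacing(vg)
#' @export
voxelGrid <- function(data, spacing = c(1, 1, 1)) {
  new("VoxelGrid", data = data, spacing = as.numeric(spacing))
}

#' Construct an RoiMask
#'
#' @param mask logical (or coercible) 3-D array.
#' @param spacing numeric length-3 voxel size in mm.
#' @param reader reader identity, e.g. "reader1".
#' @param role one of "liver", "tumor", "exclusion".
#' @return An [RoiMask-class] object.
#' @export
roiMask <- function(mask, spacing = c(1, 1, 1), reader = "none",
                    role = "tumor") {
  m <- mask
  if (!is.logical(m)) {
    d <- dim(m)
    m <- as.logical(m)
    dim(m) <- d
  }
  new("RoiMask", mask = m, spacing = as.numeric(spacing),
      reader = reader, role = role)
}

#' @describeIn voxelGrid Extract the voxel array.
#' @param x a VoxelGrid or RoiMask.
#' @export
gridData <- function(x) x@data

#' Voxel spacing accessor
#' @param x a [VoxelGrid-class] or [RoiMask-class].
#' @return numeric length-3 spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "VoxelGrid", function(x) x@spacing)

#' @rdname spacing
#' @export
setMethod("spacing", "RoiMask", function(x) x@spacing)

#' Logical mask array accessor
#' @param x an [RoiMask-class].
#' @export
maskArray <- function(x) x@mask

#' Reader identity of a mask
#' @param x an [RoiMask-class].
#' @export
readerId <- function(x) x@reader

#' Number of voxels inside a mask
#' @param x an [RoiMask-class].
#' @export
maskVoxelCount <- function(x) sum(x@mask)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelGrid %d x %d x %d, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = " x "),
              min(object@data), max(object@data)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RoiMask (%s, %s) %d x %d x %d, %d voxels set\n",
              object@role, object@reader, d[1], d[2], d[3],
              sum(object@mask)))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(
    "SegmentationResult: threshold %.3f SUV, %d component(s), MTV %.2f ml\n",
    object@threshold_suv, object@n_components, object@total_mtv_ml))
})

#' Segmentation accessors
#' @param x a [SegmentationResult-class].
#' @name segmentation-accessors
NULL

#' @rdname segmentation-accessors
#' @export
thresholdSuv <- function(x) x@threshold_suv

#' @rdname segmentation-accessors
#' @export
tumorMask <- function(x) x@tumor_mask

#' @rdname segmentation-accessors
#' @export
nComponents <- function(x) x@n_components

#' @rdname segmentation-accessors
#' @export
totalMtvMl <- function(x) x@total_mtv_ml

# internal: classed error helper so callers can condition on failure modes
petradStop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "petrad_error"),
                      call = call))
}

# internal: check a mask is aligned (shape + spacing) with a grid
checkAligned <- function(grid, mask) {
  if (!identical(dim(gridData(grid)), dim(maskArray(mask))) ||
      max(abs(spacing(grid) - spacing(mask))) > 1e-6)
    petradStop("petrad_geometry_mismatch",
               "mask is not aligned with the grid (shape/spacing differ)")
  invisible(TRUE)
}
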