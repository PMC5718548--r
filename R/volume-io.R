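# NIfTI input/output for volumes and lung images.

#' @include AllClasses.R AllGenerics.R
NULL

#' Write a volume to NIfTI
#'
#' Stores the HU array with the voxel sizes in the NIfTI pixdim header
#' (fine volumes: the isotropic pitch; clinical volumes: pixel size in
#' plane and slice interval along z). Values are stored as doubles so that
#' a write/read round trip preserves them to floating-point precision.
#'
#' @param vol an [ObjectVolume-class], [BlurredVolume-class],
#'   [ClinicalVolume-class] or [LungImage-class].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolumeNIfTI <- function(vol, path) {
    if (is(vol, "ClinicalVolume")) {
        v <- vol@values
        pd <- c(vol@pixelSize, vol@pixelSize, vol@sliceInterval)
    } else if (is(vol, "ObjectVolume") || is(vol, "BlurredVolume")) {
        v <- vol@values
        pd <- rep(vol@pitch, 3L)
    } else if (is(vol, "LungImage")) {
        v <- vol@values
        pd <- rep(vol@pixelSize, 2L)
    } else stop("unsupported volume class: ", class(vol)[1L])
    img <- RNifti::asNifti(v)
    RNifti::pixdim(img) <- pd
    RNifti::writeNifti(img, path, datatype = "double")
    invisible(path)
}

#' Read a volume from NIfTI
#'
#' Returns the raw array and per-axis voxel sizes; refuses files without
#' usable spatial metadata rather than assuming a default.
#'
#' @param path a NIfTI file.
#' @return a list with elements `values` (numeric array) and `spacing`
#'   (per-axis voxel size in mm).
#' @seealso [readLungImage()] for reading a 2D slice as a
#'   [LungImage-class].
#' @export
readVolumeNIfTI <- function(path) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    nd <- length(dim(img))
    sp <- sp[seq_len(min(nd, length(sp)))]
    if (length(sp) == 0L || any(!is.finite(sp)) || any(sp <= 0))
        stop("'", path, "' has no usable voxel-size metadata")
    list(values = unclass(as.array(img)), spacing = as.numeric(sp))
}

#' @describeIn readVolumeNIfTI read a 2D slice (or the first slice of a
#'   3D file) as a [LungImage-class]; requires isotropic in-plane pixels.
#' @export
readLungImage <- function(path) {
    v <- readVolumeNIfTI(path)
    a <- v$values
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    if (abs(v$spacing[1L] - v$spacing[2L]) > 1e-9)
        stop("anisotropic in-plane pixels are not supported for lung images")
    lungImage(a, v$spacing[1L])
}
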