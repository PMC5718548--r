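# Generics and simple accessors.

#' @include AllClasses.R
NULL

#' Accessors for scanner profiles
#'
#' @param object a [KernelProfile2D-class] or [AxialProfile-class].
#' @return `profileValues` returns the amplitude grid, `profilePitch` the
#'   sampling pitch in mm, `profileLabel` the identifier, and
#'   `profileExtent` the half-width of the support in mm.
#' @examples
#' psf <- gaussianPSF(fwhm = 0.8, pitch = 0.05)
#' profilePitch(psf)
#' profileExtent(psf)
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname profileValues
#' @export
setGeneric("profilePitch", function(object) standardGeneric("profilePitch"))

#' @rdname profileValues
#' @export
setGeneric("profileLabel", function(object) standardGeneric("profileLabel"))

#' @rdname profileValues
#' @export
setGeneric("profileExtent", function(object) standardGeneric("profileExtent"))

#' @export
#' @rdname profileValues
setMethod("profileValues", "ScannerProfile", function(object) object@values)

#' @rdname profileValues
setMethod("profilePitch", "ScannerProfile", function(object) object@pitch)

#' @rdname profileValues
setMethod("profileLabel", "ScannerProfile", function(object) object@label)

#' @rdname profileValues
setMethod("profileExtent", "KernelProfile2D", function(object)
    (nrow(object@values) - 1L) / 2 * object@pitch)

#' @rdname profileValues
setMethod("profileExtent", "AxialProfile", function(object)
    (length(object@values) - 1L) / 2 * object@pitch)

#' Accessors for voxel volumes
#'
#' @param object an [ObjectVolume-class], [BlurredVolume-class] or
#'   [ClinicalVolume-class].
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @return `voxelData` returns the HU array; `voxelPitch` the (isotropic)
#'   fine-grid pitch in mm; `axisCoords` the voxel-center coordinates along
#'   an axis, in mm relative to the nodule center; `noduleCenter` the
#'   center coordinates in mm.
#' @examples
#' obj <- makeSphere(diameter = 2, pitch = 0.1, margin = 1)
#' dim(voxelData(obj))
#' range(axisCoords(obj, "x"))
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setGeneric("voxelPitch", function(object) standardGeneric("voxelPitch"))

#' @rdname voxelData
#' @export
setGeneric("axisCoords", function(object, axis = c("x", "y", "z"))
    standardGeneric("axisCoords"))

#' @rdname voxelData
#' @export
setGeneric("noduleCenter", function(object) standardGeneric("noduleCenter"))

#' @rdname voxelData
setMethod("voxelData", "ObjectVolume", function(object) object@values)
#' @rdname voxelData
setMethod("voxelData", "BlurredVolume", function(object) object@values)
#' @rdname voxelData
setMethod("voxelData", "ClinicalVolume", function(object) object@values)
#' @rdname voxelData
setMethod("voxelData", "LungImage", function(object) object@values)

#' @rdname voxelData
setMethod("voxelPitch", "ObjectVolume", function(object) object@pitch)
#' @rdname voxelData
setMethod("voxelPitch", "BlurredVolume", function(object) object@pitch)

.fineAxisCoords <- function(object, axis) {
    axis <- match.arg(axis, c("x", "y", "z"))
    i <- match(axis, c("x", "y", "z"))
    object@origin[i] + (seq_len(dim(object@values)[i]) - 1L) * object@pitch
}

#' @rdname voxelData
setMethod("axisCoords", "ObjectVolume", .fineAxisCoords)
#' @rdname voxelData
setMethod("axisCoords", "BlurredVolume", .fineAxisCoords)
#' @rdname voxelData
setMethod("axisCoords", "ClinicalVolume", function(object, axis = c("x", "y", "z")) {
    axis <- match.arg(axis)
    switch(axis, x = object@xs, y = object@ys, z = object@zs)
})

#' @rdname voxelData
setMethod("noduleCenter", "ObjectVolume", function(object) object@center)
#' @rdname voxelData
setMethod("noduleCenter", "BlurredVolume", function(object) object@center)
#' @rdname voxelData
setMethod("noduleCenter", "ClinicalVolume", function(object) c(0, 0, 0))

#' Clinical geometry accessors
#'
#' @param object a [ReconstructionConfig-class] or [ClinicalVolume-class].
#' @return `pixelSize` returns the in-plane sampling interval (mm),
#'   `sliceThickness` and `sliceInterval` the z geometry (mm),
#'   `offsetTriple` the `(dx, dy, dz)` sub-voxel offset of a resampled
#'   volume (mm).
#' @examples
#' cfg <- reconstructionConfig(fov = 200, matrixSize = 512,
#'                             sliceThickness = 1)
#' pixelSize(cfg)
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname pixelSize
#' @export
setGeneric("sliceThickness", function(object) standardGeneric("sliceThickness"))

#' @rdname pixelSize
#' @export
setGeneric("sliceInterval", function(object) standardGeneric("sliceInterval"))

#' @rdname pixelSize
#' @export
setGeneric("offsetTriple", function(object) standardGeneric("offsetTriple"))

#' @rdname pixelSize
setMethod("pixelSize", "ReconstructionConfig", function(object)
    object@fov / as.numeric(object@matrixSize))
#' @rdname pixelSize
setMethod("pixelSize", "ClinicalVolume", function(object) object@pixelSize)
#' @rdname pixelSize
setMethod("pixelSize", "LungImage", function(object) object@pixelSize)

#' @rdname pixelSize
setMethod("sliceThickness", "ReconstructionConfig", function(object)
    object@sliceThickness)
#' @rdname pixelSize
setMethod("sliceThickness", "ClinicalVolume", function(object)
    object@sliceThickness)

#' @rdname pixelSize
setMethod("sliceInterval", "ReconstructionConfig", function(object)
    object@sliceInterval)
#' @rdname pixelSize
setMethod("sliceInterval", "ClinicalVolume", function(object)
    object@sliceInterval)

#' @rdname pixelSize
setMethod("offsetTriple", "ClinicalVolume", function(object) {
    o <- object@offset
    names(o) <- c("dx", "dy", "dz")
    o
})

#' Accessors for density measurements
#'
#' @param object a [DensityMeasurement-class].
#' @return `meanHU` the measured mean density (HU), `measuredFWHM` the
#'   profile FWHM (mm), `roiDiameter` the ROI diameter (mm), `roiPixelCount`
#'   the number of pixels averaged.
#' @export
setGeneric("meanHU", function(object) standardGeneric("meanHU"))

#' @rdname meanHU
#' @export
setGeneric("measuredFWHM", function(object) standardGeneric("measuredFWHM"))

#' @rdname meanHU
#' @export
setGeneric("roiDiameter", function(object) standardGeneric("roiDiameter"))

#' @rdname meanHU
#' @export
setGeneric("roiPixelCount", function(object) standardGeneric("roiPixelCount"))

#' @rdname meanHU
setMethod("meanHU", "DensityMeasurement", function(object) object@meanHU)
#' @rdname meanHU
setMethod("measuredFWHM", "DensityMeasurement", function(object) object@fwhm)
#' @rdname meanHU
setMethod("roiDiameter", "DensityMeasurement", function(object)
    object@roiDiameter)
#' @rdname meanHU
setMethod("roiPixelCount", "DensityMeasurement", function(object)
    object@nPixels)

#' Accessors for accuracy curves
#'
#' @param object an [AccuracyCurves-class].
#' @return `ctMax`/`ctMin` the per-diameter envelope HU; `curveDiameters`
#'   the diameter grid (mm); `measuredSeries` the per-offset series matrix;
#'   `measurementTable` the full data.frame of individual measurements.
#' @export
setGeneric("ctMax", function(object) standardGeneric("ctMax"))

#' @rdname ctMax
#' @export
setGeneric("ctMin", function(object) standardGeneric("ctMin"))

#' @rdname ctMax
#' @export
setGeneric("curveDiameters", function(object) standardGeneric("curveDiameters"))

#' @rdname ctMax
#' @export
setGeneric("measuredSeries", function(object) standardGeneric("measuredSeries"))

#' @rdname ctMax
#' @export
setGeneric("measurementTable", function(object)
    standardGeneric("measurementTable"))

#' @rdname ctMax
setMethod("ctMax", "AccuracyCurves", function(object) object@ctMax)
#' @rdname ctMax
setMethod("ctMin", "AccuracyCurves", function(object) object@ctMin)
#' @rdname ctMax
setMethod("curveDiameters", "AccuracyCurves", function(object)
    object@diameters)
#' @rdname ctMax
setMethod("measuredSeries", "AccuracyCurves", function(object) object@series)
#' @rdname ctMax
setMethod("measurementTable", "AccuracyCurves", function(object)
    object@measurements)

#' Blur a volume with the scanner response
#'
#' @param object an [ObjectVolume-class] (or a plain 3D array for
#'   low-level use).
#' @param psf a [KernelProfile2D-class] sampled at the volume pitch.
#' @param ssp an [AxialProfile-class] sampled at the volume pitch.
#' @param ... further arguments for methods (`pitch` and `background` for
#'   the array method).
#' @return a [BlurredVolume-class] (or a plain array for the array method).
#' @seealso [regridProfile()] to bring kernels onto the volume pitch.
#' @export
setGeneric("blurVolume", function(object, psf, ssp, ...)
    standardGeneric("blurVolume"))
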