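# S4 classes shared across the simulation pipeline.

#' @import methods
NULL

.UNIT_INTEGRAL_TOL <- 1e-8

# ---- scanner response ------------------------------------------------------

#' Scanner resolution profiles
#'
#' `KernelProfile2D` holds the in-plane point spread function (PSF) of a CT
#' reconstruction kernel on a square, odd-sized grid with sampling pitch
#' `pitch` (mm per sample) and the symmetry center at the central sample.
#' `AxialProfile` holds a slice sensitivity profile (SSP) along the scan
#' axis, again odd-sized and centered. Both are stored normalized to unit
#' discrete integral (`sum(values) * pitch^d == 1`), the property that makes
#' convolution preserve Hounsfield units in uniform regions.
#'
#' @slot values numeric matrix (`KernelProfile2D`) or numeric vector
#'   (`AxialProfile`) of kernel amplitudes.
#' @slot pitch sampling pitch in mm.
#' @slot label human-readable identifier (e.g. `"smooth"`, `"standard"`).
#' @slot nominalThickness for `AxialProfile`, the nominal reconstructed
#'   slice thickness in mm (`NA` when unknown, e.g. a loaded tabulation
#'   without metadata).
#'
#' @seealso [gaussianPSF()], [edgeEnhancedPSF()], [gaussianSSP()],
#'   [kernelPreset()], [regridProfile()]
#' @name ScannerProfile-classes
#' @aliases KernelProfile2D-class AxialProfile-class ScannerProfile-class
#' @exportClass KernelProfile2D
#' @exportClass AxialProfile
setClass("ScannerProfile",
         representation("VIRTUAL",
                        values = "ANY",
                        pitch = "numeric",
                        label = "character"))

setClass("KernelProfile2D", contains = "ScannerProfile")

setValidity("KernelProfile2D", function(object) {
    v <- object@values
    p <- object@pitch
    if (!is.matrix(v) || !is.numeric(v))
        return("'values' must be a numeric matrix")
    if (nrow(v) != ncol(v))
        return("kernel grid must be square")
    if (nrow(v) %% 2L == 0L)
        return("kernel grid must be odd-sized (center on the central sample)")
    if (!all(is.finite(v)))
        return("kernel values must be finite")
    if (length(p) != 1L || !is.finite(p) || p <= 0)
        return("'pitch' must be a single positive number")
    if (abs(sum(v) * p^2 - 1) > .UNIT_INTEGRAL_TOL)
        return("kernel must have unit discrete integral (sum * pitch^2 == 1)")
    TRUE
})

setClass("AxialProfile", contains = "ScannerProfile",
         representation(nominalThickness = "numeric"),
         prototype(nominalThickness = NA_real_))

setValidity("AxialProfile", function(object) {
    v <- object@values
    p <- object@pitch
    if (!is.numeric(v) || !is.null(dim(v)))
        return("'values' must be a numeric vector")
    if (length(v) %% 2L == 0L)
        return("profile must have odd length (center on the central sample)")
    if (!all(is.finite(v)))
        return("profile values must be finite")
    if (length(p) != 1L || !is.finite(p) || p <= 0)
        return("'pitch' must be a single positive number")
    if (abs(sum(v) * p - 1) > .UNIT_INTEGRAL_TOL)
        return("profile must have unit discrete integral (sum * pitch == 1)")
    TRUE
})

# ---- fine-grid volumes -----------------------------------------------------

#' Fine-pitch object function of a spherical nodule
#'
#' A binary-valued voxel grid holding the unblurred object function
#' O(x, y, z): `densityIn` HU inside the sphere, `densityBg` HU outside.
#' Coordinates are continuous mm with the sphere center at `center`
#' (normally the origin, pinned to a voxel center); the voxel `(i, j, k)`
#' sits at `origin + (c(i, j, k) - 1) * pitch`.
#'
#' @slot values 3D numeric array of HU values.
#' @slot pitch isotropic sampling pitch in mm.
#' @slot origin mm coordinates of voxel `(1, 1, 1)`.
#' @slot center mm coordinates of the sphere center.
#' @slot diameter sphere diameter in mm.
#' @slot densityIn,densityBg HU inside/outside the sphere.
#'
#' @seealso [makeSphere()], [choosePitch()], [blurVolume()]
#' @name ObjectVolume-class
#' @aliases ObjectVolume-class
#' @exportClass ObjectVolume
setClass("ObjectVolume",
         representation(values = "array",
                        pitch = "numeric",
                        origin = "numeric",
                        center = "numeric",
                        diameter = "numeric",
                        densityIn = "numeric",
                        densityBg = "numeric"))

setValidity("ObjectVolume", function(object) {
    v <- object@values
    if (length(dim(v)) != 3L)
        return("'values' must be a 3D array")
    if (length(object@pitch) != 1L || object@pitch <= 0)
        return("'pitch' must be a single positive number")
    if (length(object@origin) != 3L || length(object@center) != 3L)
        return("'origin' and 'center' must be length-3 mm coordinates")
    two <- c(object@densityIn, object@densityBg)
    n <- length(v)
    sub <- if (n <= 2^24) v else
        v[seq.int(1L, n, by = max(1L, n %/% 2^22))]  # strided for huge grids
    if (!all(sub == two[1L] | sub == two[2L]))
        return("voxel values must be exactly densityIn or densityBg")
    TRUE
})

#' Blurred fine-grid CT image
#'
#' The image I(x, y, z) obtained by convolving an [ObjectVolume-class] with
#' the in-plane PSF and the axial SSP, on the same grid as its source.
#'
#' @slot values 3D numeric array of HU values.
#' @slot pitch isotropic sampling pitch in mm.
#' @slot origin mm coordinates of voxel `(1, 1, 1)`.
#' @slot center mm coordinates of the nodule center.
#' @slot provenance list with at least `psf`, `ssp` (kernel labels) and
#'   `diameter` of the source sphere.
#'
#' @seealso [blurVolume()], [resampleToClinical()]
#' @name BlurredVolume-class
#' @aliases BlurredVolume-class
#' @exportClass BlurredVolume
setClass("BlurredVolume",
         representation(values = "array",
                        pitch = "numeric",
                        origin = "numeric",
                        center = "numeric",
                        provenance = "list"))

setValidity("BlurredVolume", function(object) {
    if (length(dim(object@values)) != 3L)
        return("'values' must be a 3D array")
    if (length(object@pitch) != 1L || object@pitch <= 0)
        return("'pitch' must be a single positive number")
    if (length(object@origin) != 3L || length(object@center) != 3L)
        return("'origin' and 'center' must be length-3 mm coordinates")
    TRUE
})

# ---- clinical grid ---------------------------------------------------------

#' Clinical HRCT reconstruction geometry
#'
#' Field of view, matrix size, slice thickness and slice interval of the
#' clinical grid that the fine-pitch image is resampled onto. The in-plane
#' pixel size is `fov / matrixSize` (about 0.4 mm for a 200 mm FOV at
#' 512 x 512). The slice interval may be smaller than the slice thickness
#' (overlapping reconstruction) but never larger.
#'
#' @slot fov field of view in mm.
#' @slot matrixSize in-plane matrix size (samples per axis).
#' @slot sliceThickness nominal reconstructed slice thickness in mm.
#' @slot sliceInterval spacing of reconstructed slices in mm.
#' @slot kernelLabel reconstruction kernel identifier (informational).
#'
#' @seealso [reconstructionConfig()], [pixelSize()], [offsetSweep()]
#' @name ReconstructionConfig-class
#' @aliases ReconstructionConfig-class
#' @exportClass ReconstructionConfig
setClass("ReconstructionConfig",
         representation(fov = "numeric",
                        matrixSize = "integer",
                        sliceThickness = "numeric",
                        sliceInterval = "numeric",
                        kernelLabel = "character"))

setValidity("ReconstructionConfig", function(object) {
    if (object@fov <= 0) return("'fov' must be positive")
    if (object@matrixSize < 1L) return("'matrixSize' must be >= 1")
    if (object@sliceThickness <= 0)
        return("'sliceThickness' must be positive")
    if (object@sliceInterval <= 0 ||
        object@sliceInterval > object@sliceThickness + 1e-12)
        return("require 0 < sliceInterval <= sliceThickness")
    TRUE
})

#' Resampled clinical HRCT volume
#'
#' The volume Id obtained by trilinear resampling of a
#' [BlurredVolume-class] at clinical pixel size and slice interval, with a
#' controlled offset `(dx, dy, dz)` between the nodule center and the
#' nearest voxel center. Axis coordinates `xs`, `ys`, `zs` are mm relative
#' to the nodule center, so the voxel nearest the center sits at `offset`.
#'
#' @slot values 3D numeric array of HU values, dims
#'   `(length(xs), length(ys), length(zs))`.
#' @slot pixelSize in-plane sampling interval in mm.
#' @slot sliceThickness,sliceInterval z geometry in mm.
#' @slot offset length-3 numeric `(dx, dy, dz)` in mm.
#' @slot xs,ys,zs voxel-center coordinates in mm (nodule center at 0).
#' @slot kernelLabel reconstruction kernel identifier.
#'
#' @seealso [resampleToClinical()], [measureNodule()]
#' @name ClinicalVolume-class
#' @aliases ClinicalVolume-class
#' @exportClass ClinicalVolume
setClass("ClinicalVolume",
         representation(values = "array",
                        pixelSize = "numeric",
                        sliceThickness = "numeric",
                        sliceInterval = "numeric",
                        offset = "numeric",
                        xs = "numeric",
                        ys = "numeric",
                        zs = "numeric",
                        kernelLabel = "character"))

setValidity("ClinicalVolume", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L)
        return("'values' must be a 3D array")
    if (!identical(d, c(length(object@xs), length(object@ys),
                        length(object@zs))))
        return("axis coordinate lengths must match array dims")
    if (length(object@offset) != 3L)
        return("'offset' must be length-3 (dx, dy, dz)")
    if (sum(object@zs < 0) < 3L || sum(object@zs > 0) < 3L)
        return("need at least 3 slices on each side of the central slice")
    TRUE
})

# ---- measurement and analysis ----------------------------------------------

#' Single ROI density measurement
#'
#' Result of the clinical densitometry rule on one resampled nodule image:
#' FWHM of the in-plane density profile through the nodule center, a
#' circular ROI of diameter 70% of that FWHM, and the mean HU over pixels
#' whose centers fall inside the ROI.
#'
#' @slot fwhm measured full width at half maximum in mm.
#' @slot roiDiameter ROI diameter in mm (0.7 x fwhm by default).
#' @slot meanHU mean HU over the ROI pixels.
#' @slot sliceIndex index of the measured (central) slice.
#' @slot nPixels number of pixel centers inside the ROI.
#' @slot offset the `(dx, dy, dz)` offset of the measured volume.
#' @slot meta list of additional context (kernel label, geometry).
#'
#' @seealso [measureNodule()]
#' @name DensityMeasurement-class
#' @aliases DensityMeasurement-class
#' @exportClass DensityMeasurement
setClass("DensityMeasurement",
         representation(fwhm = "numeric",
                        roiDiameter = "numeric",
                        meanHU = "numeric",
                        sliceIndex = "integer",
                        nPixels = "integer",
                        offset = "numeric",
                        meta = "list"))

setValidity("DensityMeasurement", function(object) {
    if (object@fwhm <= 0) return("'fwhm' must be positive")
    if (object@roiDiameter <= 0) return("'roiDiameter' must be positive")
    if (object@nPixels < 1L) return("'nPixels' must be >= 1")
    TRUE
})

#' Density-accuracy curves with CTmax/CTmin envelopes
#'
#' Measured nodule density as a function of true diameter, one series per
#' sub-voxel offset, together with the pointwise maximum (`CTmax`) and
#' minimum (`CTmin`) envelopes over the offsets. The gap between the two
#' envelopes quantifies the irreproducibility of a clinical density
#' measurement caused by the unknown nodule-center offset.
#'
#' @slot diameters strictly increasing true diameters in mm.
#' @slot series numeric matrix, `length(diameters)` rows x one column per
#'   offset, of measured mean HU.
#' @slot offsets data.frame of the swept offsets (columns dx, dy, dz in mm).
#' @slot ctMax,ctMin pointwise envelope HU per diameter.
#' @slot measurements data.frame of all individual measurements (one row
#'   per diameter x offset, with FWHM, ROI size and pixel count).
#' @slot config list describing the reconstruction configuration.
#'
#' @seealso [densityVsDiameter()], [envelopeVsInterval()]
#' @name AccuracyCurves-class
#' @aliases AccuracyCurves-class
#' @exportClass AccuracyCurves
setClass("AccuracyCurves",
         representation(diameters = "numeric",
                        series = "matrix",
                        offsets = "data.frame",
                        ctMax = "numeric",
                        ctMin = "numeric",
                        measurements = "data.frame",
                        config = "list"))

setValidity("AccuracyCurves", function(object) {
    nd <- length(object@diameters)
    if (is.unsorted(object@diameters, strictly = TRUE))
        return("'diameters' must be strictly increasing")
    if (nrow(object@series) != nd)
        return("'series' must have one row per diameter")
    if (ncol(object@series) != nrow(object@offsets))
        return("'series' must have one column per offset")
    if (length(object@ctMax) != nd || length(object@ctMin) != nd)
        return("envelopes must have one value per diameter")
    if (any(object@ctMin > object@ctMax + 1e-9))
        return("ctMin must not exceed ctMax")
    TRUE
})

# ---- lung image ------------------------------------------------------------

#' 2D lung CT slice for nodule insertion
#'
#' A single axial lung CT slice in HU, used as the host image when
#' compositing simulated nodules via the offset-and-add rule.
#'
#' @slot values numeric matrix of HU values.
#' @slot pixelSize in-plane pixel size in mm.
#'
#' @seealso [insertNodule()], [syntheticLungSlice()]
#' @name LungImage-class
#' @aliases LungImage-class
#' @exportClass LungImage
setClass("LungImage",
         representation(values = "matrix",
                        pixelSize = "numeric"))

setValidity("LungImage", function(object) {
    if (!is.numeric(object@values))
        return("'values' must be a numeric matrix")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        return("'pixelSize' must be a single positive number")
    TRUE
})
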