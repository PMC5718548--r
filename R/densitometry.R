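# Clinical nodule densitometry: central slice, FWHM of the density profile
# through the center, and the 70%-of-FWHM circular ROI.

#' @include AllClasses.R AllGenerics.R
NULL

#' Index of the axial slice nearest the nodule center
#'
#' Returns the index of the slice whose z coordinate minimizes the distance
#' to the nodule center; an equidistant tie (dz equal to half the slice
#' interval) is broken toward the lower index.
#'
#' @param vol a [ClinicalVolume-class].
#' @return integer slice index.
#' @export
centralSliceIndex <- function(vol) {
    stopifnot(is(vol, "ClinicalVolume"))
    ord <- order(abs(vol@zs), seq_along(vol@zs))
    ord[1L]
}

#' Measure the FWHM of the in-plane density profile
#'
#' Takes the single horizontal pixel row nearest the nodule center, finds
#' its peak, sets the half-maximum level midway between the known
#' background and the peak, and locates the outermost half-maximum
#' crossing on each side of the peak by linear interpolation between the
#' bracketing pixels (robust to the ringing of edge-enhancing kernels).
#'
#' @param image numeric matrix, one axial slice (x by y).
#' @param xs,ys pixel-center coordinates of the slice in mm.
#' @param centerXY length-2 mm coordinates of the nodule center in the
#'   slice plane (default the origin).
#' @param background known background density in HU (the simulation
#'   controls it; -900 for lung).
#' @param contrastFloor minimum peak-above-background contrast in HU below
#'   which the nodule is reported unmeasurable.
#' @return the FWHM in mm.
#' @export
measureFWHM <- function(image, xs, ys, centerXY = c(0, 0),
                        background = -900, contrastFloor = 10) {
    stopifnot(is.matrix(image), nrow(image) == length(xs),
              ncol(image) == length(ys), length(centerXY) == 2L)
    if (centerXY[1L] < min(xs) - 1e-9 || centerXY[1L] > max(xs) + 1e-9 ||
        centerXY[2L] < min(ys) - 1e-9 || centerXY[2L] > max(ys) + 1e-9)
        stop("'centerXY' lies outside the image")
    j <- which.min(abs(ys - centerXY[2L]))
    .fwhmFromProfile(xs, image[, j], baseline = background,
                     contrastFloor = contrastFloor)
}

#' Mean density in a circular ROI
#'
#' Mean over the pixels whose centers lie within `roiDiameter / 2` of the
#' ROI center (pixel-center membership, as in routine clinical ROI tools).
#' If no pixel center qualifies, the single pixel nearest the center is
#' used.
#'
#' @inheritParams measureFWHM
#' @param roiDiameter ROI diameter in mm.
#' @return a list with elements `meanHU` and `nPixels`.
#' @export
roiMeanDensity <- function(image, xs, ys, centerXY = c(0, 0), roiDiameter) {
    stopifnot(is.matrix(image), nrow(image) == length(xs),
              ncol(image) == length(ys), roiDiameter > 0)
    if (centerXY[1L] < min(xs) - 1e-9 || centerXY[1L] > max(xs) + 1e-9 ||
        centerXY[2L] < min(ys) - 1e-9 || centerXY[2L] > max(ys) + 1e-9)
        stop("'centerXY' lies outside the image")
    d2 <- outer((xs - centerXY[1L])^2, (ys - centerXY[2L])^2, "+")
    sel <- d2 <= (roiDiameter / 2)^2
    if (!any(sel))
        sel[which.min(d2)] <- TRUE
    list(meanHU = mean(image[sel]), nPixels = sum(sel))
}

#' Measure nodule density with the clinical ROI rule
#'
#' Composes the full densitometry procedure on a resampled clinical
#' volume: pick the axial slice nearest the nodule center, measure the
#' FWHM of the density profile through the center, and average the pixels
#' inside a circular ROI of diameter `roiFraction * FWHM` (70% by
#' default) centered on the true (continuous) nodule center projected into
#' the slice. The measured mean HU is compared against the known true
#' density of the object function by the caller.
#'
#' @param vol a [ClinicalVolume-class].
#' @param background known background density in HU.
#' @param contrastFloor minimum measurable peak contrast in HU.
#' @param roiFraction ROI diameter as a fraction of the measured FWHM.
#' @return a [DensityMeasurement-class].
#' @examples
#' obj <- makeSphere(3, pitch = 0.1, margin = c(2, 2, 4))
#' bl <- blurVolume(obj, identityPSF(0.1), identitySSP(0.1))
#' cfg <- reconstructionConfig(200, 512, sliceThickness = 1)
#' m <- measureNodule(resampleToClinical(bl, cfg))
#' meanHU(m)    # -400: no blur, ROI strictly interior to the sphere
#' @export
measureNodule <- function(vol, background = -900, contrastFloor = 10,
                          roiFraction = 0.7) {
    stopifnot(is(vol, "ClinicalVolume"), roiFraction > 0)
    k <- centralSliceIndex(vol)
    sl <- vol@values[, , k]
    f <- measureFWHM(sl, vol@xs, vol@ys, c(0, 0), background, contrastFloor)
    roi <- roiMeanDensity(sl, vol@xs, vol@ys, c(0, 0),
                          roiDiameter = roiFraction * f)
    new("DensityMeasurement", fwhm = f, roiDiameter = roiFraction * f,
        meanHU = roi$meanHU, sliceIndex = as.integer(k),
        nPixels = as.integer(roi$nPixels), offset = vol@offset,
        meta = list(kernel = vol@kernelLabel,
                    sliceThickness = vol@sliceThickness,
                    sliceInterval = vol@sliceInterval,
                    pixelSize = vol@pixelSize,
                    background = background))
}
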