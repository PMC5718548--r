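# Compact show() methods.

#' @include AllClasses.R AllGenerics.R
NULL

setMethod("show", "KernelProfile2D", function(object) {
    cat("KernelProfile2D '", object@label, "': ",
        nrow(object@values), " x ", ncol(object@values),
        " samples at ", format(object@pitch), " mm pitch (extent ",
        format(profileExtent(object)), " mm)\n", sep = "")
    if (min(object@values) < 0)
        cat("  edge-enhancing (negative side lobes)\n")
})

setMethod("show", "AxialProfile", function(object) {
    cat("AxialProfile '", object@label, "': ", length(object@values),
        " samples at ", format(object@pitch), " mm pitch", sep = "")
    if (!is.na(object@nominalThickness))
        cat(", nominal thickness ", format(object@nominalThickness),
            " mm", sep = "")
    cat("\n")
})

setMethod("show", "ObjectVolume", function(object) {
    d <- dim(object@values)
    cat("ObjectVolume: ", object@diameter, " mm sphere (",
        object@densityIn, " HU in ", object@densityBg, " HU background)\n",
        "  grid ", paste(d, collapse = " x "), " at ",
        format(object@pitch), " mm pitch\n", sep = "")
})

setMethod("show", "BlurredVolume", function(object) {
    d <- dim(object@values)
    cat("BlurredVolume: grid ", paste(d, collapse = " x "), " at ",
        format(object@pitch), " mm pitch\n  psf=",
        object@provenance$psf %||% "?", ", ssp=",
        object@provenance$ssp %||% "?", ", source diameter=",
        format(object@provenance$diameter %||% NA), " mm\n", sep = "")
})

setMethod("show", "ReconstructionConfig", function(object) {
    cat("ReconstructionConfig: FOV ", object@fov, " mm / ",
        object@matrixSize, " matrix (pixel ",
        format(pixelSize(object), digits = 6), " mm), thickness ",
        object@sliceThickness, " mm, interval ", object@sliceInterval,
        " mm\n", sep = "")
})

setMethod("show", "ClinicalVolume", function(object) {
    d <- dim(object@values)
    cat("ClinicalVolume: ", paste(d, collapse = " x "), " voxels, pixel ",
        format(object@pixelSize, digits = 6), " mm, thickness ",
        object@sliceThickness, " mm, interval ", object@sliceInterval,
        " mm\n  offset (dx, dy, dz) = (",
        paste(format(object@offset, digits = 4), collapse = ", "),
        ") mm\n", sep = "")
})

setMethod("show", "DensityMeasurement", function(object) {
    cat("DensityMeasurement: mean ", format(object@meanHU, digits = 6),
        " HU over ", object@nPixels, " pixels\n  FWHM ",
        format(object@fwhm, digits = 4), " mm, ROI diameter ",
        format(object@roiDiameter, digits = 4), " mm, slice ",
        object@sliceIndex, ", offset (",
        paste(format(object@offset, digits = 4), collapse = ", "),
        ") mm\n", sep = "")
})

setMethod("show", "AccuracyCurves", function(object) {
    cat("AccuracyCurves: ", length(object@diameters), " diameters (",
        format(min(object@diameters)), "-", format(max(object@diameters)),
        " mm) x ", nrow(object@offsets), " offsets, kernel '",
        object@config$kernel %||% "?", "'\n  CTmax range [",
        paste(format(range(object@ctMax), digits = 6), collapse = ", "),
        "] HU, CTmin range [",
        paste(format(range(object@ctMin), digits = 6), collapse = ", "),
        "] HU\n", sep = "")
})

setMethod("show", "LungImage", function(object) {
    cat("LungImage: ", nrow(object@values), " x ", ncol(object@values),
        " pixels at ", format(object@pixelSize, digits = 6), " mm\n",
        sep = "")
})
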