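# Compositing simulated nodules into lung CT slices by the offset-and-add
# rule: shift the simulated image so its background is 0 HU, then add.

#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a lung image
#'
#' Wraps a 2D axial lung CT slice (HU values) with its pixel size.
#'
#' @param values numeric matrix of HU values.
#' @param pixelSize in-plane pixel size in mm.
#' @return a [LungImage-class].
#' @export
lungImage <- function(values, pixelSize) {
    if (!is.matrix(values)) values <- as.matrix(values)
    new("LungImage", values = values, pixelSize = as.numeric(pixelSize))
}

#' Synthetic lung-slice fixture
#'
#' A uniform aerated-lung field (-900 HU) crossed by a few soft-tissue
#' vessel-like strokes (-50 HU), deterministic and free of any clinical
#' data; convenient as a host image for [insertNodule()] examples and
#' tests.
#'
#' @param n image size in pixels (n x n).
#' @param pixelSize pixel size in mm.
#' @param background lung-field density in HU.
#' @param vesselHU stroke density in HU.
#' @return a [LungImage-class].
#' @examples
#' lung <- syntheticLungSlice()
#' range(voxelData(lung))
#' @export
syntheticLungSlice <- function(n = 160L, pixelSize = 200 / 512,
                               background = -900, vesselHU = -50) {
    stopifnot(n >= 32L)
    v <- matrix(background, n, n)
    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    ## three straight strokes of width ~2 px, fixed geometry
    d1 <- abs(ij$i - 0.35 * ij$j - 0.2 * n)
    d2 <- abs(ij$j - 0.15 * n)
    d3 <- abs((ij$i - 0.8 * n) + (ij$j - 0.7 * n))
    v[d1 < 1.5 | d2 < 1 | d3 < 1.5] <- vesselHU
    lungImage(v, pixelSize)
}

#' Extract the central axial nodule slice
#'
#' Convenience accessor returning the 2D HU matrix of the slice nearest
#' the nodule center of a resampled [ClinicalVolume-class] (the slice used
#' for densitometry and for insertion into a lung image).
#'
#' @param vol a [ClinicalVolume-class].
#' @return a numeric matrix.
#' @export
noduleSlice <- function(vol) {
    stopifnot(is(vol, "ClinicalVolume"))
    vol@values[, , centralSliceIndex(vol)]
}

#' Composite a simulated nodule into a lung CT slice
#'
#' Adds the background shift (900 HU, turning the simulated -900 HU lung
#' background into 0 HU) to the simulated nodule slice and adds the result
#' to the lung image at the requested position. Pixels where the simulated
#' background is exactly -900 HU are left unchanged; the insertion is
#' purely additive, so subtracting the same shifted patch recovers the
#' original image bit-exactly.
#'
#' @param lung a [LungImage-class].
#' @param nodule a 2D HU matrix with -900 HU background (e.g. from
#'   [noduleSlice()]), or a [ClinicalVolume-class] whose central slice is
#'   used (its pixel size must match the lung image).
#' @param position length-2 integer pixel coordinates (row, column) of the
#'   lung image where the nodule-patch center is placed.
#' @param backgroundShift HU added to the simulated image before the
#'   composite (900 for the standard -900 HU simulated background).
#' @return a [LungImage-class].
#' @examples
#' lung <- syntheticLungSlice()
#' patch <- matrix(-900, 5, 5); patch[3, 3] <- -400
#' out <- insertNodule(lung, patch, position = c(80, 80))
#' voxelData(out)[80, 80]   # -400 on a -900 background
#' @export
insertNodule <- function(lung, nodule, position, backgroundShift = 900) {
    stopifnot(is(lung, "LungImage"), length(position) == 2L)
    if (is(nodule, "ClinicalVolume")) {
        if (abs(nodule@pixelSize - lung@pixelSize) > 1e-9)
            stop("pixel-size mismatch: lung ", lung@pixelSize,
                 " mm vs nodule ", nodule@pixelSize,
                 " mm; resample before insertion")
        nodule <- noduleSlice(nodule)
    }
    stopifnot(is.matrix(nodule))
    patch <- nodule + backgroundShift
    pr <- nrow(patch); pc <- ncol(patch)
    i0 <- as.integer(round(position[1L])) - (pr - 1L) %/% 2L
    j0 <- as.integer(round(position[2L])) - (pc - 1L) %/% 2L
    i1 <- i0 + pr - 1L; j1 <- j0 + pc - 1L
    if (i0 < 1L || j0 < 1L || i1 > nrow(lung@values) ||
        j1 > ncol(lung@values))
        stop("nodule footprint exceeds the lung image bounds")
    v <- lung@values
    v[i0:i1, j0:j1] <- v[i0:i1, j0:j1] + patch
    lungImage(v, lung@pixelSize)
}
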