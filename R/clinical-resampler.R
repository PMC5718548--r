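# Resampling of the fine-pitch blurred image onto the clinical HRCT grid
# with a controlled nodule-center / voxel-center offset, and the offset and
# slice-interval sweeps.

#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a clinical reconstruction configuration
#'
#' @param fov field of view in mm (200 mm for targeted lung HRCT).
#' @param matrixSize in-plane matrix size (512 for HRCT).
#' @param sliceThickness nominal slice thickness in mm.
#' @param sliceInterval slice spacing in mm; values below the thickness
#'   describe overlapping reconstruction. Defaults to the thickness.
#' @param kernelLabel reconstruction kernel identifier (informational).
#' @return a [ReconstructionConfig-class].
#' @examples
#' cfg <- reconstructionConfig(200, 512, sliceThickness = 1)
#' pixelSize(cfg)      # 0.390625 mm, approximately 0.4 mm
#' @export
reconstructionConfig <- function(fov, matrixSize, sliceThickness,
                                 sliceInterval = sliceThickness,
                                 kernelLabel = NA_character_) {
    if (!.isCount(matrixSize))
        stop("'matrixSize' must be a positive integer")
    new("ReconstructionConfig", fov = as.numeric(fov),
        matrixSize = as.integer(matrixSize),
        sliceThickness = as.numeric(sliceThickness),
        sliceInterval = as.numeric(sliceInterval),
        kernelLabel = as.character(kernelLabel))
}

.validateOffset <- function(offset, p, s) {
    if (length(offset) != 3L || any(!is.finite(offset)))
        stop("'offset' must be a finite length-3 numeric (dx, dy, dz)")
    tol <- 1e-9
    if (offset[1L] < -tol || offset[1L] > p / 2 + tol ||
        offset[2L] < -tol || offset[2L] > p / 2 + tol)
        stop("in-plane offset out of range: require 0 <= dx, dy <= ",
             "pixelSize / 2 = ", format(p / 2, digits = 6), " mm")
    if (offset[3L] < -tol || offset[3L] > s / 2 + tol)
        stop("axial offset out of range: require 0 <= dz <= ",
             "sliceInterval / 2 = ", format(s / 2, digits = 6), " mm")
    invisible(offset)
}

# dz-stage of the trilinear resampling: interpolate the fine volume onto
# the clinical slice positions, leaving the fine in-plane grid. Shared by
# resampleToClinical() and the sweep drivers (which reuse one stack across
# all in-plane offsets at a fixed dz).
.zStage <- function(vol, zs) {
    d <- dim(vol@values)
    Wz <- .axisWeights(zs, vol@origin[3L], vol@pitch, d[3L])
    M <- matrix(vol@values, d[1L] * d[2L], d[3L]) %*% Wz
    array(M, c(d[1L], d[2L], length(zs)))
}

# In-plane stage: interpolate a z-resampled stack onto clinical pixel
# centers. stack dims (nx, ny, nzc).
.xyStage <- function(stack, vol, xs, ys) {
    d <- dim(stack)
    Wx <- .axisWeights(xs, vol@origin[1L], vol@pitch, d[1L])
    Wy <- .axisWeights(ys, vol@origin[2L], vol@pitch, d[2L])
    A <- crossprod(Wx, matrix(stack, d[1L], d[2L] * d[3L]))
    A <- array(A, c(length(xs), d[2L], d[3L]))
    A <- aperm(A, c(2L, 1L, 3L))
    B <- crossprod(Wy, matrix(A, d[2L], length(xs) * d[3L]))
    B <- array(B, c(length(ys), length(xs), d[3L]))
    aperm(B, c(2L, 1L, 3L))
}

# Clinical sample coordinates along one axis: off + i * step for all
# integers i that stay inside the source extent [lo, hi].
.sampleCoords <- function(off, step, lo, hi) {
    imin <- ceiling((lo - off) / step - 1e-9)
    imax <- floor((hi - off) / step + 1e-9)
    if (imax < imin) stop("volume too small for the clinical grid")
    off + (imin:imax) * step
}

#' Resample a blurred volume onto the clinical HRCT grid
#'
#' Trilinear interpolation of the fine-pitch image at clinical sample
#' points `x = dx + i * pixelSize`, `y = dy + j * pixelSize`,
#' `z = dz + k * sliceInterval` (i, j, k integer; coordinates relative to
#' the nodule center), so that the voxel center nearest the nodule center
#' sits at displacement `(dx, dy, dz)` from it. The offset must satisfy
#' `0 <= dx, dy <= pixelSize / 2` and `0 <= dz <= sliceInterval / 2`; every
#' attainable sub-voxel geometry is equivalent to one in those ranges.
#'
#' @param vol a [BlurredVolume-class] (an unblurred [ObjectVolume-class] is
#'   also accepted, e.g. with identity kernels).
#' @param cfg a [ReconstructionConfig-class].
#' @param offset length-3 numeric `(dx, dy, dz)` in mm.
#' @return a [ClinicalVolume-class].
#' @examples
#' obj <- makeSphere(2, pitch = 0.1, margin = c(2, 2, 4))
#' bl <- blurVolume(obj, identityPSF(0.1), identitySSP(0.1))
#' cfg <- reconstructionConfig(204.8, 512, sliceThickness = 1)
#' cv <- resampleToClinical(bl, cfg, offset = c(0, 0, 0))
#' dim(voxelData(cv))
#' @export
resampleToClinical <- function(vol, cfg, offset = c(0, 0, 0)) {
    if (is(vol, "ObjectVolume"))
        vol <- new("BlurredVolume", values = vol@values, pitch = vol@pitch,
                   origin = vol@origin, center = vol@center,
                   provenance = list(psf = "none", ssp = "none",
                                     diameter = vol@diameter,
                                     background = vol@densityBg))
    stopifnot(is(vol, "BlurredVolume"), is(cfg, "ReconstructionConfig"))
    p <- pixelSize(cfg)
    s <- cfg@sliceInterval
    .validateOffset(offset, p, s)
    d <- dim(vol@values)
    xr <- range(axisCoords(vol, "x"))
    yr <- range(axisCoords(vol, "y"))
    zr <- range(axisCoords(vol, "z"))
    xs <- .sampleCoords(offset[1L], p, xr[1L], xr[2L])
    ys <- .sampleCoords(offset[2L], p, yr[1L], yr[2L])
    zs <- .sampleCoords(offset[3L], s, zr[1L], zr[2L])
    stack <- .zStage(vol, zs)
    out <- .xyStage(stack, vol, xs, ys)
    new("ClinicalVolume", values = out, pixelSize = p,
        sliceThickness = cfg@sliceThickness, sliceInterval = s,
        offset = as.numeric(offset), xs = xs, ys = ys, zs = zs,
        kernelLabel = if (!is.na(cfg@kernelLabel)) cfg@kernelLabel
                      else (vol@provenance$psf %||% NA_character_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate the sub-voxel offset sweep
#'
#' Cartesian product of the offset increments used to expose the full
#' fluctuation of the measured density: `dx, dy` in `{0, p/4, p/2}` with
#' `p` the pixel size (a quarter-pixel increment, about 0.1 mm at a 200 mm
#' FOV), and `dz` from 0 to half the slice interval in steps of one-tenth
#' of the interval for 1.0 mm slice thickness or one-twentieth for 2.0 mm.
#' For other thicknesses the denominator scales as
#' `round(10 * thickness)` (with a note).
#'
#' @param cfg a [ReconstructionConfig-class].
#' @return a data.frame with columns `dx`, `dy`, `dz` (mm); 54 rows for the
#'   1.0 mm configuration.
#' @examples
#' cfg <- reconstructionConfig(200, 512, sliceThickness = 1)
#' nrow(offsetSweep(cfg))   # 3 x 3 x 6 = 54
#' @export
offsetSweep <- function(cfg) {
    stopifnot(is(cfg, "ReconstructionConfig"))
    p <- pixelSize(cfg)
    s <- cfg@sliceInterval
    th <- cfg@sliceThickness
    dxy <- c(0, p / 4, p / 2)
    n <- if (abs(th - 1) < 1e-9) 10L
         else if (abs(th - 2) < 1e-9) 20L
         else {
             nn <- max(2L, as.integer(round(10 * th)))
             message("offsetSweep: thickness ", th,
                     " mm has no stated dz increment; using interval/", nn)
             nn
         }
    dz <- (0:(n %/% 2L)) * (s / n)
    if (n %% 2L == 1L) dz <- c(dz, s / 2)   # bound included for odd n
    out <- expand.grid(dx = dxy, dy = dxy, dz = dz,
                       KEEP.OUT.ATTRS = FALSE)
    out <- out[order(out$dz, out$dy, out$dx), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Enumerate the slice-interval sweep
#'
#' Slice intervals from 50% to 100% of the slice thickness in 10% steps;
#' intervals below the thickness describe overlapping reconstruction.
#'
#' @param sliceThickness slice thickness in mm.
#' @return increasing numeric vector of intervals in mm, ending at the
#'   thickness.
#' @examples
#' intervalSweep(1)   # 0.5 0.6 0.7 0.8 0.9 1.0
#' intervalSweep(2)   # 1.0 1.2 1.4 1.6 1.8 2.0
#' @export
intervalSweep <- function(sliceThickness) {
    stopifnot(sliceThickness > 0)
    sliceThickness * c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
}
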