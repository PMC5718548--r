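# Separable blurring: 2D in-plane convolution with the PSF followed by 1D
# axial convolution with the SSP (their order is immaterial by
# commutativity of convolution).

#' @include AllClasses.R AllGenerics.R
NULL

# Dense rectangular matrix applying a full linear 1D convolution with
# kernel k to a length-n signal, restricted to the output indices `keep`
# (1-based positions in the grown 1 : n + length(k) - 1 range). Row s of
# the result is out[keep[s]] = sum_i x[i] * k[keep[s] - i + 1].
.convMatrix <- function(k, n, keep) {
    W <- matrix(0, length(keep), n)
    for (t in seq_along(k)) {
        i <- keep - t + 1L
        ok <- i >= 1L & i <= n
        if (any(ok))
            W[cbind(which(ok), i[ok])] <- k[t]
    }
    W
}

# Linear 2D convolution of every z-slice with a dense 2D kernel via its
# singular value decomposition: K = sum_r d_r u_r v_r', so the dense
# convolution is an exact sum of separable (per-axis) convolutions, each
# evaluated as a BLAS matrix product. Output restricted to the grown-range
# indices keepX/keepY; scaled by pitch^2 so that unit-integral kernels
# preserve HU. Exact (a reorganized direct sum), no transform round-off.
.conv2dSlices <- function(A, K, pitch, keepX = NULL, keepY = NULL) {
    d <- dim(A)
    kx <- nrow(K); ky <- ncol(K)
    if (is.null(keepX)) keepX <- seq_len(d[1L] + kx - 1L)
    if (is.null(keepY)) keepY <- seq_len(d[2L] + ky - 1L)
    if (kx == 1L && ky == 1L)
        return(A * (K[1L, 1L] * pitch^2))
    sv <- svd(K)
    rank <- which(sv$d > 1e-13 * sv$d[1L])
    out <- array(0, c(length(keepX), length(keepY), d[3L]))
    for (r in rank) {
        ux <- sv$u[, r] * sqrt(sv$d[r])
        vy <- sv$v[, r] * sqrt(sv$d[r])
        Wx <- .convMatrix(ux, d[1L], keepX)
        Wy <- .convMatrix(vy, d[2L], keepY)
        M <- Wx %*% matrix(A, d[1L], d[2L] * d[3L])
        M <- array(M, c(length(keepX), d[2L], d[3L]))
        M <- aperm(M, c(2L, 1L, 3L))
        M <- Wy %*% matrix(M, d[2L], length(keepX) * d[3L])
        M <- array(M, c(length(keepY), length(keepX), d[3L]))
        out <- out + aperm(M, c(2L, 1L, 3L))
    }
    out * pitch^2
}

# Linear 1D convolution along z, restricted to grown-range indices keepZ,
# as one dense matrix product (exact). Scaled by pitch.
.convZSlices <- function(B, k1, pitch, keepZ = NULL) {
    d <- dim(B)
    kz <- length(k1)
    if (is.null(keepZ)) keepZ <- seq_len(d[3L] + kz - 1L)
    if (kz == 1L)
        return(B * (k1 * pitch))
    Wz <- .convMatrix(k1, d[3L], keepZ)
    M <- matrix(B, d[1L] * d[2L], d[3L]) %*% t(Wz)
    array(M * pitch, c(d[1L], d[2L], length(keepZ)))
}

# Core engine: subtract the background so the residual is compactly
# supported, convolve only its bounding box (zero padding then equals
# truthful constant-background padding), and embed the grown support —
# clipped to the source grid — back into a background-valued array of the
# source shape. Exact at every grid point for objects wholly inside the
# grid.
.blurArray <- function(A, pitch, K, k1, background, bbox = NULL) {
    d <- dim(A)
    if (nrow(K) > d[1L] || ncol(K) > d[2L] || length(k1) > d[3L])
        stop("insufficient margin: kernel support is wider than the volume")
    bb <- if (is.null(bbox)) .nzRangeBg(A, background) else bbox
    if (is.null(bb))
        return(array(background, d))
    hx <- (nrow(K) - 1L) %/% 2L
    hy <- (ncol(K) - 1L) %/% 2L
    hz <- (length(k1) - 1L) %/% 2L
    sub <- A[bb$x[1L]:bb$x[2L], bb$y[1L]:bb$y[2L], bb$z[1L]:bb$z[2L],
             drop = FALSE] - background
    ## grown support starts at (bb - h) on each axis; clip to the grid and
    ## only evaluate the surviving rows/columns/slices
    sx <- bb$x[1L] - hx; sy <- bb$y[1L] - hy; sz <- bb$z[1L] - hz
    xo <- max(1L, sx):min(d[1L], sx + dim(sub)[1L] + 2L * hx - 1L)
    yo <- max(1L, sy):min(d[2L], sy + dim(sub)[2L] + 2L * hy - 1L)
    zo <- max(1L, sz):min(d[3L], sz + dim(sub)[3L] + 2L * hz - 1L)
    C <- .conv2dSlices(sub, K, pitch, keepX = xo - sx + 1L,
                       keepY = yo - sy + 1L)
    C <- .convZSlices(C, k1, pitch, keepZ = zo - sz + 1L)
    out <- array(background, d)
    out[xo, yo, zo] <- background + C
    out
}

# Per-axis index ranges of the voxels differing from the background.
.nzRangeBg <- function(A, background) {
    nz <- A != background
    d <- dim(nz)
    xy <- rowSums(nz, dims = 2L)
    xc <- rowSums(xy)
    if (!any(xc > 0)) return(NULL)
    yc <- colSums(xy)
    zc <- colSums(matrix(nz, d[1L] * d[2L], d[3L]))
    list(x = range(which(xc > 0)),
         y = range(which(yc > 0)),
         z = range(which(zc > 0)))
}

.checkKernelPitch <- function(pitch, psf, ssp) {
    if (abs(psf@pitch - pitch) > 1e-9 || abs(ssp@pitch - pitch) > 1e-9)
        stop("pitch mismatch between volume (", pitch, " mm) and kernels (",
             psf@pitch, " / ", ssp@pitch,
             " mm); regrid the profiles first (see regridProfile)")
}

#' @describeIn blurVolume blur a spherical object function; returns a
#'   [BlurredVolume-class] on the same grid, with constant
#'   background-density padding outside the grid (the physical surround of
#'   a lung nodule).
#' @export
setMethod("blurVolume", "ObjectVolume", function(object, psf, ssp) {
    .checkKernelPitch(object@pitch, psf, ssp)
    ## the sphere bounding box is known analytically
    R <- object@diameter / 2
    bbox <- if (object@densityIn == object@densityBg) NULL else {
        ax <- lapply(c("x", "y", "z"), function(a) {
            i <- match(a, c("x", "y", "z"))
            range(which(abs(axisCoords(object, a) - object@center[i]) <=
                        R + 1e-12))
        })
        names(ax) <- c("x", "y", "z")
        ax
    }
    res <- .blurArray(object@values, object@pitch, psf@values, ssp@values,
                      background = object@densityBg, bbox = bbox)
    new("BlurredVolume", values = res, pitch = object@pitch,
        origin = object@origin, center = object@center,
        provenance = list(psf = psf@label, ssp = ssp@label,
                          diameter = object@diameter,
                          background = object@densityBg))
})

#' @describeIn blurVolume low-level method for a plain 3D array;
#'   `pitch` gives the grid pitch in mm and `background` the constant
#'   padding value (default 0). Returns an array.
#' @param pitch grid pitch in mm (array method).
#' @param background constant padding value in HU (array method).
#' @export
setMethod("blurVolume", "array", function(object, psf, ssp, pitch,
                                          background = 0) {
    .checkKernelPitch(pitch, psf, ssp)
    .blurArray(object, pitch, psf@values, ssp@values, background)
})

#' Extract a 1D density profile along a grid axis
#'
#' Samples the volume along the chosen axis at the grid points of the
#' row/column/stack nearest the point `through` (mm coordinates relative to
#' the nodule center).
#'
#' @param vol an [ObjectVolume-class], [BlurredVolume-class] or
#'   [ClinicalVolume-class].
#' @param axis one of `"x"`, `"y"`, `"z"`.
#' @param through length-3 mm coordinates the profile passes through.
#' @return a data.frame with columns `position` (mm) and `value` (HU).
#' @examples
#' obj <- makeSphere(3, pitch = 0.06, margin = 1)
#' pr <- lineProfile(obj, "x")
#' range(pr$value)
#' @export
lineProfile <- function(vol, axis = c("x", "y", "z"),
                        through = c(0, 0, 0)) {
    axis <- match.arg(axis)
    stopifnot(length(through) == 3L)
    cx <- axisCoords(vol, "x")
    cy <- axisCoords(vol, "y")
    cz <- axisCoords(vol, "z")
    if (through[1L] < min(cx) - 1e-9 || through[1L] > max(cx) + 1e-9 ||
        through[2L] < min(cy) - 1e-9 || through[2L] > max(cy) + 1e-9 ||
        through[3L] < min(cz) - 1e-9 || through[3L] > max(cz) + 1e-9)
        stop("'through' lies outside the volume")
    v <- voxelData(vol)
    i <- which.min(abs(cx - through[1L]))
    j <- which.min(abs(cy - through[2L]))
    k <- which.min(abs(cz - through[3L]))
    switch(axis,
           x = data.frame(position = cx, value = v[, j, k]),
           y = data.frame(position = cy, value = v[i, , k]),
           z = data.frame(position = cz, value = v[i, j, ]))
}
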