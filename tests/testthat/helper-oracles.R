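# Independent oracles used across the test files.

# Brute-force dense 3D convolution with constant background padding: the
# direct shift-and-add sum over every kernel sample of the outer-product
# kernel PSF (x) SSP. Kept free of any package convolution code.
bruteBlur3D <- function(A, psf, ssp, pitch, background) {
    K2 <- profileValues(psf)
    k1 <- profileValues(ssp)
    kx <- nrow(K2); ky <- ncol(K2); kz <- length(k1)
    hx <- (kx - 1L) %/% 2L; hy <- (ky - 1L) %/% 2L; hz <- (kz - 1L) %/% 2L
    d <- dim(A)
    P <- array(background, d + 2L * c(hx, hy, hz))
    P[hx + seq_len(d[1L]), hy + seq_len(d[2L]), hz + seq_len(d[3L])] <- A
    out <- array(0, d)
    for (i in seq_len(kx)) {
        oi <- i - 1L - hx
        for (j in seq_len(ky)) {
            oj <- j - 1L - hy
            for (l in seq_len(kz)) {
                ol <- l - 1L - hz
                w <- K2[i, j] * k1[l]
                if (w == 0) next
                out <- out + w *
                    P[hx + seq_len(d[1L]) - oi,
                      hy + seq_len(d[2L]) - oj,
                      hz + seq_len(d[3L]) - ol]
            }
        }
    }
    out * pitch^3
}

# Closed form for the center value of a uniform ball of radius R and
# contrast delta over background, blurred by an isotropic 3D Gaussian of
# scale sigma (equal sigma on all three axes).
gaussBallCenter <- function(R, sigma, background, delta) {
    erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
    background + delta * (erf(R / (sigma * sqrt(2))) -
                          (R / sigma) * sqrt(2 / pi) *
                          exp(-R^2 / (2 * sigma^2)))
}

# Width of a sampled profile at a given fractional height (outermost
# linear-interpolated crossings), used to compare profile shapes.
widthAtFraction <- function(x, v, frac) {
    level <- frac * max(v)
    ge <- v >= level
    n <- length(v)
    li <- min(which(!ge[-n] & ge[-1]))
    ri <- max(which(ge[-n] & !ge[-1]))
    xl <- x[li] + (level - v[li]) / (v[li + 1] - v[li]) * (x[li + 1] - x[li])
    xr <- x[ri] + (level - v[ri]) / (v[ri + 1] - v[ri]) * (x[ri + 1] - x[ri])
    xr - xl
}

# Small helper: value of a fine volume at the voxel nearest given mm coords.
voxelAt <- function(vol, at = c(0, 0, 0)) {
    i <- which.min(abs(axisCoords(vol, "x") - at[1]))
    j <- which.min(abs(axisCoords(vol, "y") - at[2]))
    k <- which.min(abs(axisCoords(vol, "z") - at[3]))
    voxelData(vol)[i, j, k]
}
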