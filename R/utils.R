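# Internal numerical helpers.

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# FWHM of a sampled profile: half-maximum level is baseline + peak/2 above
# baseline; crossings located by linear interpolation between bracketing
# samples, taking the OUTERMOST crossing on each side of the peak so that
# ringing from edge-enhancing kernels (multiple crossings) does not shrink
# the width.
.fwhmFromProfile <- function(pos, val, baseline, contrastFloor = 0) {
    stopifnot(length(pos) == length(val), length(pos) >= 3L)
    peak <- max(val)
    ipk <- which.max(val)
    if (peak - baseline < contrastFloor)
        stop("unmeasurable nodule: peak contrast ",
             format(peak - baseline, digits = 4),
             " HU is below the contrast floor of ", contrastFloor, " HU")
    half <- baseline + (peak - baseline) / 2
    n <- length(val)
    ge <- val >= half
    left <- which(!ge[-n] & ge[-1])       # val[i] < half <= val[i+1]
    left <- left[left < ipk]
    right <- which(ge[-n] & !ge[-1])      # val[j] >= half > val[j+1]
    right <- right[right >= ipk]
    if (length(left) == 0L)
        stop("truncated profile: no half-maximum crossing left of the peak")
    if (length(right) == 0L)
        stop("truncated profile: no half-maximum crossing right of the peak")
    i <- min(left)
    j <- max(right)
    xl <- pos[i] + (half - val[i]) / (val[i + 1L] - val[i]) *
        (pos[i + 1L] - pos[i])
    xr <- pos[j] + (half - val[j]) / (val[j + 1L] - val[j]) *
        (pos[j + 1L] - pos[j])
    xr - xl
}

# Linear-interpolation weight matrix mapping values on a uniform source grid
# (origin, pitch, n samples) to arbitrary target coordinates. Returns a
# dense n x length(targets) matrix with at most two non-zeros per column.
# Exact lattice hits are snapped so that aligned resampling is lossless.
.axisWeights <- function(targets, origin, pitch, n) {
    u <- (targets - origin) / pitch + 1
    if (any(u < 1 - 1e-6) || any(u > n + 1e-6))
        stop("sampling outside volume support")
    u <- pmin(pmax(u, 1), n)
    i0 <- floor(u + 1e-9)
    i0 <- pmin(pmax(i0, 1), n - 1L)
    w <- u - i0
    w[w < 1e-9] <- 0
    w[w > 1 - 1e-9] <- 1
    W <- matrix(0, n, length(targets))
    W[cbind(i0, seq_along(targets))] <- 1 - w
    idx <- cbind(i0 + 1L, seq_along(targets))
    W[idx] <- W[idx] + w
    W
}

.isCount <- function(x) length(x) == 1L && is.finite(x) && x == round(x) && x > 0
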