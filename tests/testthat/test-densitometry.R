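# Densitometry: central slice, FWHM, circular ROI.

.clinVol <- function(diameter = 3, pitch = 0.05, psf = identityPSF(0.05),
                     ssp = identitySSP(0.05), offset = c(0, 0, 0),
                     thickness = 1, interval = thickness,
                     marginXY = 1.6) {
    obj <- makeSphere(diameter, pitch = pitch,
                      margin = c(marginXY, marginXY, 3.5 * thickness + 0.4
                                 - diameter / 2))
    bl <- blurVolume(obj, psf, ssp)
    cfg <- reconstructionConfig(200, 512, thickness, interval)
    resampleToClinical(bl, cfg, offset)
}

test_that("central slice selection minimizes |z| with lower-index ties", {
    cv <- .clinVol(offset = c(0, 0, 0))
    expect_equal(axisCoords(cv, "z")[centralSliceIndex(cv)], 0)
    cv2 <- .clinVol(offset = c(0, 0, 0.3))
    expect_equal(axisCoords(cv2, "z")[centralSliceIndex(cv2)], 0.3)
    # dz = interval/2: both neighbors equidistant; lower index wins
    cv3 <- .clinVol(offset = c(0, 0, 0.5))
    expect_equal(axisCoords(cv3, "z")[centralSliceIndex(cv3)], -0.5)
})

test_that("the central slice carries the in-plane peak for nonnegative kernels", {
    cv <- .clinVol(psf = gaussianPSF(0.6, 0.05),
                   ssp = gaussianSSP(1, 0.05, extent = 1.2),
                   offset = c(0, 0, 0.2))
    peaks <- apply(voxelData(cv), 3, max)
    expect_equal(which.max(peaks), centralSliceIndex(cv))
})

test_that("FWHM of simple profiles matches the analytic width", {
    # rectangle of width w: FWHM = w within one pixel
    xs <- seq(-5, 5, by = 0.25)
    ys <- seq(-2, 2, by = 0.25)
    img <- matrix(-900, length(xs), length(ys))
    img[abs(xs) <= 1.5, ] <- -400
    expect_lt(abs(measureFWHM(img, xs, ys) - 3), 0.25 + 1e-9)
    # sampled Gaussian: FWHM = 2 sqrt(2 log 2) sigma within one pixel
    sg <- 1.2
    img2 <- outer(exp(-xs^2 / (2 * sg^2)), rep(1, length(ys))) * 500 - 900
    expect_lt(abs(measureFWHM(img2, xs, ys) - 2 * sqrt(2 * log(2)) * sg),
              0.25)
})

test_that("flat or truncated profiles are rejected", {
    xs <- seq(-5, 5, by = 0.25)
    ys <- seq(-2, 2, by = 0.25)
    flat <- matrix(-900, length(xs), length(ys))
    expect_error(measureFWHM(flat, xs, ys), "unmeasurable")
    # peak on the edge: no left crossing
    ramp <- matrix(rep(seq(-900, -300, length.out = length(xs)),
                       length(ys)), length(xs))
    expect_error(measureFWHM(ramp, xs, ys), "truncated")
    expect_error(measureFWHM(flat, xs, ys, centerXY = c(50, 0)), "outside")
})

test_that("ROI mean matches exhaustive pixel-center enumeration", {
    set.seed(3)
    xs <- seq(-4, 4, by = 0.4)
    ys <- seq(-4, 4, by = 0.4)
    img <- matrix(rnorm(length(xs) * length(ys), -600, 100), length(xs))
    for (roiD in c(0.9, 2.0, 3.7)) {
        got <- roiMeanDensity(img, xs, ys, c(0.1, -0.2), roiD)
        sel <- vals <- NULL
        for (i in seq_along(xs)) for (j in seq_along(ys))
            if ((xs[i] - 0.1)^2 + (ys[j] + 0.2)^2 <= (roiD / 2)^2)
                vals <- c(vals, img[i, j])
        expect_equal(got$meanHU, mean(vals))
        expect_equal(got$nPixels, length(vals))
    }
    # uniform image: mean is the constant
    u <- matrix(-555, length(xs), length(ys))
    expect_equal(roiMeanDensity(u, xs, ys, c(0, 0), 2)$meanHU, -555)
    # ROI smaller than a pixel: nearest-pixel fallback
    tiny <- roiMeanDensity(img, xs, ys, c(0.15, 0.05), 0.1)
    expect_equal(tiny$nPixels, 1L)
    expect_equal(tiny$meanHU, img[which.min(abs(xs - 0.15)),
                                  which.min(abs(ys - 0.05))])
})

test_that("identity-response measurement recovers the true density exactly", {
    m <- measureNodule(.clinVol(diameter = 3))
    expect_lt(abs(meanHU(m) + 400), 1e-9)
    expect_equal(roiDiameter(m), 0.7 * measuredFWHM(m))
    expect_gte(roiPixelCount(m), 1L)
})

test_that("maximum offset never measures above the centered case", {
    psf <- gaussianPSF(0.8, 0.05)
    ssp <- gaussianSSP(1, 0.05, extent = 1.2)
    p <- 200 / 512
    m0 <- measureNodule(.clinVol(2, psf = psf, ssp = ssp, marginXY = 3.5,
                                 offset = c(0, 0, 0)))
    m1 <- measureNodule(.clinVol(2, psf = psf, ssp = ssp, marginXY = 3.5,
                                 offset = c(p / 2, p / 2, 0.5)))
    expect_lte(meanHU(m1), meanHU(m0))
})

test_that("partial-volume underestimation shrinks with diameter", {
    psf <- gaussianPSF(0.8, 0.05)
    ssp <- gaussianSSP(1, 0.05, extent = 1.2)
    err <- vapply(c(1, 2, 4), function(d) {
        abs(meanHU(measureNodule(.clinVol(d, psf = psf, ssp = ssp,
                                          marginXY = 3.5))) + 400)
    }, 0)
    expect_true(all(diff(err) < 0))
})

test_that("measured mean always lies within the slice value range", {
    cv <- .clinVol(2, psf = gaussianPSF(0.8, 0.05),
                   ssp = gaussianSSP(1, 0.05, extent = 1.2),
                   marginXY = 3.5, offset = c(0.1, 0.05, 0.2))
    m <- measureNodule(cv)
    sl <- voxelData(cv)[, , m@sliceIndex]
    expect_gte(meanHU(m), min(sl))
    expect_lte(meanHU(m), max(sl))
})
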