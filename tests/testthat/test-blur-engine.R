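# Blur engine: separable convolution against independent oracles.

test_that("identity kernels leave the volume unchanged", {
    obj <- makeSphere(2, pitch = 0.1, margin = 0.5)
    bl <- blurVolume(obj, identityPSF(0.1), identitySSP(0.1))
    expect_identical(voxelData(bl), voxelData(obj))
    expect_equal(bl@provenance$diameter, 2)
})

test_that("constant volumes are preserved by any normalized kernel pair", {
    # exercise the full convolution path: constant -900 field declared
    # against a 0 background, checked away from the (zero-padded) edges
    A <- array(-900, c(41, 41, 35))
    ssp <- gaussianSSP(1, 0.1, extent = 1)
    for (psf in list(gaussianPSF(0.6, 0.1),
                     edgeEnhancedPSF(0.6, 0.2, 0.1))) {
        bl <- blurVolume(A, psf, ssp, pitch = 0.1, background = 0)
        hx <- (nrow(profileValues(psf)) - 1) / 2
        hz <- (length(profileValues(ssp)) - 1) / 2
        core <- bl[(hx + 1):(41 - hx), (hx + 1):(41 - hx),
                   (hz + 1):(35 - hz)]
        expect_lt(max(abs(core + 900)), 1e-6)
    }
    # and the high-level contract: a uniform object stays uniform
    obj <- makeSphere(1.5, pitch = 0.1, margin = 1.2,
                      densityIn = -900, densityBg = -900)
    bl <- blurVolume(obj, gaussianPSF(0.6, 0.1), ssp)
    expect_lt(max(abs(voxelData(bl) + 900)), 1e-6)
})

test_that("blur agrees with brute-force dense 3D convolution within 1e-9", {
    # small grid (<= 41^3), modest kernels; oracle is a direct sum
    obj <- makeSphere(1.6, pitch = 0.1, margin = 1.1)
    expect_lte(max(dim(voxelData(obj))), 41L)
    psf <- suppressWarnings(gaussianPSF(0.5, 0.1, extent = 0.5))
    ssp <- gaussianSSP(0.8, 0.1, extent = 0.8)
    bl <- blurVolume(obj, psf, ssp)
    oracle <- bruteBlur3D(voxelData(obj), psf, ssp, 0.1, background = -900)
    expect_lt(max(abs(voxelData(bl) - oracle)), 1e-9)
    # the same through the low-level array interface, edge kernel
    psf2 <- suppressWarnings(edgeEnhancedPSF(0.5, 0.2, 0.1, extent = 0.7))
    bl2 <- blurVolume(voxelData(obj), psf2, ssp, pitch = 0.1,
                      background = -900)
    expect_lt(max(abs(bl2 - bruteBlur3D(voxelData(obj), psf2, ssp, 0.1,
                                        -900))), 1e-9)
})

test_that("Gaussian-blurred sphere center matches the closed form", {
    # equal-sigma PSF and SSP make the 3D response an isotropic Gaussian;
    # the center value of a blurred ball then has a closed form
    fw <- 0.8
    R <- 0.75
    pitch <- R / 50
    obj <- makeSphere(2 * R, pitch = pitch, margin = 2.5)
    bl <- blurVolume(obj, gaussianPSF(fw, pitch),
                     gaussianSSP(fw, pitch, extent = 2 * fw))
    expected <- gaussBallCenter(R, fw / (2 * sqrt(2 * log(2))),
                                background = -900, delta = 500)
    expect_lt(abs(voxelAt(bl) - expected), 0.5)
})

test_that("in-plane and axial convolution commute", {
    obj <- makeSphere(1.4, pitch = 0.1, margin = 1)
    psf <- suppressWarnings(gaussianPSF(0.5, 0.1, extent = 0.6))
    ssp <- gaussianSSP(0.7, 0.1, extent = 0.7)
    A <- voxelData(obj) + 900                  # compact support, zero bg
    xyFirst <- noduleSim:::.convZSlices(
        noduleSim:::.conv2dSlices(A, profileValues(psf), 0.1),
        profileValues(ssp), 0.1)
    zFirst <- noduleSim:::.conv2dSlices(
        noduleSim:::.convZSlices(A, profileValues(ssp), 0.1),
        profileValues(psf), 0.1)
    expect_lt(max(abs(xyFirst - zFirst)), 1e-9)
})

test_that("blurring is linear in the object", {
    set.seed(11)
    A1 <- array(runif(17 * 17 * 15), c(17, 17, 15))
    A2 <- array(runif(17 * 17 * 15), c(17, 17, 15))
    psf <- suppressWarnings(gaussianPSF(0.4, 0.1, extent = 0.4))
    ssp <- gaussianSSP(0.5, 0.1, extent = 0.5)
    lhs <- blurVolume(2 * A1 - 3 * A2, psf, ssp, pitch = 0.1,
                      background = 0)
    rhs <- 2 * blurVolume(A1, psf, ssp, pitch = 0.1, background = 0) -
        3 * blurVolume(A2, psf, ssp, pitch = 0.1, background = 0)
    expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("nonnegative kernels keep values inside the density range and
           the center value grows with diameter", {
    psf <- gaussianPSF(0.8, 0.05)
    ssp <- gaussianSSP(1, 0.05, extent = 1.2)
    centers <- vapply(c(1, 2, 3), function(d) {
        bl <- blurVolume(makeSphere(d, pitch = 0.05, margin = 2.6),
                         psf, ssp)
        expect_gte(min(voxelData(bl)), -900 - 1e-9)
        expect_lte(max(voxelData(bl)), -400 + 1e-9)
        voxelAt(bl)
    }, 0)
    expect_true(all(diff(centers) > 0))
})

test_that("kernels wider than the volume are rejected", {
    obj <- makeSphere(1, pitch = 0.1, margin = 0.3)
    expect_error(blurVolume(obj, gaussianPSF(2, 0.1), identitySSP(0.1)),
                 "insufficient margin")
})

test_that("pitch mismatches between volume and kernels are rejected", {
    obj <- makeSphere(1, pitch = 0.1, margin = 0.5)
    expect_error(blurVolume(obj, gaussianPSF(0.5, 0.05), identitySSP(0.1)),
                 "regrid")
})

test_that("line profiles have the expected geometry", {
    obj <- makeSphere(3, pitch = 0.05, margin = 1)
    pr <- lineProfile(obj, "x")
    w <- diff(range(pr$position[pr$value == -400]))
    expect_lt(abs(w - 3), 2 * 0.05 + 1e-9)      # rectangle of width d
    far <- lineProfile(obj, "x", through = c(0, 2, 0))
    expect_true(all(far$value == -900))
    bl <- blurVolume(obj, gaussianPSF(0.6, 0.05),
                     gaussianSSP(0.8, 0.05, extent = 0.9))
    pb <- lineProfile(bl, "x")
    expect_lt(max(abs(pb$value - rev(pb$value))), 1e-6)   # symmetric
    expect_error(lineProfile(obj, "x", through = c(0, 50, 0)), "outside")
})
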