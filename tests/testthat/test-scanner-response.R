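# Scanner response: construction, normalization, regridding, CSV IO.

test_that("every constructed profile has unit discrete integral", {
    cases <- list(gaussianPSF(0.8, 0.02), gaussianPSF(1.2, 0.05),
                  edgeEnhancedPSF(0.6, 0.15, 0.03),
                  edgeEnhancedPSF(0.5, 0.4, 0.05, sigmaRatio = 3),
                  identityPSF(0.04))
    for (k in cases)
        expect_lt(abs(sum(profileValues(k)) * profilePitch(k)^2 - 1), 1e-9)
    cases1d <- list(gaussianSSP(1, 0.02), gaussianSSP(2, 0.05),
                    identitySSP(0.1))
    for (k in cases1d)
        expect_lt(abs(sum(profileValues(k)) * profilePitch(k) - 1), 1e-9)
})

test_that("Gaussian profiles have the analytic FWHM within one pitch", {
    expect_lt(abs(profileFWHM(gaussianPSF(0.8, 0.02)) - 0.8), 0.02)
    expect_lt(abs(profileFWHM(gaussianSSP(1.0, 0.02)) - 1.0), 0.02)
    expect_lt(abs(profileFWHM(gaussianSSP(2.0, 0.05)) - 2.0), 0.05)
    # property: holds for any pitch <= fwhm / 10
    for (p in c(0.08, 0.04, 0.01))
        expect_lt(abs(profileFWHM(gaussianPSF(0.8, p)) - 0.8), p)
})

test_that("a thicker SSP is wider at every fractional height", {
    s1 <- gaussianSSP(1, 0.02)
    s2 <- gaussianSSP(2, 0.02)
    x1 <- seq(-profileExtent(s1), profileExtent(s1), by = 0.02)
    x2 <- seq(-profileExtent(s2), profileExtent(s2), by = 0.02)
    for (f in c(0.1, 0.3, 0.5, 0.7, 0.9))
        expect_gt(widthAtFraction(x2, profileValues(s2), f),
                  widthAtFraction(x1, profileValues(s1), f))
})

test_that("edge-enhanced kernel has negative lobes and overshoots a step", {
    k <- edgeEnhancedPSF(0.6, 0.15, 0.05)
    expect_lt(min(profileValues(k)), 0)
    # blur a -900 -> -400 step edge: overshoot above -400 appears
    nx <- 160L; ny <- 121L
    A <- array(-900, c(nx, ny, 1L))
    A[81:160, , ] <- -400
    bl <- blurVolume(A, k, identitySSP(0.05), pitch = 0.05,
                     background = -900)
    expect_gt(max(bl[40:120, 61, 1]), -400)
})

test_that("edge-enhanced kernel converges to the Gaussian as undershoot -> 0", {
    g <- gaussianPSF(0.6, 0.05)
    e <- edgeEnhancedPSF(0.6, 1e-7, 0.05)
    expect_lt(max(abs(profileValues(e) - profileValues(g))), 1e-6)
})

test_that("invalid kernel parameters are rejected", {
    expect_error(gaussianPSF(0.8, 0.02, extent = 0.5), "truncat")
    expect_error(edgeEnhancedPSF(0.6, 1.2, 0.05), "between 0 and 1")
    expect_error(edgeEnhancedPSF(0.6, 0, 0.05), "between 0 and 1")
    expect_error(edgeEnhancedPSF(0.6, 0.2, 0.05, sigmaRatio = 0.9),
                 "sigmaRatio")
})

test_that("regridding preserves values on an identical grid", {
    s <- gaussianSSP(1, 0.05)
    s2 <- regridProfile(s, 0.05)
    expect_lt(max(abs(profileValues(s2) - profileValues(s))), 1e-12)
    k <- gaussianPSF(0.8, 0.05)
    k2 <- regridProfile(k, 0.05)
    expect_lt(max(abs(profileValues(k2) - profileValues(k))), 1e-12)
})

test_that("regridding is linear interpolation up to renormalization", {
    s <- gaussianSSP(1, 0.1)
    s2 <- regridProfile(s, 0.05)
    v1 <- profileValues(s)
    v2 <- profileValues(s2)
    c1 <- (length(v1) + 1L) / 2L
    c2 <- (length(v2) + 1L) / 2L
    scale <- v2[c2] / v1[c1]           # common renormalization factor
    # the sample midway between two source samples is their mean
    expect_equal(v2[c2 + 1L], scale * mean(v1[c1 + 0:1]), tolerance = 1e-9)
    expect_equal(v2[c2 + 3L], scale * mean(v1[c1 + 1:2]), tolerance = 1e-9)
    # unit integral restored
    expect_lt(abs(sum(v2) * 0.05 - 1), 1e-9)
})

test_that("regrid round trip on aligned grids reproduces the original", {
    for (prof in list(gaussianSSP(1, 0.1), gaussianPSF(0.8, 0.1))) {
        back <- regridProfile(regridProfile(prof, 0.05), 0.1)
        expect_lt(max(abs(profileValues(back) - profileValues(prof))), 1e-6)
    }
})

test_that("profile CSV round trip preserves values", {
    f <- tempfile(fileext = ".csv")
    s <- gaussianSSP(1, 0.05)
    writeProfileCSV(s, f)
    s2 <- readProfileCSV(f)
    expect_s4_class(s2, "AxialProfile")
    expect_lt(max(abs(profileValues(s2) - profileValues(s))), 1e-9)
    expect_equal(profilePitch(s2), 0.05)
    expect_equal(s2@nominalThickness, 1)
    k <- edgeEnhancedPSF(0.6, 0.15, 0.05)
    writeProfileCSV(k, f)
    k2 <- readProfileCSV(f)
    expect_s4_class(k2, "KernelProfile2D")
    expect_lt(max(abs(profileValues(k2) - profileValues(k))), 1e-9)
})

test_that("a loaded three-point spike profile is the identity kernel", {
    f <- tempfile(fileext = ".csv")
    p <- 0.1
    writeLines(c("position_mm,amplitude",
                 sprintf("%g,%g", c(-p, 0, p), c(0, 1 / p, 0))), f)
    s <- readProfileCSV(f)
    obj <- makeSphere(1, pitch = p, margin = 0.6)
    bl <- blurVolume(voxelData(obj), identityPSF(p), s, pitch = p,
                     background = -900)
    expect_identical(bl, voxelData(obj))
})

test_that("malformed profile files are rejected", {
    f <- tempfile(fileext = ".csv")
    writeLines(c("position_mm", "0.0", "0.1"), f)
    expect_error(readProfileCSV(f), "two columns")
    writeLines(c("position_mm,amplitude", "0,1", "-0.1,0"), f)
    expect_error(readProfileCSV(f), "increasing")
    writeLines(c("position_mm,amplitude", "-0.1,0", "0,NaN", "0.1,0"), f)
    expect_error(readProfileCSV(f), "NaN|non-numeric")
    writeLines(c("# grid2d", "0,1", "1,0"), f)
    expect_error(readProfileCSV(f), "pitch_mm")
})

test_that("radial tabulations symmetrize to an isotropic 2D kernel", {
    f <- tempfile(fileext = ".csv")
    sg <- 0.3
    r <- seq(0, 1.2, by = 0.05)
    writeLines(c("position_mm,amplitude",
                 sprintf("%.10g,%.10g", r, exp(-r^2 / (2 * sg^2)))), f)
    k <- readProfileCSV(f, type = "radial")
    expect_s4_class(k, "KernelProfile2D")
    v <- profileValues(k)
    n <- nrow(v)
    c0 <- (n + 1L) / 2L
    # isotropy: central row equals central column
    expect_equal(v[, c0], v[c0, ], tolerance = 1e-12)
    expect_lt(abs(sum(v) * profilePitch(k)^2 - 1), 1e-9)
    # close to the directly sampled Gaussian away from the truncation edge
    g <- suppressWarnings(
        gaussianPSF(2 * sqrt(2 * log(2)) * sg, 0.05, extent = 1.2))
    expect_equal(v[c0, ], profileValues(g)[c0, ], tolerance = 0.01)
})
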