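# Clinical resampling, offset sweeps and interval sweeps.

test_that("reconstruction geometry is validated and pixel size is exact", {
    cfg <- reconstructionConfig(200, 512, sliceThickness = 1)
    expect_equal(pixelSize(cfg), 200 / 512)
    expect_error(reconstructionConfig(200, 512, 1, sliceInterval = 1.2),
                 "sliceInterval")
    expect_error(reconstructionConfig(200, 512.5, 1), "integer")
})

test_that("lattice-aligned resampling passes fine-grid values through", {
    # pixel 204.8/512 = 0.4 mm = 4 x pitch; interval 1.0 = 10 x pitch
    pitch <- 0.1
    obj <- makeSphere(2, pitch = pitch, margin = c(1.5, 1.5, 3.9))
    bl <- blurVolume(obj, identityPSF(pitch), identitySSP(pitch))
    cfg <- reconstructionConfig(204.8, 512, sliceThickness = 1)
    cv <- resampleToClinical(bl, cfg, offset = c(0, 0, 0))
    xs <- axisCoords(cv, "x")
    fx <- axisCoords(bl, "x")
    ix <- match(round(xs / pitch), round(fx / pitch))
    iz <- match(round(axisCoords(cv, "z") / pitch),
                round(axisCoords(bl, "z") / pitch))
    expect_identical(voxelData(cv),
                     voxelData(bl)[ix, ix, iz])
})

test_that("off-lattice samples are linear interpolations of neighbors", {
    pitch <- 0.1
    obj <- makeSphere(2, pitch = pitch, margin = c(1.5, 1.5, 3.9))
    bl <- blurVolume(obj, gaussianPSF(0.5, pitch, extent = 1.5),
                     identitySSP(pitch))
    cfg <- reconstructionConfig(204.8, 512, sliceThickness = 1)
    cv <- resampleToClinical(bl, cfg, offset = c(0.05, 0, 0))
    # sample at x = 0.05 sits midway between fine nodes 0.0 and 0.1
    i <- which.min(abs(axisCoords(cv, "x") - 0.05))
    j <- which.min(abs(axisCoords(cv, "y")))
    k <- which.min(abs(axisCoords(cv, "z")))
    fi <- which.min(abs(axisCoords(bl, "x")))
    fj <- which.min(abs(axisCoords(bl, "y")))
    fk <- which.min(abs(axisCoords(bl, "z")))
    expect_equal(voxelData(cv)[i, j, k],
                 mean(voxelData(bl)[fi + 0:1, fj, fk]), tolerance = 1e-12)
    # convexity: interpolation never exceeds the source range
    expect_gte(min(voxelData(cv)), min(voxelData(bl)) - 1e-12)
    expect_lte(max(voxelData(cv)), max(voxelData(bl)) + 1e-12)
})

test_that("offsets outside the admissible ranges are rejected", {
    obj <- makeSphere(2, pitch = 0.1, margin = c(1.5, 1.5, 3.9))
    bl <- blurVolume(obj, identityPSF(0.1), identitySSP(0.1))
    cfg <- reconstructionConfig(204.8, 512, sliceThickness = 1)
    p <- pixelSize(cfg)
    expect_error(resampleToClinical(bl, cfg, offset = c(p, 0, 0)),
                 "in-plane offset")
    expect_error(resampleToClinical(bl, cfg, offset = c(0, -0.01, 0)),
                 "in-plane offset")
    expect_error(resampleToClinical(bl, cfg, offset = c(0, 0, 0.6)),
                 "axial offset")
})

test_that("center sampling captures the peak better than maximum offset", {
    pitch <- 0.05
    obj <- makeSphere(1.5, pitch = pitch, margin = c(1.6, 1.6, 3.9))
    bl <- blurVolume(obj, gaussianPSF(0.6, pitch),
                     gaussianSSP(1, pitch, extent = 1.2))
    cfg <- reconstructionConfig(200, 512, sliceThickness = 1)
    p <- pixelSize(cfg)
    cv0 <- resampleToClinical(bl, cfg, offset = c(0, 0, 0))
    cv1 <- resampleToClinical(bl, cfg, offset = c(p / 2, p / 2, 0.5))
    expect_gte(max(voxelData(cv0)), max(voxelData(cv1)))
})

test_that("offset sweep enumerates the stated increments", {
    cfg1 <- reconstructionConfig(200, 512, sliceThickness = 1)
    o1 <- offsetSweep(cfg1)
    expect_equal(nrow(o1), 54L)                       # 3 x 3 x 6
    expect_setequal(unique(o1$dx), c(0, 0.09765625, 0.1953125))
    expect_setequal(unique(o1$dy), c(0, 0.09765625, 0.1953125))
    expect_equal(sort(unique(o1$dz)), seq(0, 0.5, by = 0.1))
    p <- pixelSize(cfg1)
    expect_true(all(o1$dx >= 0 & o1$dx <= p / 2 + 1e-12))
    expect_true(all(o1$dy >= 0 & o1$dy <= p / 2 + 1e-12))
    expect_true(all(o1$dz >= 0 & o1$dz <= 0.5 + 1e-12))
    # 2 mm thickness: one-twentieth increments, 11 dz values
    cfg2 <- reconstructionConfig(200, 512, sliceThickness = 2)
    o2 <- offsetSweep(cfg2)
    expect_equal(nrow(o2), 99L)                       # 3 x 3 x 11
    expect_equal(max(o2$dz), 1)
    # overlap reconstruction: dz bounded by half the INTERVAL, not thickness
    cfgO <- reconstructionConfig(200, 512, sliceThickness = 2,
                                 sliceInterval = 1)
    expect_equal(max(offsetSweep(cfgO)$dz), 0.5)
    # unsupported thickness scales the denominator, with a note
    expect_message(o15 <- offsetSweep(
        reconstructionConfig(200, 512, sliceThickness = 1.5)), "increment")
    expect_equal(max(o15$dz), 0.75)
})

test_that("interval sweep spans 50-100% of the thickness in 10% steps", {
    expect_equal(intervalSweep(1), c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0))
    expect_equal(intervalSweep(2), c(1.0, 1.2, 1.4, 1.6, 1.8, 2.0))
    s <- intervalSweep(1.25)
    expect_true(all(diff(s) > 0))
    expect_equal(s[length(s)], 1.25)
})

test_that("denser slice spacing never worsens worst-case center capture", {
    pitch <- 0.05
    obj <- makeSphere(1.5, pitch = pitch, margin = c(1.6, 1.6, 3.9))
    bl <- blurVolume(obj, gaussianPSF(0.6, pitch),
                     gaussianSSP(1, pitch, extent = 1.2))
    worst <- vapply(c(1, 0.5), function(s) {
        cfg <- reconstructionConfig(200, 512, 1, sliceInterval = s)
        min(vapply(unique(offsetSweep(cfg)$dz), function(dz) {
            max(voxelData(resampleToClinical(bl, cfg, c(0, 0, dz))))
        }, 0))
    }, 0)
    expect_gte(worst[2], worst[1])     # interval 0.5 at least as good as 1.0
})
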