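# Sweep drivers over diameter, offset, kernel, slice thickness and slice
# interval; CTmax/CTmin envelopes and report tables.

#' @include AllClasses.R AllGenerics.R
NULL

# Pitch at which parametric presets are generated before being regridded to
# each object-function pitch (well below the finest object pitch of 15 um).
.REF_PITCH <- 0.005

# Grid margin for a sweep volume: in-plane the profile must reach the
# background beyond the blurred surface (PSF extent + 1 mm of background);
# axially the clinical samples reach 3.5 x the slice interval (<= thickness).
.sweepMargin <- function(diameter, psf, thickness, pitch) {
    mxy <- profileExtent(psf) + 1.0
    mz <- max(3.5 * thickness + 0.3 - diameter / 2, 3 * pitch, 0.2)
    c(mxy, mxy, mz)
}

# One measurement row, NA-filled on per-cell failure (logged as a warning
# with its sweep coordinates).
.measureCell <- function(vol, stack, zs, cfg, offset, densityBg,
                         contrastFloor, roiFraction) {
    xr <- range(axisCoords(vol, "x"))
    yr <- range(axisCoords(vol, "y"))
    p <- pixelSize(cfg)
    xs <- .sampleCoords(offset[1L], p, xr[1L], xr[2L])
    ys <- .sampleCoords(offset[2L], p, yr[1L], yr[2L])
    out <- .xyStage(stack, vol, xs, ys)
    cv <- new("ClinicalVolume", values = out, pixelSize = p,
              sliceThickness = cfg@sliceThickness,
              sliceInterval = cfg@sliceInterval,
              offset = as.numeric(offset), xs = xs, ys = ys, zs = zs,
              kernelLabel = cfg@kernelLabel)
    m <- measureNodule(cv, background = densityBg,
                       contrastFloor = contrastFloor,
                       roiFraction = roiFraction)
    c(fwhm = m@fwhm, roi = m@roiDiameter, mean = m@meanHU,
      n = as.numeric(m@nPixels))
}

# Full sweep: one blurred volume per diameter, reused across every interval
# and offset (offsets and intervals act only at the resampling stage).
# Returns the long measurement table.
.sweepAll <- function(psf, ssp, thickness, intervals, diameters,
                      fov = 200, matrixSize = 512L,
                      densityIn = -400, densityBg = -900,
                      contrastFloor = 10, roiFraction = 0.7,
                      verbose = FALSE) {
    stopifnot(length(diameters) >= 1L, length(intervals) >= 1L)
    kernelLabel <- profileLabel(psf)
    rows <- vector("list", 0L)
    for (d in diameters) {
        pitch <- choosePitch(d)
        psfr <- regridProfile(psf, pitch)
        sspr <- regridProfile(ssp, pitch)
        obj <- makeSphere(d, pitch, densityIn = densityIn,
                          densityBg = densityBg,
                          margin = .sweepMargin(d, psfr, thickness, pitch))
        if (verbose)
            message("diameter ", d, " mm: grid ",
                    paste(dim(obj@values), collapse = " x "),
                    " at ", pitch, " mm")
        bl <- blurVolume(obj, psfr, sspr)
        rm(obj)
        zr <- range(axisCoords(bl, "z"))
        nFail <- 0L
        nTot <- 0L
        for (s in intervals) {
            cfg <- reconstructionConfig(fov, matrixSize, thickness, s,
                                        kernelLabel = kernelLabel)
            offs <- offsetSweep(cfg)
            for (dz in unique(offs$dz)) {
                zs <- .sampleCoords(dz, s, zr[1L], zr[2L])
                stack <- .zStage(bl, zs)
                sub <- offs[offs$dz == dz, , drop = FALSE]
                for (r in seq_len(nrow(sub))) {
                    off <- as.numeric(sub[r, c("dx", "dy", "dz")])
                    nTot <- nTot + 1L
                    cell <- tryCatch(
                        .measureCell(bl, stack, zs, cfg, off, densityBg,
                                     contrastFloor, roiFraction),
                        error = function(e) {
                            warning("measurement failed at diameter ", d,
                                    " mm, interval ", s, " mm, offset (",
                                    paste(format(off, digits = 4),
                                          collapse = ", "),
                                    "): ", conditionMessage(e),
                                    call. = FALSE)
                            c(fwhm = NA_real_, roi = NA_real_,
                              mean = NA_real_, n = NA_real_)
                        })
                    if (is.na(cell[["mean"]])) nFail <- nFail + 1L
                    rows[[length(rows) + 1L]] <- data.frame(
                        diameter_mm = d, kernel = kernelLabel,
                        thickness_mm = thickness, interval_mm = s,
                        dx_mm = off[1L], dy_mm = off[2L], dz_mm = off[3L],
                        fwhm_mm = cell[["fwhm"]],
                        roi_diameter_mm = cell[["roi"]],
                        mean_hu = cell[["mean"]],
                        n_pixels = cell[["n"]])
                }
            }
        }
        if (nFail == nTot)
            stop("all measurements failed at diameter ", d, " mm")
        rm(bl)
        gc(FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.curvesFromTable <- function(df, config) {
    diameters <- sort(unique(df$diameter_mm))
    offs <- unique(df[, c("dx_mm", "dy_mm", "dz_mm")])
    offs <- offs[order(offs$dz_mm, offs$dy_mm, offs$dx_mm), , drop = FALSE]
    rownames(offs) <- NULL
    key <- function(dx, dy, dz) paste(signif(dx, 12), signif(dy, 12),
                                      signif(dz, 12))
    colKey <- key(offs$dx_mm, offs$dy_mm, offs$dz_mm)
    series <- matrix(NA_real_, length(diameters), nrow(offs))
    ri <- match(df$diameter_mm, diameters)
    ci <- match(key(df$dx_mm, df$dy_mm, df$dz_mm), colKey)
    series[cbind(ri, ci)] <- df$mean_hu
    names(offs) <- c("dx", "dy", "dz")
    new("AccuracyCurves", diameters = diameters, series = series,
        offsets = offs,
        ctMax = apply(series, 1L, max, na.rm = TRUE),
        ctMin = apply(series, 1L, min, na.rm = TRUE),
        measurements = df, config = config)
}

#' Measured density versus true diameter, with CTmax/CTmin envelopes
#'
#' Runs the full simulation pipeline for each (diameter, offset) pair under
#' one reconstruction configuration: fine-pitch sphere generation
#' ([choosePitch()], [makeSphere()]), blurring with the scanner response
#' ([blurVolume()]), clinical resampling ([resampleToClinical()]) and ROI
#' densitometry ([measureNodule()]). The per-offset series are retained
#' (the familiar bundle of gray curves), and the pointwise maximum/minimum
#' over offsets form the CTmax/CTmin envelopes.
#'
#' The blurred fine-grid volume is computed once per diameter and reused
#' across all offsets, which act only at the resampling stage.
#'
#' @param psf a [KernelProfile2D-class] (any pitch; regridded internally).
#' @param ssp an [AxialProfile-class]; its nominal thickness should match
#'   `sliceThickness(cfg)`.
#' @param cfg a [ReconstructionConfig-class].
#' @param diameters true sphere diameters in mm.
#' @param offsets data.frame of offsets (columns dx, dy, dz); defaults to
#'   [offsetSweep()] of `cfg`.
#' @param densityIn,densityBg true nodule and background densities in HU.
#' @param contrastFloor,roiFraction densitometry parameters, see
#'   [measureNodule()].
#' @param verbose print per-diameter progress.
#' @return an [AccuracyCurves-class].
#' @examples
#' \donttest{
#' cfg <- reconstructionConfig(200, 512, sliceThickness = 1)
#' psf <- kernelPreset("standard", pitch = 0.005)
#' ssp <- gaussianSSP(1, pitch = 0.005)
#' ac <- densityVsDiameter(psf, ssp, cfg, diameters = c(2, 4),
#'                         offsets = data.frame(dx = 0, dy = 0, dz = 0))
#' ctMax(ac)
#' }
#' @export
densityVsDiameter <- function(psf, ssp, cfg, diameters = seq(1, 8, by = 0.25),
                              offsets = NULL, densityIn = -400,
                              densityBg = -900, contrastFloor = 10,
                              roiFraction = 0.7, verbose = FALSE) {
    stopifnot(is(psf, "KernelProfile2D"), is(ssp, "AxialProfile"),
              is(cfg, "ReconstructionConfig"))
    if (!is.na(ssp@nominalThickness) &&
        abs(ssp@nominalThickness - cfg@sliceThickness) > 1e-9)
        warning("SSP nominal thickness (", ssp@nominalThickness,
                " mm) differs from the configured slice thickness (",
                cfg@sliceThickness, " mm)")
    if (is.null(offsets)) {
        df <- .sweepAll(psf, ssp, cfg@sliceThickness, cfg@sliceInterval,
                        diameters, fov = cfg@fov,
                        matrixSize = cfg@matrixSize, densityIn = densityIn,
                        densityBg = densityBg, contrastFloor = contrastFloor,
                        roiFraction = roiFraction, verbose = verbose)
    } else {
        df <- .sweepExplicit(psf, ssp, cfg, diameters, offsets, densityIn,
                             densityBg, contrastFloor, roiFraction, verbose)
    }
    .curvesFromTable(df, config = list(fov = cfg@fov,
                                       matrixSize = cfg@matrixSize,
                                       sliceThickness = cfg@sliceThickness,
                                       sliceInterval = cfg@sliceInterval,
                                       kernel = profileLabel(psf),
                                       densityIn = densityIn,
                                       densityBg = densityBg))
}

# Sweep with an explicit offset list (still grouped by dz for efficiency).
.sweepExplicit <- function(psf, ssp, cfg, diameters, offsets, densityIn,
                           densityBg, contrastFloor, roiFraction, verbose) {
    stopifnot(all(c("dx", "dy", "dz") %in% names(offsets)),
              nrow(offsets) >= 1L)
    kernelLabel <- profileLabel(psf)
    thickness <- cfg@sliceThickness
    s <- cfg@sliceInterval
    rows <- vector("list", 0L)
    for (d in diameters) {
        pitch <- choosePitch(d)
        psfr <- regridProfile(psf, pitch)
        sspr <- regridProfile(ssp, pitch)
        obj <- makeSphere(d, pitch, densityIn = densityIn,
                          densityBg = densityBg,
                          margin = .sweepMargin(d, psfr, thickness, pitch))
        if (verbose)
            message("diameter ", d, " mm: grid ",
                    paste(dim(obj@values), collapse = " x "),
                    " at ", pitch, " mm")
        bl <- blurVolume(obj, psfr, sspr)
        rm(obj)
        zr <- range(axisCoords(bl, "z"))
        for (dz in unique(offsets$dz)) {
            zs <- .sampleCoords(dz, s, zr[1L], zr[2L])
            stack <- .zStage(bl, zs)
            sub <- offsets[offsets$dz == dz, , drop = FALSE]
            for (r in seq_len(nrow(sub))) {
                off <- as.numeric(sub[r, c("dx", "dy", "dz")])
                cell <- .measureCell(bl, stack, zs, cfg, off, densityBg,
                                     contrastFloor, roiFraction)
                rows[[length(rows) + 1L]] <- data.frame(
                    diameter_mm = d, kernel = kernelLabel,
                    thickness_mm = thickness, interval_mm = s,
                    dx_mm = off[1L], dy_mm = off[2L], dz_mm = off[3L],
                    fwhm_mm = cell[["fwhm"]],
                    roi_diameter_mm = cell[["roi"]],
                    mean_hu = cell[["mean"]], n_pixels = cell[["n"]])
            }
        }
        rm(bl)
        gc(FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' CTmax/CTmin envelopes across the slice-interval sweep
#'
#' Repeats the density-versus-diameter sweep for every slice interval from
#' 50% to 100% of the slice thickness (overlapping reconstruction), with
#' the offset sweep re-enumerated per interval (the admissible dz range
#' shrinks with the interval). The blurred fine-grid volume is computed
#' once per diameter and shared across intervals and offsets.
#'
#' Under overlap reconstruction CTmax is unchanged while CTmin rises as the
#' interval shrinks: the worst-case axial offset of the central slice is
#' half the interval, so denser slice spacing can only improve the
#' worst-case capture of the nodule center.
#'
#' @inheritParams densityVsDiameter
#' @param sliceThickness nominal slice thickness in mm.
#' @param intervals slice intervals in mm (default [intervalSweep()]).
#' @param fov,matrixSize in-plane geometry.
#' @return a named list of [AccuracyCurves-class], one per interval (names
#'   `format(interval)`), in decreasing interval order.
#' @export
envelopeVsInterval <- function(psf, ssp, sliceThickness,
                               intervals = intervalSweep(sliceThickness),
                               diameters = seq(1, 8, by = 0.25),
                               fov = 200, matrixSize = 512L,
                               densityIn = -400, densityBg = -900,
                               contrastFloor = 10, roiFraction = 0.7,
                               verbose = FALSE) {
    stopifnot(is(psf, "KernelProfile2D"), is(ssp, "AxialProfile"))
    intervals <- sort(intervals, decreasing = TRUE)
    df <- .sweepAll(psf, ssp, sliceThickness, intervals, diameters,
                    fov = fov, matrixSize = matrixSize,
                    densityIn = densityIn, densityBg = densityBg,
                    contrastFloor = contrastFloor,
                    roiFraction = roiFraction, verbose = verbose)
    out <- lapply(intervals, function(s) {
        .curvesFromTable(df[abs(df$interval_mm - s) < 1e-12, , drop = FALSE],
                         config = list(fov = fov, matrixSize = matrixSize,
                                       sliceThickness = sliceThickness,
                                       sliceInterval = s,
                                       kernel = profileLabel(psf),
                                       densityIn = densityIn,
                                       densityBg = densityBg))
    })
    names(out) <- format(intervals, trim = TRUE)
    out
}

#' Run a full simulation experiment from a config file
#'
#' Reads a YAML configuration, runs the diameter/offset/interval sweeps for
#' every kernel and slice thickness, and writes one measurement table
#' (`series_<kernel>_t<thickness>.csv`, one row per diameter x interval x
#' offset) and one envelope table (`envelope_<kernel>_t<thickness>.csv`)
#' per combination. The pipeline is fully deterministic; identical
#' configurations produce byte-identical outputs.
#'
#' Recognized YAML keys: `kernels` (preset names among smooth / standard /
#' edge, or paths to profile CSV files, see [readProfileCSV()]),
#' `thicknesses_mm`, `intervals` (list of mm values or the string
#' `"sweep"` for the 50--100% sweep), `fov_mm`, `matrix`, `diameters_mm`,
#' `densities` (sub-keys `nodule_hu`, `background_hu`).
#'
#' @param configPath path to the YAML run configuration.
#' @param outDir output directory (created if needed).
#' @param verbose print progress.
#' @return invisibly, a character vector of the files written.
#' @export
runExperiment <- function(configPath, outDir, verbose = FALSE) {
    cfg <- yaml::read_yaml(configPath)
    required <- c("kernels", "thicknesses_mm", "fov_mm", "matrix",
                  "diameters_mm")
    missing <- setdiff(required, names(cfg))
    if (length(missing))
        stop("malformed config: missing key(s) ",
             paste(missing, collapse = ", "))
    diameters <- as.numeric(unlist(cfg$diameters_mm))
    if (length(diameters) == 0L || any(!is.finite(diameters)))
        stop("malformed config: 'diameters_mm' must be a non-empty ",
             "numeric list")
    densities <- cfg$densities
    densityIn <- as.numeric(densities$nodule_hu %||% -400)
    densityBg <- as.numeric(densities$background_hu %||% -900)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    for (kname in unlist(cfg$kernels)) {
        psf <- .resolveKernel(kname)
        for (th in as.numeric(unlist(cfg$thicknesses_mm))) {
            intervals <- cfg$intervals %||% "sweep"
            if (identical(intervals, "sweep")) {
                intervals <- intervalSweep(th)
            } else {
                intervals <- as.numeric(unlist(intervals))
                if (any(intervals <= 0 | intervals > th + 1e-12))
                    stop("malformed config: intervals must lie in ",
                         "(0, thickness]")
            }
            ssp <- gaussianSSP(th, .REF_PITCH)
            df <- .sweepAll(psf, ssp, th, intervals, diameters,
                            fov = as.numeric(cfg$fov_mm),
                            matrixSize = as.integer(cfg$matrix),
                            densityIn = densityIn, densityBg = densityBg,
                            verbose = verbose)
            tag <- sprintf("%s_t%s", profileLabel(psf),
                           format(th, trim = TRUE))
            seriesPath <- file.path(outDir, sprintf("series_%s.csv", tag))
            utils::write.csv(df, seriesPath, row.names = FALSE,
                             quote = FALSE)
            env <- do.call(rbind, lapply(sort(unique(df$interval_mm),
                                              decreasing = TRUE),
                                         function(s) {
                sub <- df[abs(df$interval_mm - s) < 1e-12, , drop = FALSE]
                dlev <- sort(unique(sub$diameter_mm))
                agg <- lapply(split(sub$mean_hu,
                                    factor(sub$diameter_mm, levels = dlev)),
                              range)
                data.frame(diameter_mm = dlev,
                           kernel = profileLabel(psf), thickness_mm = th,
                           interval_mm = s,
                           ct_max = vapply(agg, `[`, 0, 2L),
                           ct_min = vapply(agg, `[`, 0, 1L))
            }))
            rownames(env) <- NULL
            envPath <- file.path(outDir, sprintf("envelope_%s.csv", tag))
            utils::write.csv(env, envPath, row.names = FALSE, quote = FALSE)
            written <- c(written, seriesPath, envPath)
        }
    }
    invisible(written)
}

.resolveKernel <- function(name) {
    if (name %in% c("smooth", "standard", "edge"))
        return(kernelPreset(name, .REF_PITCH))
    if (file.exists(name)) {
        k <- readProfileCSV(name, type = "auto")
        if (!is(k, "KernelProfile2D"))
            k <- readProfileCSV(name, type = "radial")
        return(k)
    }
    stop("malformed config: unknown kernel '", name,
         "' (not a preset name or an existing profile CSV)")
}

#' @describeIn densityVsDiameter plot the per-offset series (gray), CTmax
#'   (bold) and CTmin (bold, dashed) of an [AccuracyCurves-class] against
#'   the true diameter.
#' @param x an [AccuracyCurves-class].
#' @param y ignored.
#' @param ... passed to [graphics::matplot()].
#' @export
setMethod("plot", signature(x = "AccuracyCurves", y = "missing"),
          function(x, y, ...) {
    graphics::matplot(x@diameters, x@series, type = "l", lty = 1,
                      col = "gray70",
                      xlab = "true diameter (mm)",
                      ylab = "measured density (HU)", ...)
    graphics::lines(x@diameters, x@ctMax, lwd = 2, col = "black")
    graphics::lines(x@diameters, x@ctMin, lwd = 2, lty = 2, col = "black")
    tru <- x@config$densityIn
    if (!is.null(tru))
        graphics::abline(h = tru, col = "gray40", lty = 3)
    invisible(x)
})
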