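# Construction, loading, normalization and regridding of the scanner
# response: the in-plane PSF and the axial SSP.

#' @include AllClasses.R AllGenerics.R
NULL

.sampledGrid <- function(extent, pitch) {
    m <- floor(extent / pitch + 1e-9)
    (-m:m) * pitch
}

.normalizeKernel2D <- function(v, pitch, label) {
    s <- sum(v) * pitch^2
    if (!is.finite(s) || s <= 0)
        stop("kernel '", label, "' has non-positive discrete integral")
    new("KernelProfile2D", values = v / s, pitch = pitch, label = label)
}

.normalizeAxial <- function(v, pitch, label, nominalThickness = NA_real_) {
    s <- sum(v) * pitch
    if (!is.finite(s) || s <= 0)
        stop("profile '", label, "' has non-positive discrete integral")
    new("AxialProfile", values = v / s, pitch = pitch, label = label,
        nominalThickness = nominalThickness)
}

#' Parametric in-plane PSFs
#'
#' `gaussianPSF` samples an isotropic 2D Gaussian of the given full width at
#' half maximum; it stands in for the measured PSF of a smoothing
#' reconstruction kernel. `edgeEnhancedPSF` samples a difference of
#' Gaussians, `(1 + a) G(sigma) - a G(sigmaRatio * sigma)`, whose negative
#' side lobes reproduce the overshoot behavior of high-resolution
#' (edge-enhancing) reconstruction kernels. Both are truncated at
#' `extent` (half-width) and normalized to unit discrete integral.
#'
#' `identityPSF` returns the single-sample identity kernel (`1 / pitch^2`),
#' which leaves any image unchanged under convolution; it is useful for
#' isolating resampling effects from blurring.
#'
#' @param fwhm full width at half maximum in mm (for `edgeEnhancedPSF`, of
#'   the primary positive Gaussian).
#' @param undershootFraction weight `a` in `(0, 1)` of the subtracted wide
#'   Gaussian; larger values give deeper negative lobes.
#' @param pitch sampling pitch in mm.
#' @param extent kernel half-width in mm at which the support is truncated
#'   (then renormalized). A warning is issued below `3 * fwhm`; values below
#'   `fwhm` are rejected as severe truncation.
#' @param sigmaRatio ratio of the subtracted to the primary Gaussian sigma.
#' @param label kernel identifier carried through provenance.
#' @return a [KernelProfile2D-class].
#' @examples
#' psf <- gaussianPSF(fwhm = 0.8, pitch = 0.02)
#' sum(profileValues(psf)) * profilePitch(psf)^2   # 1 by construction
#' edge <- edgeEnhancedPSF(fwhm = 0.6, undershootFraction = 0.15,
#'                         pitch = 0.02)
#' min(profileValues(edge)) < 0                    # negative side lobes
#' @seealso [kernelPreset()] for the shipped smooth/standard/edge presets,
#'   [gaussianSSP()] for the axial profile.
#' @export
gaussianPSF <- function(fwhm, pitch, extent = 3 * fwhm,
                        label = sprintf("gaussian-%.3g", fwhm)) {
    stopifnot(fwhm > 0, pitch > 0)
    if (extent < fwhm)
        stop("kernel extent ", extent, " mm truncates the profile (< fwhm)")
    if (extent < 3 * fwhm)
        warning("kernel extent below 3 * fwhm; tails are truncated")
    x <- .sampledGrid(extent, pitch)
    s <- .fwhmToSigma(fwhm)
    g <- exp(-x^2 / (2 * s^2))
    .normalizeKernel2D(outer(g, g), pitch, label)
}

#' @rdname gaussianPSF
#' @export
edgeEnhancedPSF <- function(fwhm, undershootFraction, pitch,
                            extent = 3 * fwhm, sigmaRatio = 2,
                            label = sprintf("edge-%.3g", fwhm)) {
    stopifnot(fwhm > 0, pitch > 0, sigmaRatio > 1)
    if (undershootFraction <= 0 || undershootFraction >= 1)
        stop("'undershootFraction' must lie strictly between 0 and 1")
    if (extent < fwhm)
        stop("kernel extent ", extent, " mm truncates the profile (< fwhm)")
    x <- .sampledGrid(extent, pitch)
    s1 <- .fwhmToSigma(fwhm)
    s2 <- sigmaRatio * s1
    g1 <- outer(exp(-x^2 / (2 * s1^2)), exp(-x^2 / (2 * s1^2)))
    g2 <- outer(exp(-x^2 / (2 * s2^2)), exp(-x^2 / (2 * s2^2)))
    g1 <- g1 / (sum(g1) * pitch^2)
    g2 <- g2 / (sum(g2) * pitch^2)
    v <- (1 + undershootFraction) * g1 - undershootFraction * g2
    c0 <- (length(x) + 1L) / 2L
    if (v[c0, c0] <= 0)
        stop("invalid kernel: parameters give a non-positive central value")
    .normalizeKernel2D(v, pitch, label)
}

#' @rdname gaussianPSF
#' @export
identityPSF <- function(pitch, label = "identity") {
    stopifnot(pitch > 0)
    new("KernelProfile2D", values = matrix(1 / pitch^2, 1L, 1L),
        pitch = pitch, label = label)
}

#' Parametric axial slice sensitivity profiles
#'
#' `gaussianSSP` samples a 1D Gaussian whose FWHM equals the nominal
#' reconstructed slice thickness, the usual idealization of a measured SSP.
#' `identitySSP` is the single-sample identity profile (`1 / pitch`).
#'
#' @param nominalThickness nominal slice thickness in mm (the profile FWHM).
#' @param pitch sampling pitch in mm.
#' @param extent profile half-width in mm at which the support is truncated.
#' @param label profile identifier.
#' @return an [AxialProfile-class] with unit discrete integral.
#' @examples
#' ssp <- gaussianSSP(nominalThickness = 1, pitch = 0.02)
#' sum(profileValues(ssp)) * profilePitch(ssp)     # 1 by construction
#' @export
gaussianSSP <- function(nominalThickness, pitch,
                        extent = 2 * nominalThickness,
                        label = sprintf("gaussian-ssp-%.3g", nominalThickness)) {
    stopifnot(nominalThickness > 0, pitch > 0)
    if (extent < nominalThickness)
        stop("profile extent ", extent, " mm truncates the SSP (< thickness)")
    x <- .sampledGrid(extent, pitch)
    s <- .fwhmToSigma(nominalThickness)
    .normalizeAxial(exp(-x^2 / (2 * s^2)), pitch, label, nominalThickness)
}

#' @rdname gaussianSSP
#' @export
identitySSP <- function(pitch, label = "identity") {
    stopifnot(pitch > 0)
    new("AxialProfile", values = 1 / pitch, pitch = pitch, label = label,
        nominalThickness = NA_real_)
}

#' Shipped reconstruction-kernel presets
#'
#' Three in-plane response presets emulating the behavior of typical CT
#' reconstruction kernels: `"smooth"` (a wide Gaussian, FWHM 1.2 mm, as for
#' heavy-smoothing abdominal kernels), `"standard"` (Gaussian, FWHM 0.8 mm,
#' standard lung kernels) and `"edge"` (difference of Gaussians with
#' negative side lobes, primary FWHM 0.6 mm, undershoot fraction 0.15, as
#' for high-resolution lung kernels). Smoothing presets produce monotone
#' partial-volume underestimation of small-nodule density; the edge preset
#' produces underestimation at small diameters, overestimation at
#' intermediate diameters, and convergence to the true density at large
#' diameters.
#'
#' @param name preset name.
#' @param pitch sampling pitch in mm.
#' @return a [KernelProfile2D-class].
#' @examples
#' psf <- kernelPreset("standard", pitch = 0.05)
#' profileLabel(psf)
#' @export
kernelPreset <- function(name = c("smooth", "standard", "edge"), pitch) {
    name <- match.arg(name)
    switch(name,
           smooth = gaussianPSF(1.2, pitch, label = "smooth"),
           standard = gaussianPSF(0.8, pitch, label = "standard"),
           edge = edgeEnhancedPSF(0.6, 0.15, pitch, label = "edge"))
}

#' Regrid a scanner profile by linear interpolation
#'
#' Resamples a PSF or SSP onto a grid of `targetPitch` centered on the
#' kernel center (linear interpolation per axis, which for the 2D kernel is
#' bilinear), then renormalizes to unit discrete integral. The target grid
#' never extends beyond the source support.
#'
#' @param profile a [KernelProfile2D-class] or [AxialProfile-class].
#' @param targetPitch desired sampling pitch in mm.
#' @return a profile of the same class at `targetPitch`.
#' @examples
#' ssp <- gaussianSSP(1, pitch = 0.05)
#' ssp2 <- regridProfile(ssp, 0.025)
#' profilePitch(ssp2)
#' @export
setGeneric("regridProfile", function(profile, targetPitch)
    standardGeneric("regridProfile"))

#' @rdname regridProfile
setMethod("regridProfile", "AxialProfile", function(profile, targetPitch) {
    stopifnot(targetPitch > 0)
    if (length(profile@values) == 1L)    # identity profile at any pitch
        return(new("AxialProfile", values = 1 / targetPitch,
                   pitch = targetPitch, label = profile@label,
                   nominalThickness = profile@nominalThickness))
    if (abs(targetPitch - profile@pitch) < 1e-12) {
        return(.normalizeAxial(profile@values, profile@pitch, profile@label,
                               profile@nominalThickness))
    }
    xs <- .sampledGrid(profileExtent(profile), profile@pitch)
    xt <- .sampledGrid(profileExtent(profile), targetPitch)
    if (max(xt) > max(xs) + 1e-9)
        stop("extrapolation: target grid extends beyond source support")
    v <- stats::approx(xs, profile@values, xout = xt)$y
    .normalizeAxial(v, targetPitch, profile@label, profile@nominalThickness)
})

#' @rdname regridProfile
setMethod("regridProfile", "KernelProfile2D", function(profile, targetPitch) {
    stopifnot(targetPitch > 0)
    if (length(profile@values) == 1L)    # identity kernel at any pitch
        return(new("KernelProfile2D",
                   values = matrix(1 / targetPitch^2, 1L, 1L),
                   pitch = targetPitch, label = profile@label))
    if (abs(targetPitch - profile@pitch) < 1e-12) {
        return(.normalizeKernel2D(profile@values, profile@pitch,
                                  profile@label))
    }
    xs <- .sampledGrid(profileExtent(profile), profile@pitch)
    xt <- .sampledGrid(profileExtent(profile), targetPitch)
    if (max(xt) > max(xs) + 1e-9)
        stop("extrapolation: target grid extends beyond source support")
    ## separable linear interpolation (bilinear): rows then columns
    half <- apply(profile@values, 2L, function(col)
        stats::approx(xs, col, xout = xt)$y)     # length(xt) x ncol(src)
    full <- apply(half, 1L, function(row)
        stats::approx(xs, row, xout = xt)$y)     # length(xt) x length(xt)
    .normalizeKernel2D(t(full), targetPitch, profile@label)
})

#' Measure the FWHM of a sampled profile
#'
#' Full width at half maximum of an [AxialProfile-class], or of the central
#' row of a [KernelProfile2D-class], with crossings located by linear
#' interpolation between the bracketing samples (baseline 0).
#'
#' @param profile a scanner profile.
#' @return the FWHM in mm.
#' @examples
#' profileFWHM(gaussianSSP(1, pitch = 0.02))   # close to 1 mm
#' @export
profileFWHM <- function(profile) {
    if (is(profile, "KernelProfile2D")) {
        v <- profile@values[, (ncol(profile@values) + 1L) / 2L]
    } else if (is(profile, "AxialProfile")) {
        v <- profile@values
    } else stop("'profile' must be a KernelProfile2D or AxialProfile")
    x <- .sampledGrid(profileExtent(profile), profile@pitch)
    .fwhmFromProfile(x, v, baseline = 0)
}

# ---- CSV interchange -------------------------------------------------------

#' Read and write profile CSV files
#'
#' The interchange format is plain CSV with `#`-prefixed comment lines. A 1D
#' (axial or radial) profile has one header line `position_mm,amplitude`
#' followed by two numeric columns on a uniform, strictly increasing
#' position grid. A dense 2D kernel grid is written as comma-separated
#' matrix rows preceded by comment headers `# pitch_mm=<v>` and
#' `# grid2d`. Loaded profiles are centered on the sample nearest position
#' zero and renormalized to unit discrete integral.
#'
#' `type = "radial"` interprets a two-column file as a radial PSF section
#' and rotationally symmetrizes it onto a square grid by nearest-radius
#' linear interpolation (amplitude 0 beyond the tabulated support), the
#' usual treatment of measured in-plane PSFs, which are isotropic to a good
#' approximation.
#'
#' @param path file path.
#' @param type `"auto"` (dense grids detected via the `# grid2d` marker,
#'   everything else read as axial), `"axial"`, `"radial"` or `"grid2d"`.
#' @param profile a profile to write.
#' @return `readProfileCSV` returns a [KernelProfile2D-class] or
#'   [AxialProfile-class]; `writeProfileCSV` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeProfileCSV(gaussianSSP(1, pitch = 0.05), f)
#' ssp <- readProfileCSV(f)
#' profilePitch(ssp)
#' @export
readProfileCSV <- function(path, type = c("auto", "axial", "radial", "grid2d")) {
    type <- match.arg(type)
    lines <- readLines(path)
    comments <- grep("^\\s*#", lines, value = TRUE)
    body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    pitchHeader <- NA_real_
    m <- regmatches(comments, regexec("pitch_mm\\s*=\\s*([0-9eE.+-]+)", comments))
    hits <- vapply(m, length, 1L) == 2L
    if (any(hits)) pitchHeader <- as.numeric(m[[which(hits)[1L]]][2L])
    thickHeader <- NA_real_
    m <- regmatches(comments,
                    regexec("nominal_thickness_mm\\s*=\\s*([0-9eE.+-]+)", comments))
    hits <- vapply(m, length, 1L) == 2L
    if (any(hits)) thickHeader <- as.numeric(m[[which(hits)[1L]]][2L])
    isGrid <- any(grepl("grid2d", comments))
    if (type == "grid2d" || (type == "auto" && isGrid))
        return(.readGrid2D(body, pitchHeader, path))
    .readTwoColumn(body, path, type, thickHeader)
}

.readGrid2D <- function(body, pitch, path) {
    if (is.na(pitch))
        stop("malformed input '", path, "': dense 2D grid without a ",
             "'# pitch_mm=<v>' header")
    rows <- lapply(strsplit(body, ","), function(r) as.numeric(trimws(r)))
    n <- unique(vapply(rows, length, 1L))
    if (length(n) != 1L)
        stop("malformed input '", path, "': ragged 2D grid")
    v <- do.call(rbind, rows)
    if (any(!is.finite(v)))
        stop("malformed input '", path, "': non-finite amplitudes")
    if (nrow(v) != ncol(v) || nrow(v) %% 2L == 0L)
        stop("malformed input '", path, "': 2D grid must be square and odd-sized")
    .normalizeKernel2D(v, pitch, label = basename(path))
}

.readTwoColumn <- function(body, path, type, thickHeader) {
    if (length(body) && !grepl("^[-+0-9.]", trimws(body[1L])))
        body <- body[-1L]                        # drop the one header line
    cells <- strsplit(body, ",")
    if (any(vapply(cells, length, 1L) != 2L))
        stop("malformed input '", path, "': expected two columns ",
             "(position_mm, amplitude)")
    pos <- as.numeric(vapply(cells, `[`, "", 1L))
    amp <- as.numeric(vapply(cells, `[`, "", 2L))
    if (any(!is.finite(pos)) || any(!is.finite(amp)))
        stop("malformed input '", path, "': non-numeric or NaN entries")
    if (is.unsorted(pos, strictly = TRUE))
        stop("malformed input '", path, "': positions must be strictly increasing")
    steps <- diff(pos)
    pitch <- stats::median(steps)
    if (any(abs(steps - pitch) > 1e-6 * pitch))
        stop("malformed input '", path, "': positions must be uniformly spaced")
    if (type == "radial")
        return(.radialToKernel(pos, amp, pitch, basename(path)))
    ## center on the sample nearest zero and trim to a symmetric window
    c0 <- which.min(abs(pos))
    half <- min(c0 - 1L, length(pos) - c0)
    idx <- (c0 - half):(c0 + half)
    .normalizeAxial(amp[idx], pitch, label = basename(path),
                    nominalThickness = thickHeader)
}

.radialToKernel <- function(r, a, pitch, label) {
    if (min(r) < -1e-9)
        stop("radial profile positions must be non-negative")
    m <- floor(max(r) / pitch + 1e-9)
    x <- (-m:m) * pitch
    rr <- sqrt(outer(x^2, x^2, "+"))
    v <- stats::approx(r, a, xout = pmin(rr, max(r)), rule = 2)$y
    v[rr > max(r) + 1e-12] <- 0
    dim(v) <- c(length(x), length(x))
    .normalizeKernel2D(v, pitch, label)
}

#' @rdname readProfileCSV
#' @export
writeProfileCSV <- function(profile, path) {
    if (is(profile, "AxialProfile")) {
        x <- .sampledGrid(profileExtent(profile), profile@pitch)
        hdr <- c("# noduleSim axial profile",
                 sprintf("# pitch_mm=%.12g", profile@pitch))
        if (!is.na(profile@nominalThickness))
            hdr <- c(hdr, sprintf("# nominal_thickness_mm=%.12g",
                                  profile@nominalThickness))
        writeLines(c(hdr, "position_mm,amplitude",
                     sprintf("%.12g,%.12g", x, profile@values)), path)
    } else if (is(profile, "KernelProfile2D")) {
        hdr <- c("# noduleSim 2D kernel",
                 sprintf("# pitch_mm=%.12g", profile@pitch),
                 "# grid2d")
        rows <- apply(profile@values, 1L, function(r)
            paste(sprintf("%.12g", r), collapse = ","))
        writeLines(c(hdr, rows), path)
    } else stop("'profile' must be a KernelProfile2D or AxialProfile")
    invisible(path)
}
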