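# Fine-pitch spherical object functions.

#' @include AllClasses.R AllGenerics.R
NULL

#' Choose the fine sampling pitch for a sphere diameter
#'
#' Returns a pitch smaller than one-fiftieth of the sphere diameter, capped
#' at 40 um (memory) and floored at 15 um: `min(diameter / 50, 0.040)`,
#' never below `0.015`. A warning (not an error) is issued outside the
#' 1--8 mm design range.
#'
#' @param diameter sphere diameter in mm.
#' @return pitch in mm.
#' @examples
#' choosePitch(1)    # 0.020
#' choosePitch(8)    # 0.040 (capped)
#' choosePitch(0.5)  # 0.015 (floored)
#' @export
choosePitch <- function(diameter) {
    if (!is.numeric(diameter) || length(diameter) != 1L ||
        !is.finite(diameter) || diameter <= 0)
        stop("'diameter' must be a single positive number")
    if (diameter < 1 || diameter > 8)
        warning("diameter ", diameter,
                " mm is outside the 1-8 mm design range")
    max(min(diameter / 50, 0.040), 0.015)
}

#' Generate the object function of an ideal sphere
#'
#' Builds the binary voxel grid O(x, y, z) of a uniform-density sphere on an
#' isotropic fine-pitch grid: a voxel takes `densityIn` iff its center lies
#' within `diameter / 2` of the sphere center, else `densityBg`. The sphere
#' center coincides with a voxel center by default (all sub-voxel offsets
#' are introduced later, at the clinical resampling stage); `centerOffset`
#' shifts the center off the lattice for grid-convergence studies.
#'
#' The grid extends `margin` beyond the sphere surface on each axis
#' (`margin` may be a single value or one value per axis). Because the blur
#' engine pads with the true background density, any positive margin yields
#' exact blurred values at every grid point; choose the margin by what is
#' sampled downstream (in-plane: PSF extent plus the density-profile reach;
#' z: the span of the clinical slices).
#'
#' @param diameter sphere diameter in mm.
#' @param pitch isotropic voxel pitch in mm (see [choosePitch()]).
#' @param densityIn HU inside the sphere (default -400, a solid nodule).
#' @param densityBg HU outside (default -900, aerated lung parenchyma).
#' @param margin grid margin beyond the sphere surface in mm, length 1 or 3.
#' @param centerOffset length-3 mm displacement of the sphere center from
#'   the central voxel center (default none).
#' @param maxVoxels resource guard; grids larger than this raise an error
#'   suggesting a coarser pitch.
#' @return an [ObjectVolume-class].
#' @examples
#' obj <- makeSphere(diameter = 3, pitch = 0.06, margin = 1)
#' unique(as.vector(voxelData(obj)))   # exactly the two densities
#' @export
makeSphere <- function(diameter, pitch, densityIn = -400, densityBg = -900,
                       margin = diameter, centerOffset = c(0, 0, 0),
                       maxVoxels = 4e8) {
    stopifnot(diameter > 0, pitch > 0, all(is.finite(centerOffset)),
              length(centerOffset) == 3L)
    if (length(margin) == 1L) margin <- rep(margin, 3L)
    if (length(margin) != 3L || any(margin <= 0))
        stop("'margin' must be positive, length 1 or 3")
    R <- diameter / 2
    m <- ceiling((R + margin) / pitch - 1e-9)
    dims <- 2L * m + 1L
    if (prod(dims) > maxVoxels)
        stop("grid of ", paste(dims, collapse = " x "),
             " voxels exceeds the memory budget; consider a coarser pitch ",
             "(e.g. ", format(pitch * (prod(dims) / maxVoxels)^(1 / 3),
                              digits = 3), " mm)")
    origin <- -m * pitch
    center <- centerOffset
    ## coordinates as (signed integer) x pitch so that mirrored voxels get
    ## bit-identical radii and boundary membership is exactly symmetric
    xs <- (seq_len(dims[1L]) - (m[1L] + 1L)) * pitch - center[1L]
    ys <- (seq_len(dims[2L]) - (m[2L] + 1L)) * pitch - center[2L]
    zs <- (seq_len(dims[3L]) - (m[3L] + 1L)) * pitch - center[3L]
    vals <- array(densityBg, dim = dims)
    rxy2 <- outer(xs^2, ys^2, "+")
    R2 <- R^2
    nxy <- dims[1L] * dims[2L]
    idx <- lapply(seq_len(dims[3L]), function(k) {
        rem <- R2 - zs[k]^2
        if (rem < 0) return(integer(0))
        which(rxy2 <= rem) + (k - 1L) * nxy
    })
    vals[unlist(idx)] <- densityIn
    new("ObjectVolume", values = vals, pitch = pitch, origin = origin,
        center = center, diameter = diameter, densityIn = densityIn,
        densityBg = densityBg)
}
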