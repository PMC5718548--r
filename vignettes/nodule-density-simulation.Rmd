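---
title: "Simulating HRCT lung-nodule densitometry from the scanner response"
author: "noduleSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating HRCT lung-nodule densitometry from the scanner response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleSim)
```

## The problem

When a small solid lung nodule is measured on high-resolution CT, the
density a reader records depends on much more than the nodule itself. The
finite spatial resolution of the scanner (partial-volume averaging), the
reconstruction kernel, the slice thickness, and — less obviously — the
*sub-voxel offset* between the nodule center and the nearest voxel center
all move the measured Hounsfield number. The offset is uncontrolled and
unknowable in a clinical scan: the same nodule scanned twice can land
differently on the voxel lattice and read tens to hundreds of HU apart.
`noduleSim` makes every one of these factors explicit and sweepable, so
the accuracy and reproducibility of a routine ROI density measurement can
be quantified as a function of nodule diameter and reconstruction
parameters.

## The image-formation model

The package models a CT image as the object function blurred by a
separable scanner response,

$$ I(x,y,z) \;=\; \bigl(O(x,y,z) \ast\ast\, \mathrm{PSF}(x,y)\bigr) \ast
\mathrm{SSP}(z), $$

where $O$ is the ideal attenuation distribution (here a uniform sphere of
density $-400$ HU in a $-900$ HU lung-density background), $\mathrm{PSF}$
is the in-plane point spread function of the reconstruction kernel,
$\mathrm{SSP}$ is the slice sensitivity profile along the scan axis, and
$\ast\ast$/$\ast$ denote 2D and 1D convolution. The model deliberately
excludes noise, scatter and beam hardening: it isolates the geometric /
resolution contribution to density error.

The pipeline mirrors how such images arise:

1. **Object function** (`makeSphere`, `choosePitch`): the sphere is
   voxelized on a fine isotropic grid with pitch below one-fiftieth of
   the diameter, clamped to 15–40 µm (`min(d/50, 0.040)` mm, floored at
   `0.015`). Boundary voxels are classified by voxel-center membership
   (binary, no partial-volume fractions): at these pitches the residual
   staircase error in sphere volume is below 1%, which the test suite
   verifies against the analytic volume, and it vanishes quadratically as
   the pitch shrinks.
2. **Blurring** (`blurVolume`): 2D convolution with the PSF slice by
   slice, then 1D convolution along z with the SSP (the order is
   immaterial and is asserted in the tests).
3. **Clinical resampling** (`resampleToClinical`): trilinear
   interpolation of the fine image at clinical sample positions —
   pixel size `fov/matrix` (0.390625 mm for a 200 mm targeted FOV at
   512×512) in plane, the slice interval along z — displaced by a
   controlled offset `(dx, dy, dz)` of the voxel lattice relative to the
   nodule center. Admissible offsets are half a pixel in plane and half
   a slice *interval* axially; every clinically possible geometry is
   equivalent to one in that box.
4. **Densitometry** (`measureNodule`): on the slice nearest the nodule
   center, the full width at half maximum of the density profile through
   the center is measured, and the mean HU over a circular ROI of
   diameter 70% of that FWHM is reported — the rule used in routine
   reading.

## Scanner-response inputs

Measured 2D PSFs and SSPs can be loaded from plain CSV tabulations
(`readProfileCSV`; radial sections are rotationally symmetrized, which
treats the in-plane response as isotropic). Because published kernel
shapes are rarely tabulated, the package also ships three parametric
presets chosen once as physically plausible in-plane resolutions:

| preset | form | primary FWHM | role |
|---|---|---|---|
| `smooth` | Gaussian | 1.2 mm | heavy-smoothing (abdomen-type) kernel |
| `standard` | Gaussian | 0.8 mm | standard lung kernel |
| `edge` | difference of Gaussians, undershoot 0.15, σ-ratio 2 | 0.6 mm | high-resolution lung kernel with negative lobes |

SSPs default to Gaussians whose FWHM equals the nominal slice thickness.
All profiles are normalized to unit discrete integral
(`sum × pitch^d = 1`), the property that preserves HU in uniform regions;
kernels are truncated at a stated extent (default three FWHM for PSFs,
two thicknesses for SSPs) and renormalized. Profiles are regridded to
each object-function pitch by per-axis linear interpolation.

The two Gaussian presets produce monotone partial-volume
*underestimation* that vanishes with diameter; the edge-enhancing preset
produces underestimation at small diameters, *overestimation* at
intermediate diameters (the ROI integrates the overshoot ring), and
convergence at large diameters. These are the qualitative behaviors of
smoothing versus edge-enhancing clinical kernels, and the acceptance
tests assert exactly this structure rather than any scanner-specific HU
value, which would require the (unpublished) measured response of a
particular scanner.

## Numerical design

* **Exact compact-support convolution.** The blur engine subtracts the
  background, so the residual is supported only inside the sphere;
  convolving that residual with zero padding is then *identical* to
  convolving the infinite constant-background field, because the
  physical surround of a lung nodule is lung-density. The result is
  exact at every grid point for any positive grid margin. This is why
  the sweep drivers can size grids by what is sampled downstream
  (in-plane: PSF extent plus 1 mm of profile reach; axially: 3.5× the
  slice thickness, the span of the seven clinical slices retained)
  instead of carrying blanket margins, keeping 15–40 µm volumes inside
  ordinary memory.
* **Separable evaluation of the dense 2D kernel.** Stored PSFs are dense
  matrices (measured CT PSFs need not factor), but any matrix kernel is
  a sum of separable terms via its SVD; each term is applied as two
  dense matrix products. This is a reorganized direct sum — no transform
  round-off — and the suite verifies agreement with a brute-force 3D
  convolution oracle to 1e-9 and with a closed-form expression for the
  center of a Gaussian-blurred ball to 0.5 HU.
* **Interpolation weights.** Trilinear resampling is applied per axis as
  two-nonzero-per-row weight matrices; exact lattice hits are snapped so
  aligned resampling is a lossless pass-through. Interpolated values are
  convex combinations and can never leave the local value range.
* **FWHM crossings.** The half-maximum level sits midway between the
  known background (a configuration input — the simulation controls it,
  so estimating it would only add variance) and the profile peak;
  crossings are located by linear interpolation between bracketing
  pixels, taking the *outermost* crossing on each side of the peak so
  that the ringing of edge-enhancing kernels cannot truncate the width.
  A peak contrast below 10 HU (configurable) is reported as an
  unmeasurable nodule rather than a number.
* **Ties and degenerate cases.** The central slice breaks the
  `dz = interval/2` tie toward the lower index; an ROI smaller than one
  pixel falls back to the single nearest pixel; a sphere center pinned
  to a voxel center makes the voxelization exactly symmetric under
  reflection (coordinates are built as signed-integer multiples of the
  pitch so mirrored voxels get bit-identical radii).
* **Determinism.** Nothing in the pipeline draws random numbers;
  repeated runs of `runExperiment` are byte-identical.

## Open choices and how they were resolved

* **ROI center.** The ROI is centered on the true (continuous) nodule
  center projected into the slice, not on the nearest voxel center: the
  offset is defined relative to the known center, and centering the ROI
  on the voxel center would conflate two displacements.
* **FWHM source.** The FWHM is measured on the clinical (pixelated)
  image of each reconstruction, as a reader would; one consequence is
  discussed under *Limitations*.
* **Offset sweep endpoints.** The in-plane sweep takes
  `{0, p/4, p/2}` inclusive per axis — the endpoints realize the extreme
  best/worst-case geometries that define the envelopes. The axial sweep
  steps by one-tenth of the interval at 1.0 mm thickness, one-twentieth
  at 2.0 mm, and `round(10 × thickness)` otherwise (with a note).
* **Margins.** `makeSphere` accepts any positive margin (per axis if
  desired); the exactness argument above makes large safety margins
  unnecessary, and the sweep drivers choose margins from the sampling
  geometry.

## The accuracy envelopes

`densityVsDiameter` runs the full pipeline over a diameter grid (default
1–8 mm in 0.25 mm steps) and an offset enumeration, blurring each
fine-grid volume once and reusing it across all offsets and slice
intervals (offsets act only at the resampling stage). The per-offset
series are retained; their pointwise extrema are the `CTmax`/`CTmin`
envelopes, whose gap is the offset-induced irreproducibility of a
clinical measurement. `envelopeVsInterval` repeats this for slice
intervals from 100% down to 50% of the thickness (overlapping
reconstruction): the worst-case axial miss of the nodule center is half
the interval, so overlap narrows the gap from below while leaving the
best case essentially unchanged.

The shipped test suite exercises a reduced sweep — diameters
{1, 2, 3, 5, 8} mm with the full 54-offset enumeration at 1.0 mm
thickness (99 offsets at 2.0 mm) — chosen as the smallest grid that
still spans the under-resolved, transitional and converged regimes.

## Inserting simulated nodules into real images

`insertNodule` composites a simulated nodule slice into a lung CT slice
by the offset-and-add rule: adding 900 HU to the simulated image sets
its background to exactly 0 HU, so adding the shifted patch to the lung
image changes pixels only where the simulated nodule differs from
background, and subtracting the same patch restores the host image
bit-exactly. No HU clipping is applied (the sum is reported as-is), the
insertion site is user-chosen (region selection is a reading decision,
not an image-processing one), and pixel sizes must match — the package
refuses silent resampling. A deterministic synthetic lung slice
(`syntheticLungSlice`, a −900 HU field with vessel-like strokes) ships
so the module is fully testable without clinical data.

## What the simulation does and does not show

Passing tests demonstrate that the *geometric* error structure of ROI
densitometry — partial-volume underestimation, kernel-dependent over- or
undershoot, offset fluctuation, and its suppression by overlap
reconstruction — is reproduced faithfully from first principles. They do
not certify absolute HU accuracy for any particular scanner (that
requires that scanner's measured PSF/SSP as input), and they say nothing
about noise-limited precision: real low-dose images add stochastic noise
that may dominate the offset effect, and thicker slices trade the larger
partial-volume error simulated here against lower noise. Real nodules
are also not uniform spheres; the object-function module is the natural
extension point for irregular or heterogeneous objects.

One further subtlety is inherent to the adaptive ROI rule itself:
because the ROI diameter tracks the measured FWHM, a slice slightly off
the center of a large (≥ 5 mm) sphere has a marginally narrower profile,
hence a smaller ROI that excludes the lowest rim pixels — and can
therefore average fractionally *closer* to the true density than the
centered slice. The measured density is thus not strictly monotone in
the axial offset, and the "CTmax does not change with slice interval"
idealization holds exactly for small nodules but only to a few tenths of
an HU at 5–8 mm, where the measurement has already converged. This is a
property of the clinical measurement rule, not of the simulation
numerics.
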