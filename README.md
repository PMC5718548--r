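# noduleSim

PSF-based CT image simulation for lung-nodule densitometry in R.

## The problem

Quantitative density readings of small solid lung nodules on
high-resolution CT (HRCT) are biased and irreproducible in ways that have
nothing to do with the nodule: partial-volume averaging through the
scanner's in-plane point spread function (PSF) and axial slice
sensitivity profile (SSP), the choice of reconstruction kernel and slice
thickness, and the uncontrolled sub-voxel offset between the nodule
center and the nearest voxel center. `noduleSim` simulates the whole
measurement chain from first principles so these effects can be
quantified, for researchers studying measurement accuracy and for anyone
choosing scan/reconstruction parameters for density follow-up.

## The model

A CT image is modeled as the object function blurred by a separable
scanner response,

```
I(x,y,z) = ( O(x,y,z) ** PSF(x,y) ) * SSP(z)
```

(`**`/`*` = 2D/1D convolution). The pipeline:

1. **Object function** — an ideal sphere (default −400 HU in a −900 HU
   lung background) voxelized at a fine pitch `min(d/50, 0.040)` mm
   (15–40 µm).
2. **Blurring** — 2D convolution with the PSF, then 1D with the SSP.
   Three kernel presets ship (`smooth`, `standard`, `edge` — the last a
   difference of Gaussians with negative lobes); measured profiles can
   be loaded from CSV tabulations.
3. **Clinical resampling** — trilinear interpolation onto the HRCT grid
   (200 mm FOV / 512 matrix ≈ 0.4 mm pixels; slice interval ≤ slice
   thickness for overlapping reconstruction) with a controlled offset
   `(dx, dy, dz)`, bounded by half a pixel in plane and half a slice
   interval axially.
4. **Densitometry** — on the slice nearest the nodule center, the FWHM
   of the density profile through the center sizes a circular ROI
   (diameter = 70% of FWHM) whose mean HU is the measured density.

Sweeping diameters and offsets yields per-diameter `CTmax`/`CTmin`
envelopes — the best and worst case a clinical measurement can return —
and repeating the sweep over slice intervals shows how overlapping
reconstruction stabilizes the measurement. Simulated nodules can also be
composited into real lung slices (`insertNodule`) by the offset-and-add
rule.

## Worked example

```r
library(noduleSim)

psf <- kernelPreset("standard", pitch = 0.005)    # 0.8 mm FWHM Gaussian
ssp <- gaussianSSP(nominalThickness = 1, pitch = 0.005)
cfg <- reconstructionConfig(fov = 200, matrixSize = 512, sliceThickness = 1)

## one 3 mm nodule, measured at best- and worst-case voxel alignment
pitch <- choosePitch(3)                            # 0.04 mm
obj <- makeSphere(diameter = 3, pitch = pitch, margin = c(3.4, 3.4, 2.3))
bl  <- blurVolume(obj, regridProfile(psf, pitch), regridProfile(ssp, pitch))
measureNodule(resampleToClinical(bl, cfg, offset = c(0, 0, 0)))
#> DensityMeasurement: mean -420.598 HU over 21 pixels
#>   FWHM 2.791 mm, ROI diameter 1.954 mm, slice 4, offset (0, 0, 0) mm
measureNodule(resampleToClinical(bl, cfg,
    offset = c(pixelSize(cfg)/2, pixelSize(cfg)/2, 0.5)))
#> DensityMeasurement: mean -434.175 HU over 16 pixels
#>   FWHM 2.598 mm, ROI diameter 1.819 mm, slice 4, offset (0.1953, 0.1953, 0.5000) mm
```

A true −400 HU nodule reads −420.6 HU even at perfect voxel alignment
(partial volume through a standard lung kernel at 1.0 mm slices), and
−434.2 HU at the worst alignment — a 13.6 HU spread from voxel placement
alone. The full envelopes over all 54 offsets:

```r
ac <- densityVsDiameter(psf, ssp, cfg, diameters = c(2, 3, 5))
cbind(diameter = curveDiameters(ac), CTmax = ctMax(ac), CTmin = ctMin(ac))
#>      diameter  CTmax  CTmin
#> [1,]        2 -451.6 -567.8
#> [2,]        3 -412.4 -446.6
#> [3,]        5 -400.8 -402.7
```

A 2 mm nodule can read anywhere from −451.6 to −567.8 HU (a 116 HU
fluctuation); by 5 mm the measurement has converged to within ~3 HU of
the true value. `envelopeVsInterval()` repeats this across slice
intervals from 100% down to 50% of the thickness, and `plot()` on an
`AccuracyCurves` object draws the familiar gray series with bold
envelopes.

Batch runs are driven by a YAML config
(`runExperiment("run.yaml", "results/")`, or
`Rscript inst/scripts/nodulesim.R sweep --config run.yaml --out results/`
from a shell), writing one measurement table and one envelope table per
kernel × thickness, byte-identical on reruns.

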