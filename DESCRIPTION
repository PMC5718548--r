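Package: noduleSim
Title: PSF-Based CT Image Simulation for Lung Nodule Densitometry
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates high-resolution CT (HRCT) images of small lung
    nodules from first principles. Ideal-sphere object functions sampled at
    fine pitch are blurred by a separable scanner response (an in-plane
    point spread function and an axial slice sensitivity profile), resampled
    onto a clinical HRCT grid with controlled sub-voxel offsets between the
    nodule center and the nearest voxel center, and measured with the
    70-percent-of-FWHM circular-ROI densitometry rule used in routine
    reading. Sweep drivers over diameter, offset, reconstruction kernel,
    slice thickness and slice interval produce CTmax/CTmin accuracy
    envelopes that quantify partial-volume underestimation and
    offset-induced fluctuation of measured nodule density, and tools are
    included to composite simulated nodules into real lung CT slices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accuracy-analysis.R'
    'blur-engine.R'
    'clinical-resampler.R'
    'densitometry.R'
    'nodule-insertion.R'
    'noduleSim-package.R'
    'object-function.R'
    'scanner-response.R'
    'show-methods.R'
    'utils.R'
    'volume-io.R'
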