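Package: rasterSSX
Title: Pre-Analysis and Merging for Raster-Scanning Serial Synchrotron
    Crystallography
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the pre-analysis of still-shot serial synchrotron
    crystallography (SSX) data collected by raster scanning fixed targets
    through a micro- or nano-focused X-ray beam: beam/dose arithmetic and
    raster-scan planning, frame input/output with downstream-indexer
    geometry files, detector metrology correction, per-pattern scaled
    background subtraction, threshold hit finding, maximum projection,
    azimuthal integration with resolution-limit estimation, local-maximum
    Bragg-peak detection with concentric-ring integration, Monte Carlo
    merging of integrated intensities, and half-dataset quality statistics
    (R_split, CC1/2, R_merge, completeness, multiplicity). A built-in
    synthetic diffraction simulator generates raster scans with full
    ground truth (lattice-predicted Bragg spots for a tetragonal cell,
    solvent-ring background, Poisson noise) so the whole chain can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'geometry.R'
    'imageIO.R'
    'correction.R'
    'hitfinder.R'
    'peakfinder.R'
    'merging.R'
    'synthetic.R'
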