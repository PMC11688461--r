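Package: optisect
Title: Quantitative Comparison of Optical-Sectioning Microscopy Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytic and simulation tools for comparing optical-sectioning
    fluorescence microscopy methods on a common quantitative footing.
    Provides defocused optical transfer function (OTF) models built from
    pupil autocorrelation, axial-response curves and sectioning-strength
    (FWHM) calculators for confocal (pinhole and slit), two-photon,
    structured and hybrid illumination, light-sheet and line-illumination
    modulation (LiMo) microscopy, deep-background tail integrals with
    asymptotic order fits, a line-scan off-axis spatiotemporal-multiplexed
    image-formation simulator with four digital reconstructions (LC, DSIM,
    DHiLo, LiMo) evaluated on synthetic filament phantoms, and calculators
    for imaging time, signal-to-noise ratio, penetration depth and
    phototoxicity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'optical-config.R'
    'otf.R'
    'axial-response.R'
    'background-tails.R'
    'psf-engine.R'
    'sample-volume.R'
    'scan-simulator.R'
    'reconstruction.R'
    'performance.R'
    'io.R'
    'pipeline.R'
    'optisect-package.R'
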