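Package: dcpam
Title: Forward Simulation and Reconstruction for Dual-Channel
    Hexagon-Scanner Photoacoustic Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale forward simulator and processing pipeline for
    dual-channel, polygon-scanner optical-resolution photoacoustic
    microscopy. Models the hexagon-mirror beam-steering geometry and
    acquisition timing of a two-channel system with time-multiplexed
    dual-wavelength (532/558 nm) excitation, generates synthetic 3-D
    hemoglobin phantoms, simulates time-resolved A-line data with
    facet misalignment and noise, and implements the reconstruction
    chain: wavelength demultiplexing, depth correction, volume
    assembly, maximum-intensity projection, channel stitching, facet
    registration, frame stabilization, spline upsampling, and linear
    spectral unmixing of hemoglobin oxygen saturation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'geometry.R'
    'extinction.R'
    'phantom.R'
    'forward.R'
    'recon.R'
    'postproc.R'
    'evaluation.R'
    'io.R'
    'cli.R'
    'dcpam-package.R'
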