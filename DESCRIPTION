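Package: naturalfmri
Title: Stimulus-Annotated Analysis of Naturalistic fMRI with Group ICA and
    Voxel-Wise GLM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-subject fMRI acquired during rich
    naturalistic audiovisual stimulation (e.g. free viewing of a film).
    Provides stimulus annotation extraction (audio descriptors in 1-s
    windows, DCT high-pass contrast-edge density, object-track motion
    scoring), double-gamma HRF regressor construction with Gaussian-weighted
    running-line high-pass detrending, temporal-concatenation group spatial
    ICA with bootstrapped stability clustering and subject back-reconstruction,
    inter-subject correlation screening, annotation-GLM fitting with
    circular-shift permutation thresholds, 18-connectivity cluster labeling,
    ICA-versus-voxelwise overlap classification, and ROI functional
    connectivity permutation testing.  A synthetic-data generator with
    planted spatial networks and AR(1) noise makes the whole pipeline
    testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'annotations.R'
    'synthgen.R'
    'audio-features.R'
    'video-features.R'
    'design.R'
    'ica.R'
    'inference.R'
    'networks.R'
    'io.R'
    'pipeline.R'
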