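Package: ramus
Title: Randomized Multiresolution Scanning for E/MEG Source Reconstruction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Focal electro-/magnetoencephalography (E/MEG) source
    reconstruction at variable depth via hierarchical Bayesian maximum a
    posteriori estimation. Implements the iterative alternating sequential
    (IAS) optimizer with gamma and inverse-gamma hyperpriors, run
    coarse-to-fine over randomized nested multiresolution decompositions of
    the source space and averaged (RAMUS). Includes an analytic three-shell
    spherical head forward simulator (Legendre-series EEG potentials, Sarvas
    radial magnetometer fields), region-of-interest accuracy metrics with a
    detection criterion, and a configuration-driven battery of two-dipole
    (deep thalamic plus superficial somatosensory) validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, Matrix, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'forward-head.R'
    'forward-sourcespace.R'
    'forward-eeg.R'
    'forward-meg.R'
    'forward-simulate.R'
    'ias.R'
    'multires.R'
    'ramus.R'
    'evaluation.R'
    'cases.R'
    'io.R'
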