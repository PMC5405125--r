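Package: gaitTCR
Title: Template Correlation Rejection of Motion Artifacts in Walking EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and removes EEG channels and independent components that
    carry movement-locked artifacts recorded during cyclic motion such as
    treadmill walking.  Gait cycles are detected from vertical ground reaction
    force, each cycle is time-warped to a common length and correlated against
    the across-cycle average template; channels whose epochs correlate with the
    template far more often than a surrogate (random-event) null allows, and
    whose amplitude range lies above the knee of the sorted across-channel
    amplitude curve, are flagged for rejection.  The same template-correlation
    screen is applied to independent-component activations, with spectral-peak
    and scalp-map checks that protect components carrying neural content, and
    flagged components are removed by mixing-matrix back-projection.  Includes
    a synthetic walking-EEG generator with known ground truth, conventional
    bad-channel screening, band power and gait-locked amplitude diagnostics,
    and simple recording/event file I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gaitTCR-package.R'
    'spectral.R'
    'tcr-core.R'
    'ic-screening.R'
    'io-events.R'
    'preprocessing.R'
    'synthetic-data.R'
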