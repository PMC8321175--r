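Package: acrqc
Title: Automated Quality Control for MRI Systems Using the ACR Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated analysis of axial T1 ACR accreditation phantom
    acquisitions for routine MRI quality control. Locates the phantom,
    places every region of interest deterministically with respect to the
    detected phantom geometry, and computes percent signal ghosting (PSG),
    percentage image uniformity (PIU), signal-to-noise ratio (SNR) in its
    single-image and two-image subtraction variants, and SNR uniformity
    (SNRU), together with pass/fail verdicts against ACR and AAPM/Greek
    protocol limits. A randomized ROI-placement mode emulates manual ROI
    drawing to quantify the sensitivity of PSG to operator variability.
    Includes a synthetic phantom-image generator with known ground truth
    (Rician magnitude noise, configurable ghost band and intensity
    non-uniformity) and a minimal DICOM reader/writer so the whole
    pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'acrqc-package.R'
    'detect.R'
    'dicom.R'
    'image_io.R'
    'metrics.R'
    'report.R'
    'roi.R'
    'synth.R'
    'utils.R'
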