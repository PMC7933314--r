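Package: rembo
Title: Radioembolization Planning Dosimetry and Target-Volume Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for yttrium-90 radioembolization treatment planning and
    for auditing how the choice of imaging modality used to define the
    target volume propagates into absorbed-dose estimates. Implements the
    MIRD partition model for tumor, normal-liver and lung compartments,
    activity prescription rules (40 Gy normal-liver cap, 100 Gy tumoricidal
    floor), per-artery activity splitting, percentage-of-maximum isocontour
    volumetry on 3D activity maps, conjugate-view lung shunt estimation from
    planar scintigraphy, and Lin's concordance correlation coefficient with
    Fisher-z confidence intervals. Ships a 24-patient cohort table of
    per-modality target volumes (CECT, cone-beam CT, 99mTc-MAA SPECT/CT and
    post-therapy 90Y PET/CT), plus seeded digital liver phantom and cohort
    simulators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
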