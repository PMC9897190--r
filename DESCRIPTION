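Package: fourtract
Title: Four-Tract Tractography Targeting for MR-Guided Focused-Ultrasound
    Thalamotomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tractography-based targeting of the ventral intermediate
    thalamic nucleus for incisionless focused-ultrasound thalamotomy.
    Provides log-linear diffusion tensor fitting with fractional-anisotropy
    maps, deterministic tensor-deflection streamline tractography with
    ROI-recipe delineation of the decussating and non-decussating
    dentato-rubro-thalamic tracts, the corticospinal tract and the medial
    lemniscus (including the published parameter-fallback rescue cascade),
    AC-PC stereotactic frame construction with indirect and
    confluence-based tractography targets under corticospinal/medial
    lemniscus safety margins, burned-in treatment overlay volumes, cohort
    target-offset statistics, and a synthetic four-tract diffusion phantom
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
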