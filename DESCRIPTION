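Package: drgvol
Title: Volumetric MRI Analysis of Mouse Dorsal Root Ganglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement of dorsal root ganglion (DRG) size from small-animal
    T2-weighted axial MRI. Implements a spinal-cord-referenced delineation
    pipeline (dorso-ventral alignment, reference-slice averaging, cord edge
    detection, maximum intensity projection, cord zeroing, intensity-based DRG
    delineation) with cross-sectional-area quantification, test-retest
    reliability statistics (one-way random-effects ICC, Bland-Altman limits of
    agreement, pixel-count relative differences), longitudinal group comparison
    via Student's t-tests under a closed testing procedure, and a synthetic
    phantom generator with analytic ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    tiff,
    jsonlite,
    stats,
    tibble,
    dplyr,
    readr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
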