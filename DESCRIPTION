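Package: chemotaxr
Title: Automated Quantification of Chemotaxis in Optically Generated
    Chemoattractant Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analyzing high-throughput chemotaxis
    assays in which chemoattractant gradients are generated by photo-uncaging
    and cell movement is recorded by time-lapse nuclear imaging. Includes a
    radial diffusion simulator for uncaging pulse schedules with gradient
    steepness metrics, a ground-truthed synthetic movie and plate generator,
    blockwise-percentile background subtraction, threshold plus watershed
    nuclei segmentation, mutual nearest-neighbor cell tracking with crowding
    and nonmover filters, per-well motility statistics (basal and stimulated
    speed, directed speed, angular bias), and screen-level phenotype scoring
    against in-well controls with robust-regression normalization and a
    two-Gaussian replicate-error model yielding confidence intervals and
    P-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
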