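Package: shredcot
Title: Amodal Area Recovery for Overlapped Elongated Objects in Binary
    Instance Masks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Geometric reconstruction of the hidden overlap region between
    two overlapping elongated objects (such as tobacco shreds on a quality
    inspection line) from their visible instance masks.  The occluded
    object's visible mask splits into fragments; the maximum inscribed
    circle is fitted in each of the two largest fragments, and the common
    external tangent trapezoid of the two circles is intersected with the
    covering instance to estimate the hidden area.  Includes image
    preprocessing (Otsu foreground extraction, minimum enclosing circle,
    background-reducing crop), area-recovery metrics (AAR/CAR) with
    summary statistics, a seeded synthetic generator of overlapped ribbon
    samples with amodal ground truth, region-proposal anchor generation
    with coverage diagnostics, and a validated machine-readable
    feature-pyramid fusion topology.  Readers and writers are provided for
    PNG masks, LabelMe polygon JSON, COCO polygon annotations and CSV/JSON
    area reports, plus a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
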