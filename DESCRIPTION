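Package: etdilate
Title: CT-Based Quantification of Eustachian Tube Balloon Dilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to quantify the effect of balloon dilation of the
    Eustachian tube (ET) on CT images. Reads CT volumes (single-frame DICOM
    series or raw volumes with JSON sidecar metadata), converts Hounsfield
    units to 8-bit display gray values, reslices the volume along the ET
    longitudinal axis defined by three bony landmarks (medial pterygoid
    plate, opposite pterygoid plate hamulus, sphenoid spine), constructs
    balloon-guided rectangular regions of interest, calibrates air/tissue/
    bone gray-value ranges from reference regions, counts air-classified
    pixels before and after dilation, and measures lumen widths and lengths.
    Includes a parametric synthetic head phantom with ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
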