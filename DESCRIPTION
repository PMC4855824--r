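Package: eitzones
Title: Regional Overdistension, Recruitment and Cyclic Collapse from
    Electrical Impedance Tomography PEEP Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies pixels of functional electrical impedance tomography
    (EIT) image sequences recorded at successive positive end-expiratory
    pressure (PEEP) levels into overinflated, tidally recruited/derecruited
    (cyclic) and recruited lung regions. End-inspiratory and end-expiratory
    frames are located on the global impedance waveform, averaged into status
    images, and thresholded relative to each image's maximum to delineate
    end-expiratory and tidal lung regions; set differences between these
    regions define the three pathological categories. Includes a full
    incremental-PEEP trial orchestrator with percentage reporting, Pearson
    correlation of region sizes against ancillary physiology, a labelled
    synthetic phantom generator for end-to-end validation without recorded
    data, and rendering of classified-region maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
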