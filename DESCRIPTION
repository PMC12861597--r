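Package: voltagram
Title: Mass Voltammograms and Transformation-Product Annotation for
    Electrochemistry-Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mass voltammograms from raw electrochemistry-mass
    spectrometry (EC-MS) runs and a staircase potential-ramp description,
    removes interfering compounds by reference-run subtraction, detects and
    annotates electrochemical transformation products by exact-mass
    arithmetic against a biotransformation library, and annotates their
    tandem mass spectra by neutral-loss chains. Includes a seeded synthetic
    EC-MS run generator with known ground truth so every pipeline stage can
    be exercised without instrument data. Reads and writes mzML via 'mzR'.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    mzR,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    writexl
Config/testthat/edition: 3
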