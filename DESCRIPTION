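Package: biospot
Title: Bioactivity-Guided Correlation of Micro-Fractionated LC-MS Runs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for compound-resolved, bioactivity-based metabolomics with
    micro-fractionated LC runs spotted onto paper-based analytical devices
    (uPADs). Converts luminescence images of spotted uPADs into
    median-normalized per-fraction bioactivity values (spot densitometry with
    grid fitting, serpentine fraction indexing and halo quantification), builds
    retention-time-resolved bioactivity chromatograms with Gaussian smoothing
    and prominence-based peak detection, detects LC-MS features from mzML runs
    with a minimal mass-trace algorithm, and ranks candidate bioactive
    compounds by retention-time gating and Pearson peak-shape correlation.
    Includes seeded synthetic-fixture generators (uPAD images and linked mzML
    runs) and an MS2 filter producing molecular-networking-ready output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    base64enc,
    jsonlite,
    png,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
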