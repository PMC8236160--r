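Package: radfilm
Title: Radiochromic Film Dosimetry and Gamma-Analysis QA Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific quality assurance with radiochromic
    film on flatbed scanners: four-orientation scan averaging, net optical
    density computation, nine-level grid calibration with third-order
    polynomial netOD-to-dose curves, planar dose conversion, rigid
    registration of film to planned dose planes, gamma-index analysis
    (global dose difference, absolute and relative normalization) with a
    brute-force verification oracle, central-axis profile comparison with
    percent dose-difference statistics, and a seeded synthetic-data
    generator that emulates open square fields, calibration-grid films and
    multi-orientation flatbed scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
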