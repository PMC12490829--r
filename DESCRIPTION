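Package: axztools
Title: Read, Validate, Quality-Control and Export AFM-IR Instrument Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for working with AFM-IR (Atomic Force Microscopy-based
    Infrared spectroscopy) instrument files in an AXZ dialect: compressed XML
    containers holding base64-encoded channel maps, optical images and
    rendered spectra. Provides a document object model, container detection
    and decompression (gzip, zip, plain XML), bit-exact array round-tripping,
    minimal display processing (per-line height leveling, deflection setpoint
    subtraction, raw line profiles, labeled-array conversion), heuristic data
    quality control (apparent prior processing, AFM tracking error, PLL phase
    error, PLL saturation), CSV/metadata/report exports, a deterministic
    synthetic-file generator with artifact injection, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
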