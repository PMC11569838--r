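Package: duplexfit
Title: Thermodynamic and Biophysical Analysis of Modified DNA Duplexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for comparing short DNA duplexes that carry
    bulky non-nucleotide modifications. Implements two-state melting-curve
    fitting with sloping linear baselines, van 't Hoff concentration-series
    estimation of duplex formation enthalpy and entropy, gel-mobility-based
    bend-angle estimation, spectrophotometric and fluorimetric titration
    metrics (hypochromic effect, fluorescence quenching), and quantification
    of nucleotide excision repair time courses from band-intensity tables.
    A seeded synthetic-data generator emulates every instrument input so all
    stages are testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, signal
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
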