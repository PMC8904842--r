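Package: vasomech
Title: Biomechanical and Histological Quantification of Arterial Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for arterial biomechanics studies: converts
    uniaxial tensile force-displacement records to Cauchy stress-stretch
    curves and extracts low- and high-strain elastic moduli, transition and
    rupture points, and Simpson's-rule strain energies; quantifies
    longitudinal pre-stretch from marker traces and circumferential residual
    strain from ring opening angles with triplicate-measurement reliability
    statistics; fits four-parameter logistic concentration-response curves
    from wire myography (EC50/pD2, maximal responses); and quantifies
    histological sections by stain deconvolution, nuclei morphometry and
    perimeter-based vessel geometry. A synthetic-data module generates
    ground-truth-labelled inputs (tensile curves, ring phantoms, marker
    traces, dose-response records, stained-section phantoms) so that every
    analysis stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
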