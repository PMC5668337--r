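Package: reimsid
Title: Species Fingerprinting and Real-Time Recognition for Rapid
    Evaporative Ionisation Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for authenticating fish tissue from rapid evaporative
    ionisation mass spectrometry (REIMS) burn spectra. Provides a seeded
    generator of synthetic REIMS-like scan streams, preprocessing of raw
    runs into TIC-normalised 0.5 Da lipid fingerprints over m/z 600-950,
    a PCA-LDA species classifier with a 5-sigma Mahalanobis-style outlier
    rule (offline, cross-validated and in streaming mode), OPLS-DA model
    fitting with R2/Q2 validation, permutation testing, S-plot and VIP
    marker mining, and monoisotopic ion-mass arithmetic for putative
    phospholipid annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
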