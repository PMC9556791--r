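Package: fibrilquant
Title: Quantitative Analysis of Amyloid-Membrane Solid-State NMR, TEM and
    Plate-Reader Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis chain used in solid-state
    NMR studies of amyloid-beta interactions with biological membranes:
    lipid motional correlation times (fast, nanosecond and slow,
    microsecond) from 31P T1/T2 relaxation with first-order uncertainty
    propagation; internuclear distance estimation from PITHIRDS-CT and
    REDOR dipolar dephasing curves; interstrand versus intrastrand
    contact classification from isotope-dilution 2D 13C-13C spin
    diffusion crosspeak volumes; fibril mass-per-length from dark-field
    TEM intensities calibrated against the tobacco mosaic virus
    standard, with constrained mixture fitting at integer multiples of a
    unit mass-per-length; and plate-reader assay quantification
    (thioflavin-T fibrillation kinetics, BCA membrane binding, GdnHCl
    denaturation midpoints, MTT cell viability, group significance).
    A seeded synthetic-data generator emulates every input with known
    ground truth so the full pipeline is testable without spectrometer
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
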