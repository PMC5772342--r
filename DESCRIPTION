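Package: metallosense
Title: Quantitative Analysis of Metal-Sensor Protein Allostery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of metal-sensing
    transcriptional repressors: mass-action speciation and global fitting of
    chelator-competition metal titrations, protein-DNA binding isotherms from
    fluorescence anisotropy or gel-shift band fractions with allosteric
    coupling free energies, ratiometric pulsed-alkylation mass spectrometry
    (isotope-coded peptide masses, per-cysteine alkylation kinetics, MS/MS
    site-occupancy partitioning), model-free small-angle X-ray scattering
    analysis (Guinier, Kratky, regularised indirect Fourier transform,
    Porod-volume molecular weight), and ion-mobility mass spectrometry
    (oligomer/charge assignment and minimum-component Gaussian decomposition
    of collision-cross-section distributions). Seeded synthetic-data
    generators reproduce the statistical structure of each experiment so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
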