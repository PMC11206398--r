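Package: quinspec
Title: Conformer Ensembles, UV-Vis Spectral Shifts and Potency Descriptors
    for 4-Anilinoquinazoline Kinase Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for quantum-chemistry conformer
    ensembles of halogen-substituted 4-anilinoquinazoline EGFR inhibitors.
    Computes strain energies and Boltzmann conformer populations, superposes
    crystal poses onto global-minimum structures (plane-anchored or Kabsch
    least-squares) with RMSD, builds broadened UV-Vis absorption spectra
    from excited-state stick data, extracts principal absorption maxima
    under an oscillator-strength rule, classifies crystal-versus-minimum
    spectral shifts as blue or red, and correlates dipole moments and
    optical shifts with inhibitor potency as ln(IC50 in nM). Includes a
    seeded synthetic ensemble generator with full ground truth so the whole
    pipeline is testable without electronic-structure software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
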