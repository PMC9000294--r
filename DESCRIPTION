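Package: polyeneQC
Title: Post-Processing, Validation and Benchmarking of Quantum-Chemistry
    Results for Conjugated Polyene Dyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale post-processing of electronic-structure results for
    conjugated chromophores such as the achiote (Bixa orellana) pigments
    bixin, isobixin, norbixin and isonorbixin.  Computes the bond-length
    alternation (BLA) statistic over a declared conjugation path, frontier
    orbital gaps and Koopmans estimates, scalar nonlinear-optical invariants
    (dipole magnitude, mean polarizability, the beta-vector projection of the
    first hyperpolarizability) with esu reporting, and Gaussian-broadened
    UV-Vis absorption spectra from vertical-transition records.  Ships
    transcribed reference benchmark tables for the four dyes at three DFT
    functionals in gas phase and chloroform, a trend/consistency report over
    them, readers and writers for XYZ geometries and a JSON summary-record
    format ('qcsum/1'), and a synthetic-data generator producing polyene
    geometries, transition records and NLO tensors with prescribed
    invariants for testing without a quantum-chemistry engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
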