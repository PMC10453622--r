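Package: thermorank
Title: Semi-Rational Thermostability Design Analysis for Proteases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semi-rational protein thermostability engineering
    analysis: nomination of flexible candidate sites from C-alpha B-factors in
    PDB structures, substitution proposals from residue frequencies in homolog
    multiple sequence alignments, first-order thermal-inactivation kinetics
    (half-life fitting with a model-free cross-check), composite scoring and
    ranking of mutants by activity and thermostability, combination-mutant
    planning around loop regions, and sliding-window hydropathy and average
    flexibility profiles. Includes seeded synthetic-data generators (PDB,
    alignment, decay time courses) so the whole pipeline is testable offline,
    plus a reproducible end-to-end workflow runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
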