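Package: cuabthermo
Title: Thermodynamic-Cycle Analysis of Cu(II)/Cu(I) Binding to Amyloid-Beta Model Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composite ab initio thermochemistry of copper-peptide
    coordination equilibria. Assembles per-species gas-phase and aqueous free
    energies from quantum-chemistry energy components (composite MP2
    large-basis scheme, scaled zero-point energies, conformational mixing and
    1 M standard-state entropy terms, continuum solvation free energies with
    experimental overrides for the proton and water), computes reaction free
    energies by Hess summation over balanced stoichiometries, converts them to
    pH-conditional free energies, binding constants, pKa values and Cu(II)/Cu(I)
    reduction potentials versus the standard hydrogen electrode, and ships the
    published reaction-level data for the copper/amyloid-beta model-ligand
    system as an audited fixture together with a seeded synthetic-data
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
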