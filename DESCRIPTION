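Package: fibrilcohesion
Title: Hydration-Dependent Decomposition of Collagen Fibril Cohesive Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mesoscale energy-decomposition model for the lateral cohesion
    between tropocollagen molecules in Type I and Type II collagen fibrils.
    The cohesive energy per molecule is split into five hydration-modulated
    mechanisms: direct hydrogen bonds (Hill-equation site occupancy by water),
    water-mediated bridges with dipolar distance decay, Lennard-Jones van der
    Waals contacts from side-chain atom statistics, entropic hydrophobic
    association of CH2/CH3 groups, and dielectric-screened salt bridges with a
    Maxwell Garnett effective-medium permittivity. Includes composition
    profiling of collagen chains from FASTA or count tables, hydration and
    lattice geometry derivations, synthetic collagen-like sequence generation,
    and report serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
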