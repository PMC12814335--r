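Package: clr3disp
Title: State-Specific Dispersion Corrections for Polarizable QM/MM Excitation Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes state-specific van der Waals dispersion corrections to
    electronic excitation energies of chromophores embedded in polarizable
    atomistic (MMPol) environments. Implements Hirshfeld partitioning of
    Gaussian-cube electron densities into atomic volume ratios, effective C6
    dispersion coefficients in the Tkatchenko-Scheffler volume-scaling scheme,
    atom-wise excited-state polarizability rescaling from distributed (HHS)
    polarizabilities, damped pairwise QM-MM dispersion sums, and assembly of
    the four-component cLR3 excitation-energy correction with per-residue
    decomposition of the dispersion shift. Includes a seeded synthetic-fixture
    generator (model atomic densities on cube grids, toy QM/MM geometries,
    parameter tables) so every stage can be exercised without quantum-chemistry
    software, and a command-line driver tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
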