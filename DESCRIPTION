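Package: phenolox
Title: QTAIM Topology and Antioxidant Thermochemistry for Phenolic Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for density-functional studies of phenolic
    antioxidants such as the flavone luteolin. Reads and writes Gaussian-style
    cube files, evaluates analytic (promolecular) and grid-interpolated electron
    densities with gradients and Hessians, locates bond critical points and
    computes QTAIM topological parameters (rho, Laplacian, G, v, h, |v|/G) with
    hydrogen-bond classification and density-based binding-energy estimates.
    Provides conceptual-DFT reactivity descriptors from frontier-orbital
    energies, molecular electrostatic potential evaluation with a molecular
    polarity index, NBO second-order perturbation energies, and the
    HAT/SET-PT/SPLET thermodynamic descriptors (BDE, IP, PDE, PA, ETE) with
    explicit-water effect statistics. Ships literature reference tables for
    luteolin-solvent complexes and seeded synthetic-fixture generators so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
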