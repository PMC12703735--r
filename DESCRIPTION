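Package: nnpforge
Title: Data-Efficient Construction and Validation of Machine-Learned
    Interatomic Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for building purpose-specific
    machine-learned interatomic potentials for small organic (CHON)
    molecules: nonequilibrium training-structure generation by coordinate
    scaling/random displacement and by normal-mode displacement,
    cohesive-energy labelling against a reference calculator, two-model
    committee active learning with molecular-dynamics-driven sampling, a
    trainable atom-centered descriptor potential with analytic forces,
    velocity-Verlet molecular dynamics with Langevin and velocity-rescale
    thermostats, relaxed potential-energy-surface scans, vibrational
    density of states from the mass-weighted velocity autocorrelation
    function, radial distribution functions, cutoff-resolved error
    tables, trajectory cross-evaluation, and implicit-solvation
    free-energy estimation from gas/solvent energy differences. A
    built-in analytic toy potential (Morse bonds, harmonic angles,
    cosine torsions, Lennard-Jones nonbonded terms and a smooth
    coordination-dependent solvent shift) serves as the reference-energy
    oracle so the entire workflow is exercisable without any quantum
    chemistry code.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'chemio.R'
    'oracle.R'
    'structgen.R'
    'mlpot.R'
    'dynamics.R'
    'active.R'
    'evalsuite.R'
    'solvate.R'
    'fixtures.R'
    'workflow.R'
    'nnpforge-package.R'
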