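Package: torsbo
Title: Bayesian Optimization over Torsion Angles for Low-Energy Conformer
    Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Finds low-energy conformers of small molecules by Bayesian
    optimization over the torsion-angle hypercube. A Gaussian-process
    surrogate with chemistry-informed locally periodic kernels (one
    periodicity per rotatable bond, assigned from a SMARTS library or an
    atomic-hybridization fallback) models the fixed-rotor MMFF94 energy
    landscape; expected improvement, probability of improvement, or a
    lower confidence bound proposes the next torsion vector. Uniform
    random search and a systematic torsion-driving baseline share the
    same objective interface, and an evaluation layer provides
    symmetry-aware heavy-atom RMSD, torsion fingerprint deviation,
    energy differences, and paired Wilcoxon signed-rank comparisons for
    benchmarking the search strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction
RoxygenNote: 7.3.3
Collate: 
    'utils-angles.R'
    'AllGenerics.R'
    'AllClasses.R'
    'kernels.R'
    'gp.R'
    'acquisition.R'
    'openbabel.R'
    'molecule-io.R'
    'rotors.R'
    'torsions.R'
    'objective.R'
    'search.R'
    'metrics-rmsd.R'
    'metrics-tfd.R'
    'stats.R'
    'benchmark.R'
    'torsbo-package.R'
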