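# torsbo

Bayesian optimization over torsion angles for finding a small molecule's
lowest-energy conformer.

## The problem

Most drug-like molecules are flexible: rotation about each acyclic single
bond multiplies the number of energetically accessible shapes, and finding
the global minimum of the potential energy surface quickly becomes
intractable for systematic enumeration. Torsion-driving enumerators visit a
fixed grid of "ideal" angles per bond — thorough but combinatorial, and
blind to minima that fall between grid points. Random sampling scales to
higher dimensions but wastes evaluations.

`torsbo` treats conformer search as black-box optimization of the energy
over the torsion hypercube `[0, 2π)^d`, where `d` is the number of
rotatable bonds. Bond lengths, bond angles and ring systems stay frozen at
a reference geometry (the fixed-rotor convention); the objective is the
single-point MMFF94 energy of the driven geometry. A Gaussian-process
surrogate models the landscape and an acquisition function picks each next
torsion vector, so good conformers are found within ~10²
energy evaluations where systematic search may need 10⁴–10⁶.

## The model

The GP prior uses a *locally periodic* kernel — a per-dimension product of
a periodic factor and a squared-exponential factor:

    k(x, y) = σ² ∏ᵢ exp(−2 sin²(π(xᵢ−yᵢ)/pᵢ)/ℓ²per,i) · exp(−rᵢ²/(2ℓ²se,i))

The period `pᵢ = 2π/mᵢ` encodes the chemistry prior: the integer
periodicity `mᵢ` (number of equivalent torsional minima per turn) is
assigned per rotatable bond from a SMARTS library with first-match-wins
semantics, falling back to hybridization rules (sp²–sp² → 2, sp²–sp³ → 6,
sp³–sp³ → 3). The SE factor, taken on the chordal circle distance
`rᵢ = 2 sin(Δᵢ/2)` so the kernel respects the torus and stays positive
definite, lets the amplitudes of the periodic wells vary. Periods are
never fitted; length scales, variance and noise maximize the log marginal
likelihood under box bounds, with energies normalized to zero mean and
unit scale and a jitter ladder guarding the Cholesky factorization.

Acquisition functions (with `z = (f_best − μ(x))/σ(x)`):

* `PI(x) = Φ(z)` — probability of improvement,
* `EI(x) = σ(x)·(zΦ(z) + φ(z))` — expected improvement (default),
* `GP-LCB(x) = μ(x) − κσ(x)` — lower confidence bound, default `κ = 2`.

Baselines sharing the same objective interface: uniform random search, and
a systematic torsion driver (per-bond angle grids, energy cutoff, RMSD
deduplication). The evaluation layer provides symmetry-aware heavy-atom
RMSD (minimized over graph automorphisms after least-squares
superposition), torsion fingerprint deviation (TFD), energy differences
`ΔE`, paired Wilcoxon signed-rank tests, and benchmark summaries (champion
rate, lowest-energy-conformer recovery, maximum variation).

## Worked example

Biphenyl has a single rotatable bond — the inter-ring axis — with a
periodicity of 2 from its sp²–sp² hybridization. Fifteen evaluations of
BOA with expected improvement pin down the twisted minimum:

```r
library(torsbo)
biphenyl <- readMolecule(system.file("extdata", "biphenyl.sdf", package = "torsbo"))
biphenyl
#> TorsionMolecule 'biphenyl': 22 atoms, 23 bonds, 1 rotatable
#>   rotor 1: axis 6-7 (quadruple 1-6-7-8), p=2 [fallback]

obj <- mmff94Objective(biphenyl)
res <- boaSearch(obj, d = 1, periodicities = periodicities(biphenyl),
                 config = searchConfig(budget = 15, seed = 1))
res
#> SearchResult [boa-ei]: 15 evaluations, best 39.7306 (termination: budget)

round(bestTorsions(res) * 180 / pi, 1)
#> [1] 314

head(searchTrace(res, degrees = TRUE), 3)
#>   iteration   theta_1 energy_kcal_mol best_so_far
#> 1         1  95.58312        40.78217    40.78217
#> 2         2 133.96460        39.73095    39.73095
#> 3         3 206.22721        41.18830    39.73095
```

The best torsion (314°, i.e. −46°) reproduces the twisted equilibrium
geometry of biphenyl under MMFF94 — a minimum a coarse systematic grid of
multiples of 90° would never visit. A 360-point 1° scan of the same
objective confirms 39.73 kcal/mol as the grid minimum. The best conformer
carries coordinates and energy and can be written to SDF with
`writeConformers()`.

A command-line front end is installed with the package
(`inst/scripts/torsbo`): `torsbo search input.smi --method boa-ei --budget
50 --seed 1 --out conformers.sdf --trace trace.csv`, plus `torsbo bench`
for multi-method benchmark tables.

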