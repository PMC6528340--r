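---
title: "Conformer search by Bayesian optimization over torsion angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer search by Bayesian optimization over torsion angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsbo)
```

## The search problem

A conformer of a small molecule is determined, once bond lengths, bond
angles and ring geometries are fixed, by the dihedral angles about its
rotatable bonds. `torsbo` searches the torsion hypercube $[0, 2\pi)^d$ for
the conformation minimizing the molecule's MMFF94 single-point energy
under this fixed-rotor convention. The convention matters for
comparability: geometry relaxation after each torsion move would change
the landscape being searched, so the package never optimizes geometry —
sterically clashing torsion vectors are legal inputs that simply return
very high energies.

Rotatable bonds are perceived by a purely topological rule: single order,
not in a ring (a bond is in a ring exactly when it is not a bridge of the
bond graph), and both atoms with at least two heavy-atom neighbors. Bonds
to symmetric tops (CF$_3$-like) are kept by default since their rotation
still moves atoms; a flag drops them for users who prefer the smaller
search space. The dihedral quadruple for axis $(b, c)$ uses the
lowest-index heavy neighbor on each side, which makes perception
deterministic and stable under atom reindexing.

## The surrogate

The Gaussian-process prior over the energy landscape uses a locally
periodic kernel: per torsion dimension, the product of a periodic factor
and a squared-exponential factor,

$$k(x, y) = \sigma^2 \prod_{i=1}^{d}
  \exp\!\left(-\frac{2\sin^2(\pi(x_i-y_i)/p_i)}{\ell_{per,i}^2}\right)
  \exp\!\left(-\frac{r_i^2}{2\,\ell_{se,i}^2}\right).$$

The period $p_i = 2\pi/m_i$ is fixed from the bond's integer periodicity
$m_i$ — the number of equivalent torsional minima per full turn implied by
its chemistry. Periodicities come from a SMARTS library
(first-match-wins, patterns written linearly through the bond) with a
hybridization fallback: sp$^2$–sp$^2$ $\to$ 2, sp$^2$–sp$^3$ $\to$ 6,
sp$^3$–sp$^3$ $\to$ 3; these are the standard torsional multiplicities
(sp$^2$–sp$^3$ barriers are six-fold, as in toluene). Bonds involving sp
atoms default to 1: rotation about a linear axis has essentially no
torsional structure. The bundled library is a small curated subset (amide,
ester, biaryl, conjugated, aryl–alkyl, alkyl–heteroatom); uncovered bond
types fall back to hybridization, and users can supply their own
`SMARTS<TAB>periodicity` file.

### The circle distance in the SE factor

A design point that implementation settled: the textbook locally periodic
kernel takes the SE factor on raw differences $|x - y|$ and is therefore
not $2\pi$-periodic, which misrepresents torsion topology (0 and
$2\pi - \epsilon$ are nearly identical geometries). The intuitive fix —
the wrapped geodesic distance $\min(|x-y|, 2\pi - |x-y|)$ — turns out to
be **indefinite**: Gaussians of geodesic distances on circles are not
positive semidefinite, and in practice Gram matrices on dense BOA designs
with long fitted length scales showed minimum eigenvalues near $-1\%$ of
the diagonal, enough to defeat any reasonable jitter and abort runs. The
package therefore uses the chordal distance $r_i = 2\sin(\Delta_i/2)$
(the straight-line distance on the unit circle's embedding). This kernel
is provably PSD — it is exactly a $2\pi$-periodic kernel — and agrees with
the geodesic for small separations. `kSE()` exposes all three distances
(`"chordal"`, `"wrapped"`, `"raw"`); the surrogate uses chordal, and
`circularSE = FALSE` gives the topology-ignoring raw variant for
comparison with conventional BO stacks.

### Fitting

Energies are normalized to zero mean and unit scale at every refit (the
mean function is constant zero on normalized outputs), which makes the
hyperparameter bounds meaningful across molecules whose absolute MMFF94
energies differ by hundreds of kcal/mol. Length scales
$\ell \in [0.05, 10]$ rad, variance $\sigma^2 \in [10^{-3}, 10^3]$ and
noise $\sigma_n^2 \in [10^{-6}, 10^{-1}]$ (normalized units) are fitted by
maximizing the log marginal likelihood with L-BFGS-B in log-parameter
space, using analytic gradients and a small number of restarts (the
previous iteration's optimum warm-starts the first). Periods are never
fitted. Cholesky failures escalate a jitter ladder of $10^{-8}$ to
$10^{-4}$ *relative to the mean kernel diagonal* — an absolute jitter is
meaningless when $\sigma^2$ may legitimately reach $10^3$ — and only
exhaustion of the ladder raises a conditioning error. The search loop
treats that error as an early stop and returns the partial trace flagged
`early_stop`, so benchmark harnesses can exclude such runs rather than
crash.

Refits are cubic in the number of observations, so hyperparameters are
re-optimized every iteration while $n \le 50$ and every fifth iteration
beyond, with the cached factorization refreshed in between.

## Acquisition and the inner optimizer

With $z(x) = (f_{best} - \mu(x))/\sigma(x)$: probability of improvement
$\Phi(z)$, expected improvement $\sigma(x)(z\Phi(z) + \phi(z))$, and the
lower confidence bound $\mu(x) - \kappa\sigma(x)$ (minimized, unlike the
UCB form used for maximization). At $\sigma = 0$ the continuous limits
apply. The default $\kappa = 2$ is the conventional exploration weight;
it is exposed in the configuration. The inner optimizer scores 1000
uniform random candidates in one batch, refines the top 5 by
derivative-free local search with wraparound (golden-section in 1-D,
Nelder-Mead otherwise), and breaks exact ties toward the lowest-index
candidate so proposals are reproducible given the RNG state.

## Search strategies and budgets

`boaSearch()` draws `nInit = 5` uniform random torsion vectors, then
iterates fit–propose–evaluate until `K` total evaluations, so only
$K - 5$ conformers are chosen by the surrogate. `defaultBudget()` gives
$K = 50$ for molecules with at most three rotatable bonds and $K = 100$
otherwise. `uniformSearch()` evaluates $K$ i.i.d. uniform vectors.
`systematicSearch()` enumerates per-bond angle grids — by default
$2m_i$ evenly spaced angles per bond, e.g. six for an sp$^3$–sp$^3$ bond —
with an energy cutoff (500 kcal/mol by default) applied relative to the
lowest energy seen and re-checked against the final minimum, RMSD
deduplication at 0.05 Å among retained conformers, and a hard cap of
$10^6$ enumerated conformers that warns rather than errors. One root seed
drives each run; repeated trials derive per-trial seeds deterministically.

## The synthetic potential generator

Tests and calibration use separable cosine potentials

$$E(\theta) = \sum_i A_i\,(1 - \cos(p_i(\theta_i - \phi_i)))
  + c \sum_{i<j} \cos(\theta_i - \theta_j) + \varepsilon,$$

which emulate the periodic, multi-well structure of torsional energy
profiles with known analytic minima (value 0 at $\theta_i = \phi_i$ when
$c = \varepsilon = 0$). The calibration ensemble draws 20 such potentials
in dimensions 2 and 3, periodicities sampled from $\{2, 3\}$ (the common
torsional multiplicities), amplitudes from $U[0.5, 2]$ kcal/mol —
realistic torsional barrier heights — and uniform phases, without coupling
or noise so the gap to the true minimum is measurable exactly. What these
potentials deliberately lack: the steep $r^{-12}$ clash walls, cross-term
couplings and amplitude heterogeneity of real force fields. Passing the
synthetic checks therefore demonstrates the optimizer's behavior on
smooth periodic landscapes, not MMFF94 fidelity; the biphenyl end-to-end
check (15-iteration BOA against a 1° exhaustive scan of the real MMFF94
torsion profile) covers the latter in one dimension, where exhaustive
oracles are affordable.

Problem sizes used throughout the checks — 20 potentials, budgets
$K \in \{50, 100, 200\}$, 5–10 seeds per claim — are the package's chosen
desk-scale conditions: large enough for the sign test on the
BOA-versus-uniform ordering to have power, small enough to run routinely.

## Evaluation metrics

**RMSD.** Heavy-atom root-mean-square deviation, minimized over the
molecule's graph automorphisms (element-colored VF2 enumeration) so that
topologically equivalent atoms — a flipped benzene ring, swapped
carboxylate oxygens — do not register as geometric difference. The
printed RMSD formula has no alignment step, and toolkit conventions vary;
conformers here are superposed by rigid-body least squares (proper
rotations only, preserving chirality) before the deviation is computed,
because comparison under arbitrary global rotation is otherwise
meaningless. `superpose = FALSE` restores the in-place convention.

**TFD.** Torsion fingerprint deviation follows the published
Schulz-Gasch–Hert–Fechner–Stahl scheme: torsions of non-terminal acyclic
bonds and of ring systems, per-torsion deviations normalized by the
maximal possible deviation, weighted by $e^{-\beta d^2}$ in the
topological distance $d$ from the molecule's most central bond (found by
minimal standard deviation of graph-distance rows), with $\beta$
calibrated so a bond at half the maximal distance weighs 0.1. Symmetric
torsion ends contribute quartet sets whose minimal angular difference is
used. Atom equivalence comes from iterated neighborhood refinement
(radius 2) — the equivalence classes, not any particular hash, are what
the algorithm needs. The default normalization is 180° for every torsion,
matching the widely used implementation default; `maxDev = "spec"`
switches to torsion-specific maxima (90°/60° at symmetric ends). Rings are
ring-averaged absolute dihedrals weighted $(N/2)e^{-\beta \bar d^2}$.
Molecules with no usable torsion raise a typed error rather than return a
meaningless 0.

**Statistics.** `pairedWilcoxon()` drops zero differences, requires at
least five informative pairs, uses the exact signed-rank distribution up
to $n = 25$ without ties and the tie-corrected normal approximation
otherwise; benchmarks report two-sided p-values at the conventional 5%
level. `summarizeBenchmark()` pools molecules with three or fewer
rotatable bonds into one group before testing, since sparse rotor classes
are individually too small.

## Numerical choices and degenerate inputs

* Angles are radians in $[0, 2\pi)$ internally, IUPAC sign convention;
  degrees appear only at the CLI boundary and in trace output.
* Dihedrals at collinear quadruples raise a degenerate-geometry error.
* Torsion driving rotates the full connected component on the far side of
  each axis; because that component is a whole graph component after
  deleting the axis edge, drives about different bonds never disturb each
  other's dihedrals, and one pass sets all angles to $10^{-9}$ rad
  round-trip accuracy with bond lengths and angles preserved to machine
  precision.
* GP variance predictions are clamped at zero against roundoff; a
  single-observation fit predicts its own training value (the normalized
  posterior mean reverts to the training mean far from data).
* Equal-scoring acquisition candidates resolve to the lowest index; a
  constant acquisition surface degenerates gracefully to a random
  candidate.
* The automorphism group is enumerated exactly; a cap (10⁴ mappings)
  guards pathological highly-symmetric inputs with a warning.

## Known limitations

* Ring conformations, bond-length/angle relaxation, stereocenter
  enumeration and tautomers are out of scope; the fixed-rotor search
  cannot find minima that require ring puckering.
* Absolute MMFF94 energies differ across implementations and versions;
  comparisons should stay within one configured force-field flavor (the
  objective records it), and tests compare energies relatively.
* The systematic baseline's default angle grids ($2m_i$ evenly spaced
  angles) are a simple stand-in for a knowledge-based torsion-driving
  angle library; its retained-conformer counts are not comparable to
  production enumerators.
* GP fitting is $O(n^3)$; budgets beyond a few hundred evaluations call
  for sparser refit cadences or a different surrogate.
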