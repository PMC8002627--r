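---
title: "Ensemble binding free energies: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble binding free energies: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crebind)
```

# The problem and the model

A flexible guest bound inside a macrocyclic host populates many thermally
accessible conformations. `crebind` treats each molecular species
(complex, host, free ligand) as a conformer–rotamer ensemble (CRE) and
computes the 1:1 binding free energy three ways:

* **Top pose**: `dg_top = min G_complex − min G_host − min G_ligand`,
  the classic single-structure estimate evaluated at the lowest Gibbs
  energy structure of each species.
* **Ensemble average**: `dg_ens` from Boltzmann-weighted species averages
  `⟨G⟩ = Σ p_i G_i`, `p_i ∝ exp(−G_i/RT)`.
* **Entropy-corrected**: `dg_ens_tscr = dg_ens − T·ΔS_CR`, with the
  conformational–rotational entropy `S_CR = −R Σ p_i ln p_i` per species.
  Algebraically this equals the difference of partition-sum free energies
  `F = −RT ln Σ exp(−G_i/RT)`, and the package exploits that identity as a
  permanent internal consistency check (`F = ⟨G⟩ − T·S_CR` is asserted to
  1e-9 kcal/mol in the test suite on random inputs).

Per-structure Gibbs energies are `G = E + G_RRHO + G_solv`: an electronic
(or force-field) total energy, an RRHO thermal/entropic correction, and an
implicit-solvation term. The package consumes `E` and `G_solv` as inputs —
it is sampler- and Hamiltonian-agnostic — and computes `G_RRHO` itself
from frequencies, masses and rotational constants.

**Assumptions.** Ideal-gas RRHO partition functions (no anharmonicity, no
hindered-rotor treatment by default), 1:1 stoichiometry, index-consistent
atom ordering within an ensemble, and a discrete conformer-state model for
the entropy: `S_CR` measures the occupancy distribution over distinct
structures, so it depends on how finely the CRE criteria discretize the
continuum. That discretization dependence is intrinsic to the method, not
an artifact of this implementation.

Two deliberate conventions, where the field's usage is ambiguous:

* The logarithm in `S_CR` is natural. Any other base would break
  `G_CR = −T·S_CR = F − ⟨G⟩`, which is the property that makes the three
  binding flavors mutually consistent.
* Boltzmann weights are computed from Gibbs energies when thermochemical
  corrections are available (they fall back to plain energies otherwise).
  Weighting on electronic energies instead is possible by passing those
  energies directly; nothing in the API forces one choice.
* The host's `S_CR` term is included in `ΔS_CR`. For a rigid host whose
  ensemble is dominated by one conformer it contributes essentially
  nothing, so including it is harmless in the rigid case and correct in
  the flexible one.

# CRE assembly

Sampled ensembles contain near-duplicates. Structures are compared
pairwise with three thresholds (`cre_thresholds()`):

| parameter | default | unit | role |
|---|---|---|---|
| `e_thresh` | 0.1 | kcal/mol | energies "equal" below this |
| `rmsd_thresh` | 0.125 | Å | geometries "identical" below this |
| `be_thresh` | 0.01 | relative | rotational constants "equal" below this |
| `window` | 6.0 | kcal/mol | retained range above the global minimum |

A pair is a *duplicate* (same energy, small RMSD), a *rotamer* (same
energy and rotational constants, large RMSD — an internal-rotation or
atom-numbering image of the same physical conformer), or a *conformer*.
The defaults are the published defaults of the CREST conformer sampler,
whose data model this package follows; all are configurable.

Assembly is greedy in ascending energy order: each structure is compared
against existing group representatives; duplicates are dropped (but
counted in the group's `occupancy`), rotamers join the group, conformers
open a new group. The energy-sorted order makes the procedure
deterministic and guarantees the global minimum is the first
representative — the grouping order is not prescribed by the method
itself, so determinism decided the choice. Raw sampler output is refined
through staged windows (default 15, 10, 6 kcal/mol), mirroring the
coarse-to-fine filtering of iterative samplers.

Occupancy counting is what lets basin populations be estimated from
quenched sampling output: for an equilibrium sampler, the fraction of
snapshots absorbed into a group estimates that conformer's Boltzmann
population.

Rotational constants are compared as `max |ΔB| / mean(B)` over the three
principal constants (the single finite constant for linear rotors); a
linear-vs-nonlinear pair is always distinct. The RMSD uses the Kabsch
algorithm with the SVD determinant correction, so only proper rotations
are searched and a structure never matches its mirror image. By default
all atoms enter the RMSD; `heavy_only = TRUE` excludes hydrogens, a common
choice in ensemble sorting that the method description leaves open —
all-atom is the stricter default, so it was chosen.

No atom-permutation matching is attempted: iterative samplers emit
index-consistent ensembles, and graph-isomorphism matching is a separate
problem out of scope here.

# RRHO thermochemistry

`rrho_thermo()` implements the standard ideal-gas expressions:
Sackur–Tetrode translation, closed-form linear/nonlinear rigid-rotor
rotation with a symmetry number (default 1 — point-group detection is out
of scope), harmonic-oscillator vibrational sums, zero-point energy, and
the RT pV term, yielding `g_rrho = ZPE + H_corr − T·S_total`. Frequencies
below zero raise an error naming the offending modes; the frequency
scaling factor defaults to 1.0. No quasi-RRHO low-frequency damping is
applied by default — the plain RRHO model is the stated method — though
the correction could be layered on by modifying the input frequencies.

Constants are centralized in `phys_constants()`:
`R = 1.98720425e-3` kcal/(mol·K), 1 Hartree = 627.5095 kcal/mol,
`B[MHz] = 505379.0 / I[amu Å²]`, default `T = 298.15` K.

# The synthetic generator

`toy_torsion_model()` builds a bead chain (bond length 1.53 Å, angle 111°,
carbon masses — standard aliphatic-chain geometry) whose energy is an
analytic function of its torsions: per-torsion cosine series
`Σ A_k (1 − cos(m_k(φ − φ_k)))`, optional nearest-neighbor coupling
`c Σ (1 − cos(φ_j − φ_{j+1}))`, and, in "complex mode", a polynomial
ellipsoid wall `w·max(0, q−1)^p` on the chain centroid that confines the
ligand the way non-covalent-interaction sampling confines weakly bound
aggregates. The default torsion is a 3-fold rotor with a 3 kcal/mol
barrier, the textbook magnitude for substituted alkanes. The wall is
removed for snapshot quenching, matching the practice of removing the
confining potential for geometry optimization.

Sampling (`run_mtd()`, `run_unbiased()`) is Metropolis Monte Carlo in
torsion space rather than force-based dynamics: the RMSD-Gaussian bias
`V_bias = Σ k_i exp(−α Δ_i²)` needs only energies, and every validation
target is distributional, not dynamical. A snapshot is deposited as a new
bias reference every `deposit_every` steps (default 50, capped at
`max_refs = 50`); recorded energies always exclude the bias, which the
tests verify by re-evaluating the bare potential. All randomness flows
from one integer seed, the caller's RNG stream is left untouched, and
`k_push = 0` reduces bit-for-bit to the unbiased walk.

On bias units: pushing strengths are conventionally quoted in
millihartree and the width parameter α in inverse Bohr, which is
dimensionally inconsistent with `exp(−αΔ²)`. The package treats α as a
per-length-squared quantity and converts Bohr→Å accordingly
(`alpha_unit = "bohr"`), with a direct per-Å² option — the inconsistency
is handled as a configuration choice, not silently resolved. Default
sampling parameters (`k_push = 1.5` mEh ≈ 0.94 kcal/mol, `α = 0.8` in the
Bohr convention, 300 K) sit mid-range of the published metadynamics
settings and are of the right magnitude relative to the default
3 kcal/mol barriers.

`brute_force_reference()` is the oracle: exhaustive evaluation on a
periodic torsion grid (≥ 36 points per torsion, capped at 1e7 total
points), local minima by steepest-descent basin assignment over the Moore
neighborhood, populations from the grid partition sum. The test suite
checks grid convergence (36 vs 360 points changes populations by < 1 %)
and cross-validates the basin populations against direct quadrature of
the Boltzmann density.

`quench_ensemble()` (BFGS relaxation of each snapshot to its basin
minimum) is deliberately part of the public surface even though it is
"only" plumbing: sampled snapshots carry thermal noise of order RT, which
would defeat the 0.1 kcal/mol duplicate threshold; quenching before CRE
assembly mirrors the snapshot geometry optimization every real workflow
performs.

**Population recovery, and which estimate to use.** For *unbiased*
sampling, snapshot basin fractions (`recover_populations()$occupancy`)
estimate populations directly, with batch-means standard errors that
respect Monte-Carlo autocorrelation (20 contiguous batches, floored at
the binomial error). For *metadynamics* runs the visit frequencies are
deliberately distorted, so the population estimate is instead Boltzmann
weighting of the *discovered, quenched* conformer energies
(`$populations`): the bias changes where the walker spends time, not the
energies of the minima it finds. The residual systematic difference
between single-point Boltzmann weights and basin-integrated populations
(unequal well curvatures) is kept well below the Monte-Carlo noise by the
near-congruent wells of the validation model.

**What the generator does and does not emulate.** It reproduces the
structural features the CRE machinery cares about — multiple torsional
minima, degenerate rotamer images, energy windows, confinement, a
history-dependent bias — with exact ground truth. It does not emulate
electronic structure: no bond breaking, no realistic frequencies or
solvation terms, no Cartesian dynamics, no atom-count scaling. Passing
tests therefore demonstrate the correctness of the ensemble bookkeeping,
thermodynamics and sampling logic, not the accuracy of any particular
energy model on real molecules.

# Benchmark statistics

`deviations()` uses the convention `d = ΔG_exp − ΔG_calc`, positive =
overbinding (the calculation binds more strongly than experiment).
`error_summary()` reports MAE, RMSE and the population standard deviation
of |d| (so `sd² = rmse² − mae²` exactly). The published summary-table SD
row is not exactly recoverable from the rounded per-ligand table, so SD
is reported but not asserted against it; the same applies to the
ensemble-column MAE/RMSE, which were evidently computed from unrounded
internal values (recomputing from the rounded table gives 3.20/3.65).
Packaged fixtures under `inst/extdata/` carry the per-ligand reference
values as plain CSV.

# Numerical choices

* Internal energies are always kcal/mol; file-side units are explicit
  flags (`"hartree"` is the multi-frame-XYZ default, matching the
  tight-binding ecosystem); coordinates are always Å.
* `ensemble_summary()` subtracts the minimum before exponentiating
  (log-sum-exp), so weights are overflow-safe and shift-invariant.
* Torsional frequencies come from a central-difference Hessian (step
  1e-3 rad) mass-weighted by effective inertias
  `I_j = Σ_a m_a |∂r_a/∂φ_j|²` computed from the embedding with the
  leading three atoms fixed (the driven-torsion convention; rotational
  recoil of the whole chain is neglected). Step halving changes
  frequencies by far less than 0.1 %.
* Degenerate inputs: single-atom structures have no rotational constants
  (error); single-structure ensembles give `S_CR = 0` and all binding
  flavors equal; empty ensembles, empty free-energy lists and
  non-decreasing window schedules raise errors rather than guessing.
* Problem sizes in the validation suite — 1000 random ensembles for the
  thermodynamic identity, 50 pairs for the RMSD-oracle comparison,
  10⁴ Monte-Carlo steps (2000 snapshots) for population recovery on a
  2-torsion model, 20 paired seeds for the enhancement comparison — were
  chosen so each check resolves its target effect with comfortable
  statistical margin on a single CPU.

# Limitations

* No standard-state (1 M) correction is applied to the binding free
  energies; the three flavors are differences of the quantities defined
  above, nothing more.
* No atom re-indexing in RMSD: permuted-but-identical inputs are treated
  as rotamers (by design), not merged as duplicates.
* The entropy `S_CR` inherits the CRE discretization; tightening the
  thresholds changes it.
* The toy generator's torsion-space sampling cannot probe Cartesian
  phenomena (ring puckering, inversion barriers, intermolecular pose
  exchange).
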