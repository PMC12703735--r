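---
title: "Constructing and validating a purpose-specific interatomic potential at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a purpose-specific interatomic potential at desk scale}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Machine-learned interatomic potentials (MLIPs, often called neural network
potentials or NNPs) replace expensive quantum-chemical energy and force
evaluations with a fitted regression model, at a cost of needing labeled
training configurations. For small organic (CHON) molecules the practical
questions are how to *generate* informative nonequilibrium configurations
cheaply, how to *label* them with a target that trains well, how to decide
*which* new configurations are worth labeling (active learning), and how to
*validate* the resulting potential for the downstream purpose — dynamics,
conformational energetics, vibrational spectra, and implicit-solvation
free-energy differences.

`nnpforge` implements that full construction-and-validation workflow as
testable R code. Every stage that would normally call a quantum-chemistry
package instead calls a built-in analytic "toy" potential that plays the
role of the reference method, so the complete pipeline — sampling, labeling,
committee active learning, training, molecular dynamics, spectroscopic
analysis and solvation-free-energy estimation — runs in minutes on one CPU,
deterministically under a seed. The toy reference is not chemically
accurate and is not meant to be; it is an exactly differentiable stand-in
with the right qualitative structure (bonded wells, angular stiffness,
torsional periodicity, nonbonded repulsion, an environment-dependent
solvent term).

# The reference oracle

The oracle (`ToyCalculator`) is a classical analytic surface bound to one
bonded topology:

* **Bonds**: Morse terms `De (1 - exp(-a (r - r0)))^2 - De` (or pure
  harmonic `k/2 (r - r0)^2` for the closed-form fixtures). Parameters come
  from a shared per-element-pair table (e.g. C–H: `De` 3.5 eV, `a`
  1.9 1/Å, `r0` 1.09 Å) with values of a plausible magnitude for covalent
  bonds but no claim of accuracy.
* **Angles**: `k (θ - θ0)^2` with `k` = 3 eV/rad² and `θ0` keyed to the
  central element (109.47° at C, 107° at N, 104.5° at O).
* **Torsions**: `v3 (1 + cos 3φ)` on every bonded quadruple, `v3` =
  0.02 eV, giving ethane-like 3-fold profiles.
* **Nonbonded**: Lennard-Jones for atom pairs three or more bonds apart.
* **Solvent**: the "implicit solvent" environment adds
  `Σ_pairs (σ_el(i) + σ_el(j)) f_c(r_ij)` with a smooth cosine cutoff
  `f_c` at 3 Å and per-element strengths σ (negative, i.e. stabilizing,
  largest for O and N). Gas and solvent energies differ by *exactly* this
  term, which is what makes the solvation studies exactly checkable.

Forces are analytic throughout and verified against central differences in
the test suite (to 1e-4 eV/Å on randomly perturbed fixtures; in practice
they agree to ~1e-9). Isolated-atom reference energies (a small per-element
table) define the cohesive energy `E_cohesive = E_total - Σ_i E_i`, the
default training target.

# Training structures

Two samplers generate nonequilibrium geometries:

* `perturbConformers()` scales coordinates about the molecular centroid by
  every factor in the inclusive grid 0.96, 0.98, …, 1.10 and then displaces
  every Cartesian component by an independent uniform draw in ±0.16 Å.
  The "cell scaling" of the published protocol is interpreted as coordinate
  scaling about the centroid, because the molecules are nonperiodic and an
  absolute cell-edge change has no meaning for an isolated molecule.
  Per-component uniform noise is the simplest reproducible reading of
  "random displacements of up to 0.16 Å" and is documented as such.
* `nmSample()` displaces the equilibrium along each Hessian eigenvector by
  ±k·Δ with Δ = 0.8 Å / 5, k = 1..5 — ten conformations per mode, zero
  excluded. For a 12-atom nonlinear molecule (30 modes) this is 300
  conformations; the grid reading (5 uniform steps per direction, endpoints
  at ±0.8 Å, step 0.16 Å) is the one consistent with ten per mode.

`filterElements()` applies the CHON element filter that defines the
chemical scope.

# The trainable potential

The shipped trainable model (`BaselineModel`) is deliberately *not* an
equivariant message-passing network: the pipeline, not the architecture, is
what this package exercises, and a GPU-free model keeps every test exact
and fast. It is an atom-centered descriptor model:

* **Descriptors**: per atom, sums of Gaussians of neighbor distances
  (8 radial centers between 0.6 Å and the 6.0 Å cutoff) in one channel per
  neighbor element, multiplied by a smooth cosine cutoff so values and
  gradients vanish at the cutoff. These are invariant to rotation,
  translation and permutation by construction.
* **Quadratic expansion** (`degree = 2`, the default): the per-atom energy
  is linear in the descriptors *and their pairwise products*. Purely radial
  linear models cannot represent angular (three-body) energy terms; the
  product features supply that sensitivity and reproduce any local surface
  to second order. This is the same trick quadratic SNAP-style potentials
  use.
* **Energy** is a sum of per-atom contributions (hence extensive and
  size-consistent beyond the cutoff); **forces** are exact analytic
  gradients via the chain rule.

Training minimizes
`energy_weight · MSE(per-atom energy) + force_weight · MSE(force components)`
with the 10:1 force:energy weighting, an 80/20 random train/validation
split, mini-batch Adam at learning rate 0.005 and batch size 5, plus a
small ridge penalty (`l2` = 1e-6 on scaled coordinates). Three numerical
choices matter and are worth stating:

* **Column scaling with a floor.** Descriptor-product columns span many
  orders of magnitude; columns are scaled to unit RMS with a floor at 1e-4
  of the largest scale so that numerically dead columns are not amplified
  into the active range.
* **Plateau-based learning-rate decay.** The learning rate halves when the
  training loss improves by less than 0.01% for 20 epochs, and training
  stops at 1e-5; small datasets additionally run at least 20 000 optimizer
  steps so every fit reaches a comparable optimization depth. The
  best-validation-loss parameters are returned, and the history records
  per-epoch train/validation MAEs.
* **Ridge pinning for committees.** The quadratic design has near-null
  directions; without the small L2 term two differently-seeded fits agree
  on the data but diverge off-distribution, which would keep committee
  disagreement artificially high. With it, the (convex) problem has one
  optimum and disagreement honestly reflects data coverage.

Because the model is linear in its parameters, the same objective also
admits a direct ridge least-squares solution, available as
`optimizer = "lsq"`. The iterative protocol is the default and is what the
chemical-accuracy and active-learning studies use; the direct solver is
used where a fully converged fit is the point (the solvation study, the
campaign's final models) — with a quadratic objective the two routes target
the same optimum, the solver simply reaches it exactly.

# Active learning

`runALLoop()` implements a two-model committee: each cycle trains two
models on the current dataset with different random initializations and
batch orders, then generates candidates by two processes — a fresh
perturbation pool ranked by committee energy disagreement `|E₁ - E₂|`, and
molecular dynamics driven by model 1 with every saved frame re-evaluated by
model 2. Structures whose disagreement exceeds the threshold (default
0.02 eV per molecule — the published protocol does not state its value, so
this default is prominently configurable) are labeled by the oracle,
de-duplicated (Kabsch-aligned RMSD below 1e-4 Å against existing records),
and appended. The loop stops when the maximum disagreement over a cycle's
newly generated configurations falls below the threshold, or after
`max_cycles`. Both models are retrained from scratch each cycle; MD
temperatures cycle through 100/200/300 K. Disagreement uses total energies
(a per-atom switch exists for mixed-size datasets).

# Dynamics and scans

`runMD()` is velocity-Verlet with Maxwell–Boltzmann initial velocities,
center-of-mass momentum removed. Thermostats are Langevin (BAOAB
splitting) and periodic velocity rescaling; these stand in for the CSVR
and Nosé–Hoover thermostats of the published protocols, since only ensemble
temperature control — not dynamical fidelity — is exercised downstream.
On the harmonic fixture at the 0.5 fs production time step the total-energy
error is bounded (≈2.5e-8 eV/atom/ps) and scales as dt², the symplectic
signature.

`minimizeStructure()` uses L-BFGS on the analytic gradient followed by a
Newton polish through the eigendecomposition of a finite-difference
Hessian (translational/rotational null modes dropped; shallow saddles —
soft torsions — are escaped by kicking along the negative-curvature
direction). Constrained minimization for `relaxedScan()` projects forces
onto the null space of one internal coordinate's gradient and restores the
coordinate exactly after every step — no SHAKE, because each scan point
constrains a single bond, angle or dihedral. Scan energies are returned
raw; conversion to relative energies is a reporting step
(`relativeEnergies()`) so that scan tables, cutoff tables and trajectory
cross-evaluation share one code path and one reference convention (the
lowest-energy conformer for scans and cutoff grouping, the first frame for
trajectory re-evaluation).

# Validation analytics

* `errorStats()`: RMSE/MAE over paired relative-energy series.
* `cutoffRmse()`: RMSE within cumulative (`ref < c`) or interval
  (`c_prev ≤ ref < c`) relative-energy groups over the default
  {50, 100, 200, 300, 400, ∞} kcal/mol grid; empty groups are marked NA,
  never zero.
* `crossEvaluate()`: the X@Y convention — re-evaluate a trajectory
  generated by method Y with calculator X, convert both series to
  relative energies, report RMSE/MAE over the first 1000 frames.
* `vdos()`: the mass-weighted velocity autocorrelation function averaged
  over time origins (every 10 frames by default — the origin stride is not
  specified by the published protocol), real FFT zero-padded to the next
  power of two with no window function, Lorentzian smoothing of 20 cm⁻¹
  FWHM, unit-maximum normalization. Center-of-mass drift is removed
  per frame, otherwise thermostatted (diffusive) trajectories bury the
  spectrum under a zero-frequency component. The last half of the
  trajectory is used by default.
* `rdf()`: pair-distance histograms normalized by the ideal shell volume;
  for a finite nonperiodic system the absolute scale is
  convention-dependent and only peak positions are meaningful — which is
  how the curves are used.

# The solvation study

`sfeEstimate()` computes `Δ = (E_solv - E_gas) · 23.0605` kcal/mol with
each energy evaluated at that environment's own optimized geometry (the
"@" convention). This is an electronic-energy difference at the bottoms of
the wells; no entropic or thermal corrections. For cohesive-target models
the isolated-atom references cancel in the difference.

`sfeRecoveryStudy()` is the end-to-end synthetic recovery exercise: 50
random CHON molecules (1–3 heavy atoms, chain skeletons, hydrogens filling
valences, all on the shared parameter tables). The "constructed offset" of
a molecule is its analytic solvent term at the gas equilibrium — the
element-keyed composition/topology variation across molecules is what
generates the spread of offsets (a per-molecule *arbitrary* offset would be
unlearnable by any element-keyed potential trained across molecules, so
the compositional construction is the only self-consistent one). Two
checks follow:

1. oracle deltas (with full geometry relaxation in both environments)
   against constructed offsets — agreement near r = 1 shows relaxation
   effects are second order;
2. deltas from a gas and a solvent baseline model, evaluated at the
   oracle-optimized geometries, against the oracle deltas.

Two design choices make the second check a fair test of the machinery
rather than of model capacity at hard extrapolation: the training
conformers sample *near the wells* (scaling 0.98–1.06, displacements up to
0.08 Å) because well-bottom energy differences are what Δ measures — the
aggressive nonequilibrium protocol serves MD robustness, not solvation
energetics; and the gas and solvent models are trained on
*geometry-paired* conformer sets with a single common train/validation
split, so per-geometry fit biases largely cancel in the difference —
the estimator is a paired comparison, as the paired ids of
`makeToyDataset()` intend.

# What the generator does and does not emulate

The synthetic systems exercise: element-keyed models and the CHON filter
(real element symbols, toy parameters), multiple bonded topologies, true
minima verified at construction (max |F| < 1e-6 eV/Å), stiff and soft
modes spanning ~100–3300 cm⁻¹, a smooth environment switch, and label
noise of exactly zero. They do not emulate: real electronic structure
(charge transfer, conjugation, reactivity — the bond graph is fixed),
conformational complexity beyond 3-fold torsions, intermolecular
interactions or condensed-phase effects, experimental noise, or the
size and chemical diversity of a real hydration-energy benchmark. Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
internally consistent at desk scale, not that any particular accuracy
would transfer to real molecules.

# Problem sizes

The shipped studies use sizes chosen so the whole suite runs comfortably
on one CPU: 500 training conformers for the chemical-accuracy study, a
40-record seed set and up to 10 cycles for active learning, 50 molecules ×
10 conformers per environment for the solvation study, 10–50 ps of MD for
thermostat and spectroscopy checks, and 2100 normal-mode conformers
(7 compounds × 300) for the cutoff analyses. All are parameters, not
constants, and scale up directly.

# Known limitations

* The trainable model is an invariant quadratic-descriptor potential; it
  cannot represent all many-body effects an equivariant network can, and
  its accuracy degrades on far-from-equilibrium geometries (visible in the
  interval cutoff tables at high relative energies).
* The committee uses energy disagreement only; force-based or
  ensemble-variance acquisition is out of scope.
* The mode-file format is bespoke plain text; quantum-chemistry log
  parsers are deliberately not included.
* Nonperiodic systems only: no lattice vectors, minimum-image convention
  or Ewald/PME electrostatics.
* The Langevin and rescale thermostats control ensemble temperature but
  are not substitutes for CSVR/Nosé–Hoover where dynamical correlation
  functions matter quantitatively; the VDOS fixture checks are run on
  analytic or NVE trajectories for that reason.
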