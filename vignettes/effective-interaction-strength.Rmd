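---
title: "Effective interaction strengths: model, conventions and validation"
author: "effint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective interaction strengths: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`effint` quantifies how strongly each pair of atomic species contributes to
the interaction (excess) internal energy of a simulated liquid, *in the
state the simulation actually sampled*. The starting point is the standard
relation between pair structure and configurational energy: assuming a
pairwise-additive force field, the excess internal energy of a fluid can be
written as a density-weighted integral of the pair potential over the pair
correlation function. `effint` keeps this integral resolved by species
pair,

$$U^{\mathrm{eff}}_{ab} = \frac{4\pi f_{ab} N_a N_b}{V}
  \int_0^{r_{\max}} r^2\, U_{ab}(r)\, g_{ab}(r)\, \mathrm{d}r,
  \qquad f_{ab} = \begin{cases} 1/2 & a = b\\ 1 & a \ne b,\end{cases}$$

and treats the individual terms — not only their sum — as the observable.
Because $g_{ab}(r)$ is an ensemble average over the trajectory, the
descriptor is configuration dependent: a demixed state concentrates
probability in like-species coordination shells and so inflates the
like-species strengths, while a mixed state shifts weight to the
cross-species terms, even though the underlying potentials $U_{ab}(r)$
never change.

Assumptions inherited from this construction:

* **pairwise additivity** of the nonbonded energy (LJ 12-6 plus, optionally,
  a bare Coulomb term $k_e q_a q_b/r$);
* **orthorhombic periodic boxes** with fixed particle numbers and fixed box
  over the analysed frames (minimum-image distances; $r_{\max}$ capped at
  half the smallest box edge);
* a "species" is an atom type *within* a molecule type, so the same element
  in two different molecules counts as two species; molecule-level energies
  are obtained by summation,
  $U^{\mathrm{eff}}_{AB} = \sum_{a \in A}\sum_{b \in B} U^{\mathrm{eff}}_{ab}$,
  with each unordered species pair entering once;
* the effective energy of mixing is the hetero-vs-homo difference
  $\Delta_{\mathrm{mix}} U^{\mathrm{eff}} = U^{\mathrm{eff}}_{AB} -
  (U^{\mathrm{eff}}_{AA} + U^{\mathrm{eff}}_{BB})$, an enthalpy-like
  indicator, *not* the total excess energy.

Two deliberate definitional choices are worth spelling out. First, the
package defines the total excess energy as the plain sum of the per-pair
effective strengths. A mixture-level closed form written with mole
fractions and a number density can be made dimensionally consistent with
this sum only under additional conventions, so `effint` does not implement
such a variant: the per-pair sum is the definition, and it is validated
directly against a brute-force energy oracle (below). Second, molecular
aggregates are always derived generically from the species-to-molecule-type
map, never from hand-enumerated per-system formulas, which guarantees the
bookkeeping identity
$U^{\mathrm{eff}}_{AA}+U^{\mathrm{eff}}_{BB}+U^{\mathrm{eff}}_{AB} =
\sum_{ab} U^{\mathrm{eff}}_{ab}$ for a two-type system.

## Counting conventions

The RDF normalisation and the prefactor of $U^{\mathrm{eff}}_{ab}$ use the
same pair count $f_{ab} N_a N_b$, so the product `prefactor * integral`
is exact by construction and the normalisation cancels out of the energy:
whatever convention generates $g$, the energy route reduces to a
shell-weighted sum over the actual pair counts. Two consequences:

* **Self pairs.** $f_{aa} N_a^2 = N_a^2/2$ differs from the exact distinct
  pair count $N_a(N_a-1)/2$ by a relative $1/N_a$. The default keeps the
  conventional $N_a^2/2$ (so $g \to 1$ normalisation carries a small finite-
  size bias); `exact_self_counting = TRUE` switches to $N_a(N_a-1)/2$,
  which makes the RDF route agree with the brute-force pair sum up to
  binning error alone. The energies themselves are identical either way,
  because the convention cancels.
* **Label splitting.** Relabelling a subset of one species as a new species
  and re-aggregating leaves molecule-level energies unchanged to machine
  precision — the test suite asserts this, and it is the reason the
  descriptor is stable under refinements of the species classification.

## Numerical choices

* **Binning.** Half-open bins $[\mathrm{lo}, \mathrm{hi})$; a distance
  exactly on an edge goes to the bin that edge opens. Default bin width
  0.05 Å, default $r_{\max}$ = half the smallest box edge. Exact spherical
  shell volumes $\tfrac43\pi(r_{k+1}^3 - r_k^3)$ are used instead of
  $4\pi r^2 \Delta r$, which matters in the first few bins.
* **Integration.** Trapezoidal rule on bin centers (`pracma::trapz`). Bins
  with $g = 0$ contribute an integrand of exactly zero — the divergent
  $r^{-12}$ core below first contact is never evaluated. No analytic tail
  correction is added by default because the empirical $g$ is only known up
  to $r_{\max}$; an LJ tail option exists (`tail_correction`) and is
  disallowed in combination with Coulomb terms, whose $r^2 \cdot r^{-1}$
  tail integral diverges.
* **Discretisation error.** Halving the default bin width moves the toy-
  system energies by well under 0.5 % (asserted in the suite); the
  step-function fixture, where the integral has the closed form
  $-\tfrac89\varepsilon\sigma^3$, is reproduced to ≪ 1 % at bin width
  $0.005\sigma$.
* **Degenerate inputs.** Self-RDFs require at least two atoms of the
  species; an all-zero $g$ yields $U^{\mathrm{eff}} = 0$ rather than an
  error; empty bins, missing species, oversized $r_{\max}$, triclinic
  lattices, duplicate atom indices and molecule ids spanning two molecule
  types are all rejected with specific messages.
* **Intramolecular pairs** are excluded by default: the descriptor targets
  intermolecular structure, and bonded neighbours would otherwise dominate
  the short-range bins with force-field-specific bonded geometry the
  nonbonded potential does not describe. Both behaviours are exposed
  (`exclude_intramolecular`), since published RDFs differ in this respect.

## The toy-system generator

The generator exists so that every pipeline stage can be exercised — and
the central identity validated — without a production MD engine. It
produces binary Lennard-Jones *point-particle* mixtures (species `S1`,
`S2`, common σ, independent ε₁₁, ε₂₂, ε₁₂):

* deterministic fixtures: a slab configuration (each species on a cubic
  sublattice in its own half-box — the fully demixed reference), an
  alternating-lattice mixture, and a seeded random mixture with a
  minimum-separation constraint (rejected above a sphere packing fraction
  of 0.35, near the random-sequential-addition jamming limit);
* a Metropolis Monte Carlo sampler: single-particle displacements, the
  acceptance rule $\min(1, e^{-\Delta E/k_B T})$ on the truncated
  (unshifted) LJ energy, energy tracked incrementally and cross-checked
  against a full recomputation at the end of the run (agreement asserted to
  10⁻⁸ kcal/mol). One sweep is $N$ attempted moves; snapshots are taken
  every `snapshot_interval` sweeps after a burn-in of 20 % of the sweeps.
  The maximum displacement is fixed for the whole run — no adaptive step
  tuning during production, which would break detailed balance; the default
  (0.3 σ) lands near 40 % acceptance at liquid-like densities. All
  randomness flows from one seed through R's Mersenne–Twister, which is
  recorded in run metadata; identical seeds give bit-identical
  trajectories.

Validation conditions used by the test suite and the acceptance script
(chosen once as representative liquid-state conditions): the oracle
identity runs 200+200 particles in a 26 Å box (reduced density ≈ 0.62,
reduced temperature ≈ 1.2), 300 sweeps with snapshots every 2 sweeps after
burn-in (~120 frames); the dilute-limit check samples a two-particle system
for 60 000 sweeps; the phenomenology comparison uses 96+96 particles with
ε₁₂ = 0.02 kcal/mol at 110 K from a slab start versus matched
(geometric-mean) ε₁₂ at 260 K from a random start.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: molecules with internal structure (bonds, angles,
intramolecular exclusions beyond the monoatomic case), electrostatics and
long-range solvers, thermo-/barostats and density equilibration, and the
slow collective dynamics of real demixing. The two-run phenomenology check
therefore compares *prepared* separated and mixed states rather than
waiting for a spontaneous transition; it asserts the ordering of the
hetero coupling and of $\Delta_{\mathrm{mix}} U^{\mathrm{eff}}$ between the
regimes, which is the descriptor's qualitative signature.

## Validation strategy

The load-bearing test is an identity, not a statistical property: for any
configuration, the RDF route with exact self counting must reproduce the
trajectory-averaged brute-force sum of distinct-pair energies truncated at
$r_{\max}$, to within binning error (< 1 % at the default bin width). The
brute-force sum is computed by an independent $O(N^2)$ kernel that never
touches histograms. Supporting checks: the closed-form step-function
integral; the two-particle Metropolis run, whose binned $g(r)$ must
correlate (> 0.99) with the Boltzmann factor $e^{-U(r)/k_B T}$ — for two
particles in a periodic box this proportionality is exact below half the
box length; swap symmetry, label-splitting invariance and extensivity
under box doubling; and the combinatorial contract that $K$ species yield
$K(K+1)/2$ pair results.

## Tunable parameters

| parameter | unit | default | notes |
|---|---|---|---|
| `bin_width` | Å | 0.05 | RDF resolution; energies stable to < 0.5 % under halving |
| `r_max` | Å | half min box edge | also the integration limit; no tail correction by default |
| `exclude_intramolecular` | – | `TRUE` | set `FALSE` to reproduce RDF conventions that keep bonded pairs |
| `exact_self_counting` | – | `FALSE` | `TRUE` for oracle-grade agreement at small $N_a$ |
| `include_coulomb` | – | `FALSE` | adds $k_e q_a q_b / r$ to the integrand |
| `stride` | frames | 1 | analyse every stride-th trajectory frame |
| `max_displacement` (MC) | Å | 0.3 σ | fixed during a run; ~40 % acceptance at liquid density |
| `burn_in_fraction` (MC) | – | 0.2 | discarded before the first snapshot |

The ideal-gas kinetic term $\tfrac32 N k_B T$ and the equimolar ideal
mixing-entropy value $T R \ln 2$ are provided as helpers for placing the
effective strengths next to entropic scales. The entropy helper evaluates
$T R \ln 2$ with $R = 1.987$ cal mol⁻¹ K⁻¹ and returns the bare number of
the field's customary reporting convention (275.5 at 200 K, 413.2 at
300 K); note that this number equals the energy in cal/mol even though it
is conventionally quoted alongside kcal/mol quantities — the helper
reproduces the convention rather than silently rescaling it.

## Known limitations

* Only orthorhombic (including cubic) fixed boxes; no triclinic cells, no
  variable-N or variable-V trajectories, no binary trajectory formats.
* The Coulomb term is the bare $1/r$ form; there is no Ewald/mesh
  treatment, so charged systems are only meaningful within the direct
  cutoff. Whether long-range electrostatics beyond the cutoff should enter
  the descriptor at all is left to the user; the package only ever
  integrates the bare pair forms against the empirical $g$.
* The descriptor is an enthalpy-like diagnostic, not a free energy: it
  carries no entropic information, and $\Delta_{\mathrm{mix}}
  U^{\mathrm{eff}}$ is not a mixing free energy.
* Desk-scale toy systems validate the machinery, not force-field-quality
  numbers; production-scale values (hundreds of molecules, nanoseconds of
  sampling) require trajectories from a real MD engine, which this package
  only analyses.
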