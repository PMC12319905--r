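# effint — effective interaction strengths in simulated liquid mixtures

Whether two molecular liquids mix or demix is decided by the interplay of
many pairwise interactions, but the interaction *parameters* alone cannot
tell you which of them actually matter in the state a simulation sampled.
`effint` computes a configuration-dependent, species-pair-resolved
descriptor of interaction enthalpy — the **effective interaction
strength** — from ordinary trajectory output, so that the enthalpic role of
every atom-type pair (and of whole molecule types) can be read off a single
table. It is aimed at people analysing classical MD or MC simulations of
liquid mixtures who want to know *which* interactions drive an observed
mixing or demixing, not just the total energy.

## The descriptor

For species $a$ and $b$ with pair potential $U_{ab}(r)$ (Lennard-Jones 12-6,
optionally plus a Coulomb point-charge term) and partial radial distribution
function $g_{ab}(r)$, the effective interaction strength is

$$U^{\mathrm{eff}}_{ab} \;=\; \frac{4\pi f_{ab} N_a N_b}{V}
  \int_0^{r_{\max}} r^2\, U_{ab}(r)\, g_{ab}(r)\, \mathrm{d}r ,$$

where $N_a$, $N_b$ are the species counts, $V$ the box volume and
$f_{ab} = \tfrac12$ for $a=b$ (1 otherwise) counts each unordered pair once.
It is the species-resolved contribution to the excess (configurational)
internal energy: summing $U^{\mathrm{eff}}_{ab}$ over all pairs recovers the
interaction part of $U = \tfrac32 N k_B T + U^{\mathrm{excess}}$. Because
$g_{ab}$ depends on the sampled configurations, the same force field gives
different strengths in mixed and demixed states.

Species-pair strengths aggregate to molecule-type energies
$U^{\mathrm{eff}}_{AB} = \sum_{a\in A}\sum_{b\in B} U^{\mathrm{eff}}_{ab}$,
and the **effective energy of mixing**

$$\Delta_{\mathrm{mix}} U^{\mathrm{eff}} = U^{\mathrm{eff}}_{AB}
  - \left(U^{\mathrm{eff}}_{AA} + U^{\mathrm{eff}}_{BB}\right)$$

is negative when mixing is enthalpically favoured under this descriptor.

Units throughout: Å, kcal/mol, elementary charges, Kelvin
($k_B = 0.0019872041$ kcal mol⁻¹ K⁻¹, $k_e = 332.06371$ kcal Å mol⁻¹ e⁻²).

## What is in the package

* readers/writers for extended-XYZ trajectories, plain-text topologies
  (species label, molecule id, molecule type, charge per atom) and
  force-field tables (per-species ε, σ, q; geometric or Lorentz–Berthelot
  combination; per-pair overrides);
* partial RDFs with periodic minimum-image distances, exact shell-volume
  normalisation and optional intramolecular exclusion;
* the effective-strength integrals, molecular aggregation and
  $\Delta_{\mathrm{mix}} U^{\mathrm{eff}}$;
* a deterministic toy-system generator (slab, random-mixture, lattice) and
  a seeded Metropolis Monte Carlo sampler for binary Lennard-Jones fluids,
  plus a brute-force pair-energy oracle used to validate the RDF route;
* a command-line interface (`rdf`, `effint`, `simulate`, `sweep`) writing
  CSV/JSON plus a rerun manifest.

## Worked example

A binary Lennard-Jones mixture with a deliberately weak cross attraction
(ε₁₂ = 0.1 vs ε₁₁ = ε₂₂ = 0.3 kcal/mol) at 140 K, sampled by the built-in
Metropolis engine and analysed with the standard pipeline:

```r
library(effint)

cfg <- toy_sim_config(N1 = 100, N2 = 100, box_length = 22, temperature = 140,
                      epsilon_11 = 0.3, epsilon_22 = 0.3, epsilon_12 = 0.1,
                      sigma = 3, r_cut = 9, n_sweeps = 200, seed = 1,
                      snapshot_interval = 5)
traj <- run_metropolis(cfg)
ff   <- toy_forcefield(cfg)
res  <- effective_strength_table(traj, traj$topology, ff,
                                 bin_width = 0.05, r_max = 9)
as.data.frame(res)
aggregate_molecular(res, c(S1 = "S1", S2 = "S2"), "S1", "S2")
```

which prints

```
  species_a species_b f_ab N_a N_b  V_A3 integral_A3_kcal_mol prefactor_A_minus3 u_eff_kcal_mol
1        S1        S1  0.5 100 100 10648              -10.755              5.901         -63.46
2        S1        S2  1.0 100 100 10648               -1.912             11.802         -22.57
3        S2        S2  0.5 100 100 10648              -10.437              5.901         -61.58

Molecular effective interaction energies (kcal/mol)
  U_eff(S1-S1) = -63.4615
  U_eff(S2-S2) = -61.585
  U_eff(S1-S2) = -22.57
  Delta_mix U_eff = 102.476  (demixing enthalpically favoured)
```

Each row stores the integral and the density prefactor separately;
`u_eff = prefactor * integral` exactly. The weak cross attraction shows up
directly: the hetero strength (−22.6 kcal/mol) is far smaller in magnitude
than either homo strength, and the positive
$\Delta_{\mathrm{mix}} U^{\mathrm{eff}} = +102$ kcal/mol says the sampled
state pays an enthalpic penalty for mixing. The brute-force pair-energy sum
over the same snapshots gives −147.76 kcal/mol against −147.62 kcal/mol for
the RDF route (0.1 % apart), the package's central internal consistency
check.

The same analysis runs from the shell on any extended-XYZ trajectory:

```sh
inst/cli/effint simulate --config sim.yaml --out-dir run/
inst/cli/effint effint --traj run/trajectory.xyz --topology run/topology.txt \
    --ff run/forcefield.txt --out-dir run/analysis
inst/cli/effint sweep --config sim.yaml --temperatures 120,160,200,240 --out-dir sweep/
```

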