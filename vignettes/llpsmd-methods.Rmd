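---
title: "llpsmd: model, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{llpsmd: model, methods and numerical choices}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`llpsmd` simulates a minimal coarse-grained model of intrinsically
disordered protein regions (IDRs) and measures how the chain's
conformational ensemble controls liquid--liquid phase separation (LLPS).
This vignette is the package's account of the model, the numerical methods
behind each stage, and the design decisions that were genuinely open.

## The model

Each protein is a homopolymer of $N$ beads (one bead per group of residues)
in implicit solvent. Three terms define the energy, all in reduced units
($\sigma$ the bead diameter and unit of length, $\epsilon$ the LJ well depth
and unit of energy, bead mass $m = 1$):

* **Non-bonded attraction** between all bead pairs except directly bonded
  ones: $u_{LJ}(r) = 4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right]$,
  truncated and *unshifted* at $r_c = 2.5\,\sigma$. The single well depth
  stands in for the aggregate of weak, promiscuous protein--protein
  interactions; one bead--bead contact is one unit of multivalent binding.
* **Bonds** between consecutive beads:
  $u_{bond}(r) = K_{bond}\,(r - r_0)^2$ with $K_{bond} = 40\,\epsilon/\sigma^2$
  and $r_0 = 1\,\sigma$. Note the printed form carries no $1/2$ prefactor;
  the effective spring constant is $2K_{bond}$.
* **Bending** on each triplet of consecutive beads:
  $u_{bend}(\theta) = K_\theta\,(\theta - \theta_0)^2$ with
  $\theta_0 = \pi$. $K_\theta^* \in \{0, 1, 3, 20\}$ spans fully flexible
  random coils to fully extended chains; it is the single dial for the
  conformational ensemble. Globular (folded) variants are instead frozen
  rigid bodies with no internal degrees of freedom.

Reduced units map to physical ones through $\epsilon/k_B = 119.81$ K,
$\sigma = 3.405$ Å and $m = 39.1$ amu (`unit_system()`, `convert_units()`),
so $T^* = 2$ is roughly 240 K and $\rho^* = 1$ is 1.64 g/cm$^3$.

Heterotypically driven LLPS uses 50:50 binary mixtures in which unlike
species attract with $\epsilon_{He} = 2\,\epsilon_{Ho}$
(`force_field(species = c("A","B"), heterotypic_factor = 2)`).

### The cutoff convention and energy bookkeeping

Whether the LJ potential is shifted at the cutoff is not part of the model
statement; `llpsmd` adopts the truncated, *unshifted* convention (the
default of the major MD engines for this pair style) and treats it as fixed:
binodals and $T_c^*$ are sensitive at the few-percent level to this choice,
so it is documented rather than exposed as a knob.

One consequence is worth spelling out. The unshifted tally jumps by
$u_{LJ}(r_c) \approx -0.0163\,\epsilon$ every time a pair crosses the
cutoff, while the forces -- and therefore the dynamics -- are identical to
the shifted convention. The quantity the integrator actually conserves in
NVE is the total energy under the *shifted* tally. The engine logs the
within-cutoff pair count (`eps_in_cutoff`), and `nve_conserved_energy()`
reconstructs the conserved quantity; drift is measured on it. On a 20-bead
chain at $\Delta t^* = 4\times10^{-4}$ the drift is
$\sim 5\times10^{-5}\,\epsilon$/bead per $10^5$ steps.

## The engine

A velocity-Verlet core (compiled, single-threaded, deterministic given the
seed) with:

* **Nose--Hoover chains** (length 3, relaxation $\tau_T^* = 0.4$) as the
  default NVT thermostat, matching the reference engine's setup. The chain
  length is a documented default, not asserted to be the original one.
* **Langevin dynamics** (BAOAB splitting, friction $1/\tau_T$) as an
  alternative. For very small systems the global Nose--Hoover chain is
  weakly ergodic: a lone 20-bead chain under NH mixes conformations with
  multi-million-step memory, and its running mean $R_g$ wanders by
  $\pm 10$--$15\%$ on affordable run lengths, while its kinetic temperature
  and a 540-bead bulk box (where NH and Langevin agree to a fraction of a
  percent in energy) are perfectly well behaved. Langevin is therefore the
  default for single-chain sampling, and the thermostat-independence check
  in the test suite compares the two thermostats on the bulk system where
  the comparison is statistically meaningful.
* **Rigid bodies**: per-chain quaternion propagation (COM force plus torque,
  body-frame inertia from a Jacobi eigendecomposition). Bead positions are
  always reconstructed from the quaternion, so internal distances are
  conserved to machine precision by construction; rigid chains carry no
  internal bonded terms and no intra-chain LJ.
* **Pressure control** for preparation runs only: a Berendsen-type
  isotropic (or z-only) box rescale towards a target pressure,
  $\tau_p^* = 0.401$. The mean pressure converges to the target; pressure
  *fluctuations* are not canonical, which is immaterial for its only use --
  compressing a starting liquid. All production coexistence runs are NVT.
* **Neighbour search**: cell-binned Verlet lists with a $0.4\,\sigma$ skin,
  rebuilt when any bead has moved more than half the skin; candidate sets
  provably cover the exact $O(N^2)$ pair set (tested against a brute-force
  oracle).
* **Overlap guard**: below $0.3\,\sigma$ the LJ core can be replaced by a
  linear continuation (finite energy, constant force). This cap is used
  during construction and annealing only, never in production; overlapping
  pairs are always flagged.
* Timestep $\Delta t^* = 4\times10^{-4}$ throughout. Runs abort with a
  diagnostic if the total energy per bead explodes.

## Builders

* `build_chain()` makes straight rods (exact $r_0$ spacing; the discrete rod
  has $R_g = \sqrt{r_0^2 (N^2-1)/12}$, a closed form used widely in the
  tests) and self-avoiding random walks.
* `build_bulk()` places replicas on a cell lattice at the exact requested
  density, randomises conformations and orientations, and removes
  construction overlaps with a short steepest-descent relaxation on the
  capped potential (flexible chains) or rejection packing (rigid chains).
  The slab's condensed block is built directly at $\rho^* = 0.7$ -- a dense
  liquid for every variant studied -- rather than prepared by NpT
  compression; the choice only affects how fast the slab equilibrates.
* `carve_slab()` re-images every molecule whole, then elongates the box
  threefold along z with the block centred: the classic direct-coexistence
  geometry.
* `make_globule()` generates the rigid reference structures. The original
  work does not describe how its semi-compact ($R_g^* = 2.40$) and compact
  ($R_g^* = 1.75$) 20-bead globules were made; annealing to a target $R_g$
  is this package's choice. A straight chain is collapsed by Langevin
  dynamics at $T^* = 0.5$; snapshots are screened for the target $R_g$, and
  the selected snapshot is settled by a brief, heavily damped quench at
  $T^* = 0.01$ that relaxes bond lengths without disturbing the fold.
  Compact folds can strain a bond or two beyond 5% of $r_0$ (bond stiffness
  and LJ packing are comparable forces at these densities), so candidates
  are additionally screened for bonds within 5%; if the step budget runs out
  first the closest fold is returned with a warning. Acceptance window:
  $\pm 0.05\,\sigma$ on $R_g$.

## Direct coexistence and the critical point

For each temperature the slab is run NVT; the density profile along z
(`density_profile`) is averaged over production frames. Phase densities
come from `coexisting_densities()`: the two Gibbs dividing surfaces are
located where the (lightly smoothed) profile crosses the midpoint density,
and bins farther than `interface_margin` (default $3\,\sigma$; the original
work says only that interfacial fluctuations are excluded) from either
surface are averaged per phase. A profile without a resolvable two-plateau
structure (relative contrast below 0.25) is reported as an explicit
*homogeneous* classification, never as a density pair. Equilibration is
declared when the plateau means agree across the two halves of the run
(`stationary` column) -- the original work states no criterion, so this one
is the package's.

The critical point comes from the laws of critical exponents and
rectilinear diameters,
$$(\rho_h^* - \rho_l^*)^{\alpha} = s_1 (1 - T^*/T_c^*), \qquad
(\rho_h^* + \rho_l^*)/2 = \rho_c^* + s_2 (T_c^* - T^*),$$
with $\alpha = 3.06$ (the 3D Ising exponent on this parametrisation). Both
laws are *linear in* $T^*$, so the joint unweighted least-squares problem
reduces to two linear regressions: the first yields $T_c^* = -a/b$ and
$s_1 = a$ from intercept and slope, the second $s_2$ and $\rho_c^*$ given
$T_c^*$. This closed form recovers generating parameters from noise-free
synthetic binodals to $10^{-9}$ (the core fit oracle in the tests) and
needs no starting values or convergence tolerance. A fit whose $T_c^*$ does
not exceed the highest fitted temperature is a flagged failure.
Uncertainties come from bootstrap resampling of the coexistence points,
reported as normal-theory intervals built on the bootstrap standard error:
with the handful of points a binodal table holds, percentile intervals
undercover (measured ~89% at nominal 95% on seven-point tables with 1%
noise) while the normal form covers at or above nominal.

## Observables

* $R_g$ and $D_{E-E}$ are computed on whole (unwrapped) molecules; the
  engine propagates unwrapped coordinates, and `unwrap_chain()` restores
  wholeness for wrapped input. A bond longer than $1.5\,r_0$ is treated as a
  wrapping artefact and raises an error rather than a silent wrong number.
* **Intra-molecular contacts** (dilute-phase compaction measure): pairs
  within $1.2\,\sigma$ separated by at least `min_sep` beads along the
  chain. The field's phrasing ("excluding bonded beads") leaves the second
  neighbour ambiguous. Both conventions are implemented; the default
  `min_sep = 3` additionally excludes $|i-j| = 2$ pairs, whose distance is
  set by chain geometry rather than attraction. This default is pinned by
  two consistency checks: a straight rod must score zero (true under both),
  and the reference tallies for the flexible 20-bead variants at
  $T^* = 1.9872$ (2.0 contacts at $K_\theta^* = 1$, 0.3 at $K_\theta^* = 3$,
  3.4 for the coil, 18 for the 80-bead coil) are reproduced by `min_sep = 3`
  only -- `min_sep = 2` roughly doubles the coil count. The published
  tallies for the *rigid globular* variants are much smaller than any
  bead-pair count a compact 20-bead fold admits, so they appear to follow a
  different (unstated) convention; they are not used as checks.
* **Inter-molecular contacts** (liquid-network connectivity): bead--bead
  pairs between different chains within $1.2\,\sigma$, counted per chain.
  Pair counting is the default (the system-wide sum is even -- each contact
  feeds two chains -- which the tests assert); unique-foreign-bead counting
  is available as `mode = "beads"` since the field's phrasing admits both.
  Condensed-phase measurements follow the stated protocol: an NVT box at
  the coexisting density and temperature.
* **Phase assignment** classifies chain centres of mass against the
  dividing surfaces with a buffer (default $1\,\sigma$); chains inside the
  buffer are `unassigned` and excluded from per-phase histograms.
* Distribution summaries use linear-interpolation quartiles (R's type 7),
  fixed and documented; the two-sample Kolmogorov--Smirnov comparison is the
  classical $D = \sup|ECDF_a - ECDF_b|$ with the asymptotic p-value (via
  `stats::ks.test`).
* Dilute-phase single-chain observables are measured on an isolated chain
  in a large box: the dilute phase at coexistence is near-ideal (its density
  at the probed temperatures is below $0.05\,\sigma^{-3}$), so chain--chain
  encounters are rare. This is an approximation to sampling the actual
  dilute slab, adopted deliberately for its enormously better statistics at
  fixed cost.

## What the synthetic generator does and does not emulate

`generate_fixtures()` and `synthetic_binodal()` construct every file-based
test input: rods and coils with closed-form observables, a two-rod contact
geometry (register-matched pairs at $1.0\,\sigma$, off-register at
$\sqrt{2}\,\sigma$, hence exactly $N$ contacts per chain), ideal-gas
two-phase slabs with known plateau densities, and binodal tables satisfying
the two critical laws exactly (plus a 1%-noise variant). These fixtures
have no thermal correlations, no interfacial width fluctuations and no
finite-size effects; tests passing on them verify the *analysis machinery*
(profiles, dividing surfaces, fit, contact counting), not the physics of
the simulations. The physics is checked separately, by the property tests
(energy conservation, equipartition, thermostat independence, the rigid-rod
limit) and by scaled-down reruns of the reference state points.

## Problem sizes, finite-size effects and limitations

Test-suite and acceptance-script simulations are scaled down to what a
single CPU core handles in minutes; these sizes are the package's choices:

* Single-chain reference runs: $5\times10^6$ steps for 20-bead chains,
  $10^7$ for the 80-bead coil (acceptance script), 20% discarded as
  equilibration; shorter variants ($0.8$--$6\times10^6$) in the test suite.
  Statistical error on mean $R_g$ at these lengths is 1--3%. The 80-bead
  coil starts from a self-avoiding random walk, which sits near the
  equilibrium coil size, so the budget is spent sampling rather than
  collapsing a rod.
* Direct coexistence: 18--64 replicas of 20-bead chains over 3--4
  temperatures. The development-scale sweep uses $3\times10^5$ steps of
  equilibration plus $3\times10^5$ of production per temperature; the test
  suite runs a further-reduced sweep ($1.2\times10^5$ plus $8\times10^4$,
  with subsequent temperatures laddered from the previous final state) --
  all against the original 512/1024 replicas. Two finite-size effects
  follow: the fitted $T_c^*$ carries a bias of a few percent, and the
  dilute branch is depleted (at 64 replicas the vapour phase holds only
  a few chains, so $\rho_l^*$ is underestimated at low $T^*$), which mainly
  distorts $\rho_c^*$, much less $T_c^*$. The published phase diagrams at
  full replica counts are explicitly not reproduced.
* The $\sim$15-contacts / $\rho^* \approx 0.35$ LLPS-threshold universality
  observation is checked only as a qualitative trend (connectivity ordering
  with $K_\theta^*$), not as a quantitative target.

Further limitations: no electrostatics, no sequence heterogeneity, no
explicit solvent (all by the model's design); no GPU or multi-thread path;
NpT is a preparation tool, not a production ensemble; trajectories are held
in memory (snapshot cadence controls the footprint).

## Reproducibility

Every stochastic stage takes an integer seed and is bit-reproducible
single-threaded: builders, velocity draws, dynamics, bootstrap. `run_md()`
records the seed and settings in the returned trajectory; the CLI logs the
package version, the merged configuration and the seed on every invocation.
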