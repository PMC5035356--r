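---
title: "Predicting crystallographic B-factors from replicate MD ensembles"
author: "fluctB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting crystallographic B-factors from replicate MD ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctB)
```

## The problem

The B-factor (Debye–Waller factor) of an atom in a refined crystal
structure is $B = 8\pi^2\langle u^2\rangle$, where $u$ is the atom's
displacement from its mean position. It mixes genuine thermal motion with
conformational and lattice disorder, and it can in principle be predicted
from physics alone: simulate the molecule, superpose the saved
conformations, and convert the residual mean-square fluctuations to $B$.

`fluctB` implements that pipeline for ensembles of short, *independent*,
replicate trajectories:

1. an ensemble of $N$ trajectories is generated (or read from multi-model
   PDB/XYZ files), each replicate differing only in its random seed (and
   optionally its starting conformation);
2. each trajectory is rigid-body superposed with a **two-step** procedure:
   every saved frame is first fitted (Kabsch, proper rotations only,
   unweighted) onto the *first saved frame* on the selected atoms and the
   selected coordinates are averaged; every original frame is then refitted
   onto that average conformation. One averaging pass, no iteration;
3. per atom, $B_i = \frac{8\pi^2}{3}\langle\|r_i-\bar r_i\|^2\rangle$ over
   the fitted frames (the PTRAJ/cpptraj "atomicfluct" convention; under
   isotropy this equals $8\pi^2\langle u^2\rangle$ with
   $\langle u^2\rangle$ the one-dimensional mean-square displacement);
4. the ensemble value of an atom is the *mean over the $N$ replicates* of
   its per-replicate B, with standard error
   $\mathrm{SE} = s_{N-1}/\sqrt N$. For that reason $N = 1$ is rejected
   outright.
5. calculated profiles are compared to experimental B-factor columns by
   RMSD (both the mean of per-replicate RMSDs $\pm$ SE and the RMSD of the
   ensemble-mean profile are reported, since either convention appears in
   practice) and by the Pearson correlation of the ensemble-mean profile.

Selections follow side-chain B-factor conventions: `"CA"` is all alpha
carbons, `"CG"` is all atoms named CG or CG2. CG1 (Ile/Val) is *not*
included in `"CG"` — this mirrors the stated convention the pipeline
reproduces, implemented literally rather than second-guessed. Backbone and
side-chain profiles are computed in fully independent passes that each use
their own selection for both the fit and the fluctuations.

## Uniform mass scaling and the $\sqrt c$ time rule

Multiplying every atomic mass by $c$ leaves the potential — and hence the
Boltzmann distribution and the B-factors — untouched, but rescales every
dynamical time by $\sqrt c$: the harmonic-oscillator period is
$2\pi\sqrt{m/k}$. The canonical "high-mass" factor $c = 100$ therefore
slows dynamics exactly tenfold, so a simulation at a nominal 1.00 fs
timestep has the time resolution of a standard-mass run at 0.10 fs, and
50 ps of nominal high-mass clock time corresponds to 5 ps of standard-mass
dynamics. `convert_time()` applies this rule; `integrate_system()`
reproduces it to machine precision (an NVE run with masses $\times c$ and
initial velocities $\div\sqrt c$ retraces the standard-mass trajectory at
timestep $\Delta t/\sqrt c$).

A caveat we surface rather than resolve: for tenfold mass *reduction*
($c = 0.1$) a widely quoted bookkeeping treats the time compression factor
as 10, whereas the dimensional identity $[m]([l]/[t])^2 = \text{const}$
that motivates the rule gives $\sqrt{10}\approx 3.16$. `convert_time()`
always follows $\sqrt c$ and emits a warning for $c < 1$ so the
discrepancy is never silent. Because the high-mass durations in the
literature may denote either nominal clock time or standard-mass
equivalent time, the pipeline provenance echoes both readouts.

`rewrite_prmtop_masses()` applies a uniform factor to the `%FLAG MASS`
block of an AMBER topology and leaves every other byte of the file intact;
no derived section needs renormalising because the scaling is uniform.
Only a single global factor is supported.

## The toy MD engine

The paper-scale experiments behind this method need cluster-scale
explicit-solvent simulations; those are out of scope here. Instead the
package ships a small deterministic MD engine whose equilibrium
fluctuations are *analytically known*, so every stage of the pipeline can
be validated end-to-end:

* **Potentials** — per-atom harmonic tethers (independent isotropic
  springs, $\langle u^2\rangle = k_BT/k$ per axis, so
  $B = 8\pi^2 k_BT/k$ exactly) and elastic networks (springs of stiffness
  $k$ between reference-structure contacts within a cutoff, default 8 Å,
  mirroring common nonbonded cutoffs).
* **Integrators** — velocity Verlet in NVE; Berendsen weak coupling
  ($\lambda = \sqrt{1+(\Delta t/\tau)(T_0/T-1)}$); and a Langevin
  thermostat using the BAOAB splitting, whose Ornstein–Uhlenbeck substep
  is exact. We chose BAOAB over impulse-style (BBK) discretisations
  because its configurational sampling of harmonic potentials is accurate
  to $O(\Delta t^2)$ with a very small prefactor, and configurational
  fluctuations are precisely what every B-recovery test measures.
  Berendsen does not guarantee canonical configurational fluctuations, so
  all quantitative B-recovery checks use Langevin; Berendsen is provided
  for protocol fidelity (heating ramps at e.g. 10 K/ps are supported as a
  time-dependent thermostat target).
* **Units** — Å, fs, amu, kcal/mol, K; $k_B = 0.0019872041$
  kcal/(mol·K); the single conversion constant
  $4.184\times10^{-4}$ (kcal/mol $\to$ amu Å$^2$/fs$^2$) is applied
  exactly once, in the acceleration.
* **Determinism** — all randomness (Maxwell–Boltzmann velocities,
  Langevin noise) flows through R's RNG, so a seed fully determines a
  trajectory; replicate ensembles differ only in their seeds. Timestep
  and saving cadence default to 1.00 fs and every $10^3$ steps, the
  protocol the package emulates. Centre-of-mass momentum is removed at
  initialisation only; rigid-body drift accumulated during a run is left
  for the superposition step to remove, deliberately exercising the
  fitting path.
* **Exact trajectory identity under mass scaling** holds in NVE only.
  Berendsen's $\lambda$ couples the clock-dependent $\tau$, which breaks
  step-for-step identity unless $\tau$ is co-scaled; this is documented
  rather than silently patched, and the equivalence tests run in NVE.

### The analytic oracle

For a harmonic system at temperature $T$ the equilibrium covariance of
coordinates is $k_BT\,H^{+}$ with $H$ the mass-unweighted Hessian
(units kcal/mol/Å$^2$) and $H^{+}$ its pseudo-inverse; per atom
$B_i = \frac{8\pi^2}{3}\mathrm{tr}\,C_{ii}$. For elastic networks the six
rigid-body zero modes are projected out (more than six near-zero modes
means the network is disconnected and is an error); tethers have none.

Two regimes limit the oracle, and the shipped test systems are chosen to
respect them:

* **Mechanical rigidity.** Central-force springs constrain only pair
  distances, so a sparse network (fewer than $3n-6$ independent
  constraints, e.g. a thin helix with only $i\pm1, i\pm2$ contacts) is
  floppy. The default 30-node test system is a compact jittered grid at
  ~4 Å spacing — protein-like packing — whose 8 Å network has ~190
  contacts and minimum node degree 5.
* **Linearisation.** The Hessian result is the small-fluctuation limit of
  the (anharmonic) spring network. The ENM recovery experiments therefore
  run at 50 K with $k = 1$ kcal/mol/Å$^2$, where the largest RMSF
  (~0.5 Å) is well below the shortest spring length; at 300 K the
  floppiest nodes leave the linear regime and the simulated B exceeds the
  analytic value — a property of the oracle, not a pipeline defect.

### Superposition removes degrees of freedom

Rigid-body fitting of $n$ isotropically fluctuating atoms absorbs the six
fitted degrees of freedom, shrinking measured fluctuations by about
$6/(3n)$. The tether recovery experiments use $n = 50$ atoms, for which
the bias is ~4%, comfortably inside the 10% agreement demanded of the
stochastic tests; at $n = 10$ it would be ~20%. This is why quantitative
B-recovery systems in the tests are never tiny.

## Sampling design of the shipped experiments

The quantitative recovery experiments (also recomputed by
`scripts/acceptance.R`) use $N = 20$ replicates — the replicate count of
the protocol this package emulates — at 1 fs timestep:

* tether system: 50 atoms, $k = 1$, $T$ chosen so $k_BT/k = 0.1$ Å$^2$
  per axis, $\gamma = 0.01$ fs$^{-1}$, $10^6$ steps saving every $10^3$
  (1000 frames/replicate). With the oscillation period ~1.1 ps and
  positional decorrelation time $\approx 2/\gamma = 200$ fs, frames 1 ps
  apart are effectively independent.
* elastic network: the 30-node grid above at 50 K,
  $\gamma = 0.005$ fs$^{-1}$, $10^6$ steps saving every 500
  (2000 frames/replicate).

These sizes were fixed from the decorrelation analysis above, as the
smallest ensembles that leave Monte-Carlo error well below the biases
being measured. Windowed analyses (e.g. 25/50/100 ps) truncate saved
frames; they never re-run dynamics.

The SE-scaling experiment draws per-replicate profiles from a fixed
per-atom Gamma distribution (shape 16, i.e. ~25% per-replicate scatter)
over 200 atoms rather than running MD: the $1/\sqrt N$ law being checked
is a property of the aggregation stage alone.

## What the synthetic data does and does not show

The toy systems are vacuum harmonic models: no solvent, no periodic
boundaries, no electrostatics, no SHAKE, no pressure coupling, and no
force-field anharmonicity. Passing tests therefore demonstrate that the
*pipeline* — superposition, fluctuation statistics, ensemble aggregation,
mass-scaling bookkeeping, I/O — is correct, and that the engine samples
the distributions it claims to sample. They say nothing about whether any
particular force field reproduces experimental protein B-factors; that
question needs the full solvated simulations this package deliberately
does not attempt. Multi-start mode (one distinct starting conformation
per replicate) is supported and tested on synthetic data in the same
spirit: it demonstrates the *capability*, in which wider starting
heterogeneity inflates the ensemble SE without systematically moving the
mean for a harmonic system.

## Numerical and design notes

* Kabsch fits reject fewer than 3 atoms or collinear selections; the SVD
  determinant correction forbids reflections (mirror pairs fit with a
  proper rotation and nonzero residual). Fits are unweighted — mass
  weighting is not part of the emulated procedure.
* Each trajectory is fitted separately (the step-1 reference is *its own*
  first frame); a pooled mode exists because the per-trajectory choice,
  while the natural reading of "averaged over 20 simulations afterwards",
  is not the only possible one.
* PDB I/O keeps altloc blank/'A' records and drops others; HETATM records
  are excluded from selections unless requested; residue numbering,
  chain breaks and insertion codes pass through verbatim. Round-trips are
  exact at format precision (10$^{-3}$ Å, 10$^{-2}$ Å$^2$).
* The PDB B column stores two decimals, so comparisons against a
  reference PDB inherit that quantisation.
* The Berendsen mean kinetic temperature is verified to 2% only after
  10 coupling times and over runs long enough that the slow KE/PE
  exchange of harmonic systems averages out.
* Ensemble aggregation refuses $N=1$; zero-variance (single-frame)
  fluctuations are an error rather than $B = 0$.
* The exact SE formula used (sample SD with $N-1$, divided by
  $\sqrt N$) is recorded in the profile metadata, since "standard error"
  conventions vary.

## A worked example

```{r example, eval = FALSE}
sys <- harmonic_tether_system(matrix(runif(150, 0, 30), 50, 3), k = 1)
cfg <- sim_config(timestep = 1, n_steps = 1e5, save_interval_steps = 1000,
                  ensemble = langevin(50.32, gamma = 0.01))
ens <- run_ensemble(sys, cfg, seeds = 1:20)
prof <- ensemble_bfactors(ens, "CA")
print(prof)
enm_analytic_bfactors(sys, 50.32)[1]   # 7.896 A^2 closed form
```

## Known limitations

* Harmonic toy physics only; no claim transfers to real force fields.
* The analytic ENM oracle degrades for floppy networks and large
  fluctuation amplitudes (see above) — by construction, not by bug.
* Uniform mass scaling only; per-region (guest/host) scaling is not
  implemented.
* mmCIF, compressed trajectory formats and anisotropic displacement
  parameters are out of scope.
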