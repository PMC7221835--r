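---
title: "Ranking ligand entry and egress pathways with steered and supervised dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking ligand entry and egress pathways with steered and supervised dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Lipid-like agonists of membrane receptors — cannabinoid, sphingosine-1-phosphate
and lysophosphatidic-acid receptors are the canonical examples — have binding
pockets buried in the transmembrane helix bundle, and an N-terminal
extracellular domain that occludes the vertical approach.  The working
hypothesis for this receptor family is that such ligands reach the orthosteric
site laterally, through a crevice between two transmembrane helices, rather
than from the extracellular solvent.  Two simulation protocols probe this:

* **Steered pulling (SMD).**  A virtual spring, whose anchor moves at constant
  velocity along a candidate exit direction, drags the bound ligand out while
  the restraint force is recorded.  Integrating force against the ligand's own
  displacement gives the pulling work for that direction; the direction with
  the smallest mean work (and, among statistically equivalent candidates, the
  smallest maximal force) is the most plausible pathway.
* **Supervised dynamics (SuMD).**  Unbiased dynamics run in short slices under
  a tabu-like supervision rule: a slice is kept only if the ligand–site
  distance improves, otherwise the slice is re-run from its checkpoint with
  fresh velocities and a previously unused seed.  Because no force is ever
  added, accepted segments are ordinary trajectories; supervision only
  rectifies the diffusive search, making entrance events observable at
  desk-scale budgets.

`egressr` implements both protocols, the analyses that consume them (work
integration, pathway ranking, interaction-energy decomposition,
centre-of-mass pose distances), and a synthetic receptor on which the whole
chain can be validated against a known ground truth.

## The synthetic receptor

Real crystal structures, all-atom force fields and hundreds of nanoseconds of
sampling are out of scope at desk scale, so the package ships a coarse-grained
stand-in with the same topology of the problem:

* **Helix ring.**  `receptor_layout()` arranges 7 vertical pillars of
  overlapping Lennard-Jones beads (σ 4.6 Å, ε 0.30 kcal/mol, 2.2 Å vertical
  spacing) on a ring.  Adjacent pillars are separated by *gates* whose
  surface-to-surface arc widths are configurable (default 2.5 Å — too narrow
  for the ligand to slip through cheaply).  Because ring radius and gap widths
  are geometrically coupled, the radius is derived from the gaps; if a radius
  is supplied explicitly the gaps are rescaled proportionally.
* **The engineered crevice.**  `widen_gate(layout, "TM1-TM7", 1.5)` widens one
  gate and flags it.  With the defaults this drops that gate's static barrier
  from ≈13 kcal/mol to ≈3 kcal/mol, a deliberately unambiguous ground truth.
* **Membrane and plug.**  Two planar bead sheets close the membrane slab
  around the ring, and an optional disc of beads above the pocket (`up_plug`,
  on by default) mimics the N-terminal domain blocking the vertical exit.
* **Ligand.**  `ligand_spec()` builds a 3-bead chain: one charged head bead
  (−1 e, the phosphate-like group) and hydrophobic tail beads with a deeper LJ
  well — the minimal abstraction of a lipid agonist with polar head and
  greasy tail.
* **Scaffold restraints.**  Every non-ligand bead is tethered to its build
  position by a harmonic restraint (10 kcal/mol/Å²).  The scaffold is mobile —
  pillars can be pushed apart at a cost — but holds its architecture.

`ground_truth_barriers()` is the package's oracle: it rigidly translates the
ligand outward along each exit line, recording the maximum ligand–scaffold
interaction energy in excess of the bound pose.  Passing the pathway-ranking
tests therefore demonstrates that the *dynamical* protocol recovers a *static*
truth it never sees.

What the toy model does **not** emulate: atomic chemistry, explicit lipids and
water, ligand flexibility beyond three beads, receptor conformational change,
and entropic/solvation contributions.  A green test suite shows the machinery
is correct and self-consistent, not that any particular real receptor gates
its ligand between two specific helices.

## Units and the dynamics engine

Internal units are Å, ps, amu, kcal/mol and elementary charge; forces are
reported both in kcal/mol/Å and in pN (1 kcal/mol/Å = 69.479 pN), pulling
speeds are stated in m/s (1 m/s = 0.01 Å/ps, exact).  The Coulomb constant is
pinned at 332.0636 kcal·Å/(mol·e²) so energy tests are exact.

`compute_forces()`/`step_langevin()` implement CHARMM-style pairwise terms
(12-6 LJ with Lorentz–Berthelot mixing, Coulomb) under a 10–12 Å switching
cutoff without periodic boundaries (the system is finite), harmonic bonds
(`0.5·k(r−r0)²`) and the scaffold tethers, propagated by the BAOAB Langevin
splitting with dt = 0.01 ps, T = 300 K and friction 5 ps⁻¹ by default.  Two
deliberate choices:

* **Scaffold pair exclusion.**  Nonbonded pairs in which *both* particles are
  restrained scaffold beads are skipped: the scaffold's geometry is maintained
  by its tethers, and only ligand-involving interactions matter for egress.
  This is what makes a 15-minute pulling campaign possible on one CPU.  An
  `all_pairs` mode restores the full sum; the interaction-energy analyses use
  explicit group pairs and are unaffected.
* **Exact deterministic limits.**  At T = 0 and friction 0 the integrator is
  velocity Verlet, and no random numbers are consumed — the NVE drift,
  momentum-conservation and replay tests all build on this.

Blow-ups (non-finite or > 10⁸ kcal/mol energies) abort with a diagnostic
suggesting a smaller dt.  Checkpoints snapshot positions, velocities, time and
the random-stream label; on disk they are tagged, versioned RDS files, and the
round trip is bit-exact.

## The pulling protocol and its scaling

Published pulling protocols for these receptors use a 70 pN/Å spring pulled
at 0.3 m/s for 15 ns — 45 Å of anchor travel across a full receptor.  The toy receptor is ≈20 Å from
pocket to solvent, and at 0.3 m/s a toy-appropriate 2 ns run would move the
anchor only 6 Å, which can never produce an egress event.  The package
therefore keeps the spring stiffness and scales the kinematics once:
`pull_schedule()` defaults to **70 pN/Å, 3 m/s, 750 ps** (22.5 Å of travel).
The slower original values remain available through the same arguments.

Per direction, the spring attaches to the centre of mass of the
`n_pull_atoms` ligand beads with the largest projection onto the pulling
direction (ties broken by bead index); the default is a single bead.
Direction vectors are the outward bisectors of the flagged helix pairs plus
`UP` (+z) — the underlying protocol names directions only by helix pairs, so
the bisector is a modelling choice of this package.  The anchor position
advances as exactly `a(t) = a(0) + v·t·u`, and the recorded spring force is
exactly `k(a − COM)` as a full 3-vector; both identities are asserted to
round-off in the tests.

**Work** is the componentwise trapezoidal sum of force against the *pulled-COM*
displacement (not the anchor displacement, which would count spring stretch
as distance).  Replicates (3 by default — a single pull is not evidence) are
aggregated as mean ± sample SD; a lone repeat reports SD 0 with a degeneracy
flag.  **Ranking** sorts by ascending mean work; two pathways whose means lie
within the larger of their SDs are treated as statistically equivalent and
ordered by ascending mean maximal force, then label.  The verdict names the
winner and whether the runner-up is equivalent.

## The supervision rule

Published supervision schemes differ in their details, so the
rule here is stated explicitly and exposed as configuration
(`sumd_config()`): dynamics run in slices of `slice_length` steps (default
500 = 5 ps); a slice is accepted iff the ligand–site COM distance at its end
satisfies `d_end < d_start − ε` (ε default 0.1 Å) **or** beats the best
distance seen so far; otherwise the checkpoint is restored, velocities are
resampled from the Maxwell–Boltzmann distribution with the next seed of the
run (`seed_base + attempt`), and the slice is retried — never reusing a seed,
which is the tabu property.  Distance is evaluated at slice ends because
restarts happen after a slice, and termination is one of `arrived`
(≤ `arrival_radius`, default 4 Å), `reject_cap` (default 30 consecutive
rejects) or `step_budget`.

For entrance experiments `funnel_layout()` widens the target gate 2× and adds
a +0.1 e attractor bead at the pocket centre.  The attraction is deliberately
weak (≈2 kcal/mol at 8 Å against the −1 e head): transport stays
diffusion-dominated, which is the regime supervision is designed for, and the
paired-seed comparison in the tests shows supervised first passage beating
plain dynamics run in the identical slice harness.

## Interaction energetics and pose distances

`interaction_energy()` sums Coulomb and LJ terms across two disjoint groups
only (no bonded or restraint contributions — ligand and receptor share no
bonds), with the engine's cutoff by default and an exact mode for tests;
`energy_profile()` evaluates it per trajectory frame and stores
`E_total = E_elec + E_vdw` computed in that order, so the decomposition
identity holds exactly, not merely to tolerance.  Display smoothing
(`smooth_profile()`, default 50-sample running mean) never touches the stored
values; the averaging behind published energy-profile figures is unstated, so
the window is exposed rather than fixed.

Pose similarity between a simulated final pose and reference (crystal) poses
uses the distance between mass-weighted centres of mass, not RMSD — simulated
and reference ligands need not share an atom mapping.  No superposition is
performed; poses must already share a frame, as crystal structures of one
receptor do.  Per-ligand means are rounded half-away-from-zero at one decimal,
the convention of the reference table shipped in
`inst/extdata/table1_pose_distances.csv` (means 3.4, 3.1, 3.5 and 8.0 Å for
THC, AEA, LPA and S1P).

## Numerical choices and problem sizes

* dt = 0.01 ps against the stiffest default mode (ligand bonds,
  ω ≈ 25 ps⁻¹) leaves ≈25 steps per period; the NVE check uses dt = 0.002 ps.
* Ligand placement resolves steric clashes by up to 100 seeded jitter
  attempts (≤2 Å), then fails naming the offending pair — bounded and
  reproducible.
* The default validation campaign — 10 batches × 5 directions × 3 repeats of
  750 ps pulls on a ≈140-bead system, plus 20 paired entrance runs capped at
  60 000 steps — was sized to give clear statistics (the engineered gate wins
  every batch with the default geometry) while completing in a few minutes on
  one CPU; these sizes are package choices, not physical claims.
* Degenerate inputs fail loudly: single-sample force records, non-monotone
  times, overlapping energy groups, zero total mass, unknown ligands or gates,
  corrupted checkpoints.

## Known limitations

Work from a single pull overestimates reversible work (no Jarzynski/Crooks
estimator is attempted — mean ± SD is the only statistic); the statistical
equivalence rule is an SD-overlap heuristic, not a test with a stated error
rate; the supervision rule is this package's concrete reading of
"restart if the distance increases too much", not a reimplementation of any
specific published variant; and the COM pose distance says nothing about
ligand orientation in the pocket.
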