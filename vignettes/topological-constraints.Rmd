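---
title: "Topological constraints on RNA 3D structure: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological constraints on RNA 3D structure: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toprna)
```

## The question the model isolates

An RNA secondary structure already fixes a great deal of 3D behavior before
any tertiary interaction forms: helices are bulky semirigid bodies, and the
single strands that connect them have finite length. Together these
*topological constraints* — excluded volume plus connectivity — restrict how
the helices of a junction can be arranged, independently of sequence,
electrostatics, or attractive tertiary chemistry.

`toprna` implements a coarse-grained molecular dynamics model built to
isolate exactly this contribution, and the analysis stack used to quantify
it on tRNA: interhelical Euler-angle coverage, mutual information between
helix orientations, contact free energies, folding cooperativity, and the
native specificity of the most compact conformers.

## The model

Each nucleotide is three beads at the base (B), sugar (S) and phosphate (P)
moiety positions. Base pairs from the input secondary structure are
permanently bonded and a fourth bead (M) fills the steric gap between the
two B beads of each pair. Contiguously paired regions are parameterized to
stay A-form; single-stranded residues keep only local bond and angle terms
and carry **no dihedrals**, so they rotate freely. The only nonbonded force
is a 6–12 Lennard-Jones term with `eps = 0.01` kcal/mol — sterics,
effectively — except that the B beads of paired residues (and the M beads)
attract each other with `eps_stack = 0.5` kcal/mol, which maintains
intra-helix stacking and makes interhelical coaxial stacking across a
junction only marginally favorable. There are no electrostatics and no
sequence-dependent tertiary energetics: the sampled ensemble is the set of
conformations a secondary structure can reach, weighted only by sterics and
connectivity.

### Where the numbers come from

Published parameter tables for this class of model were not available to
this implementation, so the geometry is self-consistent by construction:

* An idealized A-form placement (32.7° twist and 2.81 Å rise per pair;
  fixed cylindrical radius/phase per bead type, `aform_geometry()`) defines
  every equilibrium bond length, angle, improper and helical dihedral —
  they are *measured* from the ideal build in `toprna_params()`, so an
  ideal helix has exactly zero bonded energy.
* LJ radii approximate the minimum dimension of each moiety: P 2.7 Å,
  S 2.9 Å, B 1.7 Å (half the 3.4 Å base-stacking thickness, so stacked
  neighbors sit at their LJ minimum), M 1.5 Å.
* The P bead is placed radially outside the S–S line (backbone angles of
  ~121° and ~150°). This matters numerically: torsion angles through
  near-collinear backbone triples are ill-conditioned, and keeping the
  equilibrium geometry far from collinearity keeps the dihedral forces
  well-behaved.

### Keeping helices rigid at a 20 fs timestep

The protocol integrates with a 20 fs timestep (BAOAB Langevin, friction
5 ps⁻¹). A timestep this long caps how stiff any local term may be: the
stiffest normal mode must satisfy \(\omega\,\Delta t \lesssim 1.5\).
Making individual bonds and angles stiff enough to hold a helix at < 1 Å
RMSD violates that bound, so rigidity is instead supplied *collectively* by
an intra-helix elastic network between consecutively stacked pairs:
same-strand B/S/P stacking springs, M–M springs along the pair centers
(first and second neighbors, which give bending stiffness), the two B-bead
cross diagonals, and anchors tying each paired backbone to its pair center.
These springs connect heavy effective masses over several Å, so they are
low-frequency and can be stiff (`k_stack = 80` kcal/mol/Å²) while local
bonds stay soft (`k_bond = 12`). Bead masses are the moiety group masses
scaled by 3; equilibrium observables are mass-independent, and the scaling
keeps the fastest modes comfortably inside the integrator's stability
region. With these (tuned once, then frozen) constants a free 10-bp duplex
at 300 K stays at ~1.0 Å all-bead RMSD (~0.7 Å over its interior) from the
ideal build.

Two further numerical choices:

* **Dihedral force capping.** The gradient of any torsion angle diverges
  when three of its four beads become collinear, which soft single strands
  do visit. Each dihedral/improper term's force is capped at 50 kcal/mol/Å
  with a uniform scale on the four beads (net force and torque stay zero).
  The cap only engages in the ill-conditioned region; force/energy
  consistency away from it is verified to 1e-5 by finite differences.
* **Kinetic temperature.** BAOAB full-step velocities underestimate kinetic
  temperature by \((\omega\Delta t)^2/4\) per mode (~3% here). Kinetic
  temperatures are therefore measured at the post-thermostat (post-O) point
  of the cycle, where the velocity marginal is exact; the reported replica
  temperatures match the ladder to within a fraction of a percent.

## Sampling protocol

`simulation_protocol()` defaults mirror the study conditions: eight
replicas exponentially spaced 300–450 K, exchange attempts every 2000 steps
between alternating neighbor pairs (Metropolis on potential energy;
velocities rescaled by \(\sqrt{T_{new}/T_{old}}\) on acceptance), snapshots
of the 300 K replica every 2000 steps, and the leading tenth of the run
(capped at 2×10⁶ steps, the full-scale equilibration) discarded. Exchange
acceptance on the wild-type tRNA runs here is 35–50%, in the healthy range.
Runs are exactly reproducible for a fixed seed: per-segment RNG streams are
derived deterministically from `(seed, segment, replica)`.

Full-scale published ensembles use 10⁹ steps per replica; everything in
this package is exercised at desk scale (10⁵–2×10⁶ steps per replica).
Orientation-space *coverage* is monotone non-decreasing in the number of
snapshots and converges from below, so scaled-down runs give strict lower
bounds on converged coverage — the package's acceptance script
(`scripts/acceptance.R`, 10⁶ steps per replica) relies on exactly this
monotonicity. The same applies to the 9D/3D coverage ratio under
undersampling.

## Analyses

* **Euler angles.** A helix frame has z along the mean step-rotation axis
  of consecutive base-pair steps (exact on an ideal helix, noise-damped by
  averaging; principal components of the pair centers are *not* used
  because those centers lie on a 1.95 Å-radius helix and bias the axis),
  oriented 5'→3' along the first strand, with x set by the first pair's
  S-bead midpoint. Orientation between two helices is the z-y-z Euler
  triple \((\alpha_h, \beta_h, \gamma_h)\); at the gimbal degeneracies the
  twist sum is folded into \(\alpha_h\). Absolute angle values depend on
  this frame convention; coverage fractions and mutual information do not.
* **Coverage.** Triples are binned on an equal-width grid (10° → 36×18×36
  bins; 60° → 108 bins, the normalization used for joint coverage, with
  9D denominator 108³). `coverage_9d()` also reports
  \(r_{9D/(3\times3D)}\), the ratio of the 9D fraction to the product of
  the three pairwise fractions; 1 under independence, below 1 when helix
  orientations are coupled (or undersampled).
* **Mutual information** between two helices' orientation triples relative
  to a common reference helix, 45° histograms, in bits, minus the
  first-order finite-sample bias \((B_{XY}-B_X-B_Y+1)/(2N\ln 2)\), floored
  at 0 and clamped at the marginal entropies. The correction is a
  small-bias formula: it is accurate when the joint histogram is populated
  (the default analyses keep the populated-bin to sample ratio in the
  regime where it holds), not in deep undersampling. Short trajectories add
  a second failure mode: slow conformational drift makes the two
  orientation streams co-vary in the finite sample, inflating apparent MI
  in proportion to mobility — a short run of a *more* mobile variant can
  therefore show *higher* bias-corrected MI even when its converged
  orientation coupling is weaker, and the directional MI comparison in the
  acceptance suite documents exactly this regime. For such data
  `mutual_information(..., correct = "shift")` subtracts a circular
  time-shift surrogate null, which preserves each stream's autocorrelation
  while breaking their synchrony; the suite validates it on synthetic
  drifting streams with zero true MI.
* **Contacts.** Residues are in contact below 14 Å S–S distance with ≥ 5 nt
  sequence separation; loops contact when any residue pair does; coaxial
  stacking between the tracked stem pairs (D/AC, T/A, and V/AC when a
  V-stem exists) uses the three-criteria geometric test (closing-pair plane
  normals, B-bead center distance with 9/14 Å direct/1-nt thresholds, and
  normal-to-center-line angles < 60°). Contact probabilities convert to
  \(\Delta G^{topo} = -k_BT \ln(P/(1-P))\); unobserved contacts report the
  finite-sample bound \(\ln n\) and are flagged. Cooperativity is
  \(C = P(c_1..c_n)/\prod P(c_i)\), and restrained-versus-unrestrained
  coupling \(\Delta\Delta G_{coop}\) refuses loop pairs that carry an
  active restraint between them.
* **Best-packed conformers.** Snapshots are ranked by
  \(E = n_l\epsilon_l + n_s\epsilon_s\) (interloop residue contacts and
  coaxial stacks; defaults −0.6 and −3.5 k\_BT). The subset size defaults
  to `min(500, n/10)` so short runs get proportionally smaller sets.
  Conformer entropies use the smooth 10 Å kernel
  \(S_i = \ln[1 + \sum_j \exp(-rmsd_{ij}^3/10^3)]\) over P beads, with the
  species-variable A/D-, V- and ACCA-loops excluded from the RMSD so values
  compare across secondary-structure variants. Native specificity
  \(\langle N\rangle\) is the entropy-weighted fraction of conformers with
  a D–T loop contact and none of the ten native-inconsistent loop-pair
  contacts.

## Reference structures and restraints

`build_reference_trna()` assembles the cloverleaf's helices into the tRNA
"L" (A-stem stacked on T-stem, D-stem on AC-stem, arms at right angles),
interpolates the single strands, and settles the loops by a deterministic
staged minimization: first with sterics off — chains may pass through one
another, which removes any entanglement of the interpolated loops — then
with radii ramped back to full size, under stiffened and 20%-narrowed
copies of the tertiary-pair windows plus scaffold springs holding the two
coaxial arm junctions. The result satisfies all standard restraint windows
of the six conserved tertiary pairs (U8·A14, G15·C48, G18·U55, G19·C56,
U54·A58, G26·A44), has the D–T loop contact, no native-inconsistent
contacts, and both native stacks; it defines the default native contact
table. The build uses no random numbers, so it is identical from any seed.
U54·A58 deserves a note: it lies inside the 7-nt T-loop at sequence
separation 4, where its B–B and S–S windows pull against chain geometry —
the narrowed construction windows are what buys the margin. Base triples
are user-supplied (`make_restraints("base_triple", ...)` with reference
distances); semiconserved triples have no default table.

Flat-bottom restraints are zero inside `[r_min, r_max]`, harmonic
(k = 2 kcal/mol/Å²) just outside, with force capped at 2 kcal/mol/Å. A
capped 2 kcal/mol/Å wall at 300 K (k\_BT ≈ 0.6 kcal/mol) permits thermal
excursions of a few tenths of an Å beyond the window; restrained-run
monitors report the strict in-window fraction, and the two-bead
restraint test in the suite checks that fraction against the exact 1D
Boltzmann integral rather than against an arbitrary percentage.

## What the synthetic generators do and do not show

`make_synthetic_ensembles()` plants known ground truth: independent
uniform Euler streams (MI = 0; 9D/3D ratio → 1 only once the joint grid
saturates, which the tests exercise on a coarser 90° grid where saturation
is reachable), correlated Bernoulli contact streams with exact marginal
and joint probabilities (planted cooperativity), and Gaussian-jittered
copies of a reference structure. These validate the estimators'
arithmetic. They do not validate the physics: passing them says nothing
about whether the force field samples realistic RNA ensembles. The
physics-side checks are separate — force/finite-difference consistency,
NVE symplecticity, exact Boltzmann laws on analytically solvable systems,
kinetic-temperature equipartition, helix rigidity, and directional
reproductions (junction cutting increases pairwise coverage and decreases
orientation coupling; native contacts cost less than non-native; the
wild type is more native-specific than the cut variant) at matched
snapshot counts and shared seeds.

## Known limitations

* The model is deliberately blind to sequence, electrostatics and specific
  tertiary chemistry; its free energies are topological baselines, not
  total folding energetics.
* Force-field constants are this package's own calibration against the
  stated criteria, not a published table; absolute energetics of the
  stacking attraction in particular are order-of-magnitude choices.
* Desk-scale runs undersample: coverage numbers are lower bounds, MI
  estimates carry finite-sample noise, and best-packed subsets from short
  runs are small. Converged values need cluster-scale step counts.
* Pseudoknots, modified nucleotides and multi-chain assemblies are out of
  scope; one chain, nested pairs, 1-based numbering throughout.
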