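---
title: "Flexible compound alignment and alignment-based docking: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible compound alignment and alignment-based docking: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given a query small molecule and the known 3D structure of a related
reference ligand, we want the conformation and placement of the query that
best reproduces the reference's shape — and, when a receptor structure is
available, that also forms favorable protein–ligand interactions. The first
task is flexible compound-to-compound alignment; the second is
alignment-based docking, the realistic cross-docking setting where a ligand
is docked into a protein solved with a *different* ligand and a rigid
*ab initio* search often fails because of small induced-fit changes.

# The objective

Every pose is scored by a hybrid alignment energy

$$E_\mathrm{align} = S^{-\operatorname{sgn}(E)}\, E$$

where $S \in [0,1]$ is the shape-match score against the reference and $E$
(kcal/mol) is the compound energy: the ligand internal energy for plain
alignment, or the full docking energy (protein–ligand interaction terms plus
internal energy) for docking. For favorable energy ($E<0$) the objective is
$S\,E$ — a good shape match amplifies the reward; for unfavorable energy it
is $E/S$ — a poor match amplifies the penalty. In both regimes improving $S$
strictly lowers the objective, the sign of $E_\mathrm{align}$ always equals
the sign of $E$, and $E = 0$ gives 0. $S$ is floored at $10^{-6}$ before the
negative exponent so the penalty branch stays finite. We note the printed
form of this expression is ambiguous as typeset; the signed-exponent reading
adopted here is the only one consistent with the stated behavior ("large
negative for a good shape match and favorable energy") — an additive reading
would *reward* unfavorable energy at good shape match.

## Shape score

Atoms are spheres at their van der Waals radii (Bondi table, shipped in
`inst/extdata/vdw_radii.tsv`) scaled by `radius_scale = 0.8` to emphasize
core overlap. The score is the sum of per-atom match scores: each heavy atom
contributes the analytic sphere-intersection volume with its best-matching
atom in the other molecule, scaled by `cross_type_factor = 0.7` when the two
atom types differ; the sum is symmetrized over the two molecules and divided
by the larger molecule's total atomic volume.

Two choices here were genuinely open:

* **Best-match vs all-pairs summation.** Summing over *all* atom pairs
  looks natural but saturates: with 0.8-scaled radii, bonded neighbors'
  spheres interpenetrate, the all-pairs numerator exceeds the denominator
  for any dense overlay, and after clamping to 1 the score can no longer
  distinguish a 0.5 Å overlay from a 4 Å one (we observed exactly this).
  The per-atom best-match sum is bounded by the denominator by
  construction, symmetric in the two molecules, and reaches 1 only for a
  perfect same-type overlay, so it discriminates across the whole range.
* **Heavy atoms only** (default): hydrogens rotate freely and add noise,
  and the evaluation metric is heavy-atom RMSD. Configurable.

Atom types default to the element symbol — the simplest typing consistent
with both the shape penalty and the pairing penalty below; a finer typing
can be plugged in through the `atype` field.

## Energy model

The docking energy is a hybrid of AutoDock4-style physics terms:

* 12-6 Lennard-Jones (per-element $R_{min}/2$ and $\varepsilon$ in
  `inst/extdata/nonbonded_params.tsv`),
* 12-10 hydrogen bond ($r_0 = 1.9$ Å, $\varepsilon = 5$ kcal/mol) between
  polar hydrogens (H on N/O) and N/O acceptors, replacing the LJ term for
  those pairs,
* Coulomb with the Mehler–Solmajer distance-dependent dielectric,
* Gaussian-contact desolvation ($\sigma = 3.6$ Å) with atomic solvation
  parameters $S_i = \mathrm{asp}_i + 0.01097\,|q_i|$,

over an 8 Å cutoff, plus a ligand bonded term. Ligand internal terms run
over atom pairs separated by more than three bonds; exactly-three-bond (1–4)
pairs are computed separately and scaled by `w8`. Eleven weights combine the
terms; they are user-overridable. The shipped defaults are unit weights for
the protein–ligand terms with these deliberate exceptions:

* `w4–w7 = 0.5` (ligand internal nonbonded): the internal energy's
  conformer-to-conformer spread must not outvote the shape match in the
  hybrid objective — at unit weight, a partially misaligned pose whose
  conformer packs ~1 kcal/mol better can outrank the exact overlay. The
  value was calibrated by a small grid search on the synthetic
  self-alignment/self-docking benchmarks (0.5 maximizes both recovery
  rates; 0.3 starts to cost docking accuracy).

* `w8 = 0`: without a dedicated 1–4 parameter set, the plain 12-6 at 1–4
  distances (2.5–3.0 Å against $R_{min} \approx 4$ Å) contributes a 20–50
  kcal/mol repulsive baseline that drowns every other term; excluding 1–4
  nonbonded interactions from the internal energy is also the AutoDock4
  convention. The terms are still computed and reported in the breakdown.
* `w9 = w10 = 0`: the knowledge-based hydrophobic-match and pair-potential
  terms are pluggable hooks (`register_energy_hook()`); their published
  parameter tables are not redistributable here, so they default to off.
* The bonded term is a torsional strain potential over the rotatable bonds
  (3-fold, 3 kcal/mol for saturated; 2-fold, 10 kcal/mol for conjugated
  bonds). Bond lengths and angles are frozen by the DOF parameterization,
  so only torsions (and discrete ring states) can change during sampling
  and only they need a bonded penalty.

Partial charges default to six damped Gasteiger PEOE iterations seeded with
the formal charges (parameters in `inst/extdata/gasteiger_params.tsv`);
any external charge set can be supplied through the `charge` field.

For docking, the receptor (cofactors included, rigid) is precomputed on a
cubic grid — 22.5 Å default edge centered on the reference ligand's
geometric center, 0.375 Å spacing, trilinear interpolation — with one LJ and
one hydrogen-bond channel per ligand atom class plus electrostatic and two
desolvation channels. Ligand heavy atoms leaving the box pay a quadratic
wall penalty (10 kcal/mol/Å²), which keeps local minimization well-behaved
for ligands larger than the box; the box is *not* auto-enlarged because a
larger search volume tends to hurt more than the truncation.

# Degrees of freedom and sampling

A conformation is a DOF vector: centroid translation, orientation
quaternion, one dihedral per rotatable bond, and one discrete library index
per flexible ring. Rotatable bonds are non-ring single bonds with at least
two heavy atoms on each side, amide C–N excluded (the common convention; the
torsion tree roots at the largest rigid fragment). Realization applies ring
templates, then dihedrals down the tree, then the rigid transform; bond
lengths and angles are conserved exactly.

Ring conformers come from a programmatic library: per ring topology
(size + element + hybridization sequence), 200 randomly puckered embeddings
of an ideal polygon are relaxed under a small cyclic force field (harmonic
bonds/angles, periodic torsions), deduplicated, clustered by complete
linkage at the size-dependent cutoff $0.3\sqrt{(n-1)/6}$ Å, and the cluster
medoids stored with strain energies relative to the best (for cyclohexane
this recovers the chair as reference and the twist-boat family above it).
Pairs of stored templates always respect the cutoff — medoids that violate
it after linkage cutting are pruned keeping the lower-energy one. States are
sampled with Boltzmann probability at RT = 0.593 kcal/mol (300 K). When a
template replaces a ring's geometry it is fitted in the label-preserving
cycle mapping closest to the current geometry (otherwise a chair applied at
a rotated phase would swap axial and equatorial substituents), and each
exocyclic substituent moves rigidly with its anchor atom's local frame.
Building from crystallographic ring statistics is out of scope here — the
generator is a stand-in with the same interface, so absolute conformer
populations should not be over-interpreted. Fused and macrocyclic ring
systems are kept rigid at their input geometry: a programmatic conformer
generator for fused systems would dominate the codebase for marginal
benefit at this scale, and large fused/macrocyclic rings are a known
limitation of library-based ring sampling anyway.

# Global optimization (CSA)

Conformational space annealing keeps a bank of 30 conformations.
The initial bank: 30 torsion-randomized, ring-resampled conformers, each
relaxed on the plain energy; five rigid placements per conformer from the
triad overlay (below) give 150 posed conformations; K-means in heavy-atom
coordinate space reduces them to 30 (best-scoring member per cluster), each
locally minimized on the alignment energy. Iterations then generate 20
trials (mutation — torsion perturbation within ±60°, ring resampling with
probability 0.3, small rigid jitter — or crossover with a donor from the
current or initial bank, swapping the rigid-body block or a torsion
subtree), minimize them, and apply the replacement rule: a trial within
d-cut of its nearest bank member replaces it if better; a trial farther than
d-cut from everyone replaces the worst member if better. Distance is
symmetry-aware heavy-atom RMSD in the common reference frame. d-cut anneals
geometrically from $D_{avg}/2$ to $D_{avg}/5$ ($D_{avg}$ = mean pairwise
RMSD of the initial bank), reaching the floor at half the budget — the
standard schedule in the CSA lineage, since no schedule is published for
this application. Default budget: 50 iterations, early stop after 10
improvement-free iterations, then one deeper minimization of every member
before final ranking. Local minimization is Nelder–Mead over the continuous
DOFs (ring states frozen), capped at 200 evaluations, and never returns a
worse member than it received. A single RNG stream seeded from the
configuration drives every stochastic choice, so runs are bit-reproducible.

The rigid placement stage pairs each query heavy atom with the reference
atom whose radial environment is most similar (cosine similarity of 6-bin
neighbor-count histograms within 6 Å, times 0.7 across different types),
enumerates atom triads from the 10 best pairs (triangle filter: mapped
side-length differences below 1 Å), superposes each candidate triad by
Kabsch (proper rotations only), ranks transforms by the total squared
distance over all mapped pairs, and returns the 5 best after deduplication
at 0.25 Å induced RMSD. Enumerating *all* triads is combinatorially
explosive; anchoring them in the highest-similarity pairs preserves the
intent at tractable cost, and both knobs are in the configuration.

# Evaluation metric

Pose accuracy is the minimum heavy-atom RMSD over graph automorphisms of
the heavy-atom molecular graph (element- and bond-order-preserving, Kekulé
patterns normalized to one aromatic label), computed in a common frame with
no re-superposition — so benzene's six-fold symmetry or a flipped phenyl
never inflates the deviation. Automorphisms are enumerated with VF2 and
capped at 10,000; past the cap the identity mapping is used with a warning
(the metric is for evaluation, not scoring, and such symmetry is rare in
drug-like molecules).

# What the synthetic benchmarks do and do not show

The fixture generator builds heavy-atom "drug-like" molecules (decorated
5/6-rings, 7–20 heavy atoms, up to ~9 rotatable torsions, C/N/O
composition), relaxed into staggered clash-free conformers — mirroring the
usual preprocessing in which input ligand structures are energy-minimized.
Pockets are abstract shells of typed, charged receptor atoms placed ~4 Å
from the ligand's crystal pose, guaranteed clash-free and verified
attractive. Scenarios: *self-alignment* (realign a torsion-randomized,
rigidly displaced copy onto its own crystal pose), *cross-alignment*
(shared scaffold, one substituent changed), *self-dock* (recover the
crystal placement in its own pocket).

These exercise every stage — perception, scoring, ring sampling, CSA,
grids — under fully controlled conditions, and the acceptance suite checks
recovery rates on them (20 alignment and 10 docking scenarios; the suite
and `scripts/acceptance.R` state the exact counts). They do **not**
demonstrate performance on real crystallographic data: real ligands have
hydrogens, charged groups, conjugation patterns and ring systems the
generator does not produce, and real pockets are not spherical shells.
Cross-docking against experimental complexes needs curated benchmark sets
outside this package's scope.

# Numerical choices

* Sphere overlaps use the exact lens formula with containment and disjoint
  branches; continuity at the touching distance is tested.
* Nonbonded distances are clamped at 0.75 Å so $r^{-12}$ stays finite
  during minimization; grid nodes use the same clamp, so grid and direct
  sums agree to interpolation error (~2 % at 0.375 Å spacing).
* Ties everywhere break toward the lower atom index; K-means degenerates
  gracefully (duplicate padding with a warning) when a rigid molecule
  yields fewer than 30 distinct poses.
* The superposition solver enforces det(R) = +1 via the SVD sign
  correction and flags collinear triads as degenerate.
* Quaternions are normalized on construction; torsions wrap to (−π, π].

# Problem sizes

The shipped tests and the acceptance script run entirely on generated
fixtures: 20 self-alignment and 10 self-docking scenarios at the default
CSA budget, 100-iteration annealing traces on small chains, $10^7$-sample
Monte-Carlo sphere-overlap checks, and ring libraries for 5/6-membered
carbocycles. These sizes were chosen so a full run completes on a single
CPU in well under an hour while still probing every stage at the fidelity
the contracts require.

# Known limitations

* Element-level atom typing: no hybridization-aware shape or H-bond
  directionality terms.
* The knowledge-based interaction terms are hooks, not implementations.
* Fused/macrocyclic ring systems are rigid; nitrogen inversion and
  amide/ester cis–trans flips are not sampled.
* Protonation states, tautomers and stereochemistry are taken as given.
* Receptor flexibility and explicit waters are out of scope.
* Top-1 selection is the weakest link on the synthetic benchmarks: the
  best pose in the final bank sits around 0.4–0.55 Å from the crystal on
  average, while the top-ranked one averages just above 1 Å, because with
  heavy-atom-only molecules the internal energy's spread between conformers
  is large relative to its magnitude and occasionally outvotes a perfect
  shape match. An all-atom, empirically trained energy (out of scope here)
  is the known remedy.
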