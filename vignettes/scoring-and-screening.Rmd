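---
title: "A desolvation-corrected empirical scoring function and the two-track selectivity screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desolvation-corrected empirical scoring function and the two-track selectivity screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`selectiscreen` scores a protein–ligand pose with an empirical binding
free energy in aqueous solution,

$$
\Delta G_b^{aq} =
W_{vdW}\sum_i\sum_j\left(\frac{A_{ij}}{r_{ij}^{12}}-\frac{B_{ij}}{r_{ij}^{6}}\right)
+ W_{hbond}\sum_i\sum_j E(t)\left(\frac{C_{ij}}{r_{ij}^{12}}-\frac{D_{ij}}{r_{ij}^{10}}\right)
+ W_{elec}\sum_i\sum_j \frac{q_i q_j}{\varepsilon(r_{ij})\,r_{ij}}
+ W_{tor} N_{tor}
+ \sum_i S_i\left(O_i^{max}-\sum_{j\neq i} V_j e^{-r_{ij}^2/2\sigma^2}\right),
$$

where the pair sums run over receptor–ligand atom pairs within a 12 Å
cutoff and the last sum runs over ligand atoms only.  The first four
terms are the gas-phase interaction energy: a 12-6 van der Waals term
with AMBER-style pair coefficients, a 12-10 hydrogen-bond term weighted
by an angular factor $E(t)$, a Coulomb term screened by a
distance-dependent sigmoidal dielectric, and a torsional entropy penalty
proportional to the rotatable-bond count.  The final term is the
negative of the ligand hydration free energy in a solvent-contact
picture: each atom type carries a hydration energy density $S_i$
(kcal mol⁻¹ Å⁻³), an atomic volume $V_i$ (Å³) and a maximum occupancy
$O_i^{max}$ (Å³); the Gaussian envelope (width $\sigma$) measures how
much of atom $i$'s hydration shell is crowded out by the rest of the
solute.  A polar atom ($S_i > 0$) that stays solvent-exposed in the
bound state pays a dehydration penalty; buried apolar atoms contribute
a small favourable term.  This term is a property of the ligand
conformation alone — receptor coordinates never enter it — and the
residual exposure is clamped at zero so crowded atoms cannot contribute
negative exposure.

### Model assumptions

* The receptor is rigid; ligand flexibility is rigid-body motion plus
  free torsions about acyclic single bonds.
* Hydrogen bonds require a donor hydrogen (`HD` type: H on N/O/S) and
  an acceptor heavy atom; the angular weight is $\cos^2 t$ of the
  deviation from linear D–H···A geometry, zero beyond 90°.  The 12-10
  well replaces the 12-6 interaction for those pairs.
* Electrostatic screening follows the sigmoidal dielectric
  $\varepsilon(r) = A + B/(1 + k\,e^{-\lambda B r})$ with
  $A=-8.5525$, $B=86.9525$, $k=7.7839$, $\lambda=0.003627$, rising from
  ≈1.35 at contact to the bulk-water 78.4.
* Covalent binding is outside the model: the scientific setting is
  precisely inhibitors that must work without the covalent anchor lost
  to the C797S mutation.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `w_vdw`, `w_hbond`, `w_elec`, `w_tor` | 0.1485, 0.0656, 0.1146, 0.3113 | – | term weights (classic empirical docking calibration; refit weights can be supplied by config) |
| `sigma` | 3.5 | Å | Gaussian width of the hydration-shell envelope |
| `nb_cutoff` | 12 | Å | nonbonded pair cutoff, no smoothing |
| `r_clamp` | 0.5 | Å | inner wall: distances below this evaluate at the clamp, keeping clashed poses finite |
| `hbond_angle_cutoff` | 90 | deg | angular cutoff of $E(t)$ |
| S/V/O^max table | shipped | see above | solvent-contact parameters per atom type |

All of these are externalized: term weights and constants in a YAML
config (`read_energy_config()`), pair potentials and hydration
parameters as TSV tables (`write_pair_potentials()` /
`read_pair_potentials()` and the hydration analogues).  The shipped
hydration table is an internally consistent illustrative set — polar
types carry positive energy densities, carbon slightly negative — not a
fitted one; fitted values drop in through the same TSV contract.

## Grid maps and the pose search

Docking uses precomputed grid maps: for every probe atom type, the
weighted 12-6 sum over receptor atoms at each node, a separate 12-10
map for hydrogen-bond-capable probes, and a screened electrostatic
potential per unit charge.  Poses are scored by trilinear
interpolation; points outside the box receive a +10⁴ kcal/mol penalty
that pushes searches back inside.  Map values are clamped at 10⁵ so
nodes inside an atom stay finite.

The hydrogen-bond maps store the orientation-independent upper bound
$E(t)=1$, because a probe-type map cannot know where a ligand's donor
hydrogens point.  Two consequences drive the pipeline design:

* grid minima can be *optimistic* near acceptor sites, so final poses
  are always rescored with the exact function (`rescore_direct()`),
  which applies true angular directionality; and
* the steep 12-10 wells (equilibrium ≈1.9 Å) are poorly represented at
  practical node spacings, so `dock_ligand()` refines the best few
  grid candidates against the exact function — a stochastic descent
  with shrinking moves, a restarted Nelder–Mead simplex polish of the
  pose parameters, and a short low-temperature Metropolis finisher
  that can step across shallow neighbouring minima.

The search itself (`optimize_pose()`) is multi-start Metropolis
annealing over the pose genome (translation, orientation quaternion,
one dihedral per rotatable bond) with geometric cooling and a greedy
terminal descent.  It is deliberately not a genetic algorithm: the
scientific content of the package is the scoring function, and a
simple, fully seeded optimizer is easier to reason about and to make
reproducible — identical inputs and seed give identical poses, and
each molecule of a batch draws from its own seed stream.

Default spacings are 0.375 Å for pocket boxes and 1.0 Å for
whole-domain boxes used in peripheral-site scans
(`whole_domain_box()`, `peripheral_site_scan()`), which report cluster
representatives of poses with negative total energy over a start
lattice covering the entire receptor.

## The two-track screen

The screening funnel mirrors dual-target selectivity screening against
a drug-resistant kinase mutant and its wild type:

1. **Molecular-weight window** 300–400 amu, bounds inclusive (the
   source phrasing "ranging from 300 and 400" is ambiguous; inclusive
   is documented here as the package's reading).
2. **Rule of five**: MW ≤ 500, logP ≤ 5, donors ≤ 5, acceptors ≤ 10;
   compliant means at most one violation (the original oral-drug
   heuristic).  Donors are N/O bearing hydrogens, acceptors the N+O
   count; logP comes from Open Babel's atom-contribution model.
3. **Redundancy removal**: greedy leader clustering in input order on
   2048-bit hashed path fingerprints; an entry joins the first
   representative with Tanimoto similarity strictly above 0.8.
4. **Two-track docking**: each representative is docked and exactly
   rescored against both receptors.  A candidate passes when
   ΔG(mutant) < −10.0 and ΔG(wild type) > −6.0 kcal/mol, both strict —
   which forces a selectivity gap above 4 kcal/mol — and when it forms
   at least two hinge hydrogen bonds.
5. **Hinge filter**: complementary donor–acceptor contacts between
   ligand N/O atoms and hinge (residues 791–795) backbone amide N or
   carbonyl O, heavy-atom distance strictly below 3.5 Å.  A ligand N/O
   counts as donor when it bears a hydrogen, as acceptor otherwise; no
   angle criterion is applied, matching the stated distance-only rule.

Thresholds are applied to the direct rescored totals, not grid scores.
Per-molecule failures are logged in the output record and never abort
a batch.

## De novo design

`enumerate_derivatives()` replaces a genetic structure builder with
deterministic exhaustive enumeration: every combination of (fragment or
hydrogen) at up to two substitution sites, minus the unmodified parent
— $(f+1)^2 - 1$ raw derivatives for $f$ fragments — de-duplicated by
canonical SMILES and rebuilt in 3D.  `empirical_prefilter()` keeps
derivatives whose *gas-phase* score (the four interaction terms,
without the dehydration term, matching the four-term function used at
this stage) against the mutant is strictly better than the parent's and
whose rule-of-five profile passes.  `two_track_select()` then applies
the full function to both receptors and keeps candidates with
ΔG(mutant) < ΔG(wild type) and a gap strictly larger than 5.0 kcal/mol,
ranked by mutant-track energy.  Whether the published 5 kcal/mol gap was
computed with or without the hydration term is not stated; the full
function is used here for the final selection.

## Synthetic fixtures and what they do (and do not) show

Real receptor structures are optional inputs; every pipeline stage is
testable against generated fixtures with known ground truth:

* `make_receptor_pair()` builds a toy kinase pocket: a five-residue
  hinge mimic numbered 791–795 whose backbone N–H (residue 793) and
  C=O (residue 791) point into the pocket — the alternating exposure of
  real kinase hinges — plus a nonpolar carbon cage lining the pocket,
  and two mutation-site atoms.  The mutant/wild-type toggle swaps a
  polar hydroxyl for a nonpolar carbon at the gatekeeper position (790)
  and a thiol for a hydroxyl at position 797, echoing T790M/C797S.
* The planted binder's coordinates are the relaxed minimum of the
  scoring function in that pocket (frozen as constants), so a correct
  search must localize it essentially exactly; its acceptor nitrogen
  and hydroxyl donor complement the two exposed hinge groups at
  hydrogen-bond distance.  One cage atom is placed to sterically
  exclude a methyl-flipped rotamer that is otherwise a decoy local
  minimum 0.13 kcal/mol above the planted pose.
* `make_library()` draws from a curated pool: 20 structurally diverse
  drug-like scaffolds inside the 300–400 amu window (pairwise path
  Tanimoto ≤ 0.70), small/large molecules outside the window, and
  sugar-like in-window molecules with two rule-of-five violations.
  In-window molecules are planted as exact-duplicate clusters
  (Tanimoto 1.0), so the expected survivor count of every filtration
  stage is known in advance: with the defaults, 200 → 150 (MW) →
  120 (rule of five) → 20 (clustering).

These fixtures validate the *contracts* — Eq.-level arithmetic, filter
logic, search convergence, determinism — not structural-biology
realism.  Passing them says nothing about pose accuracy on real
proteins, about the transferability of the illustrative hydration
table, or about how the funnel would behave on a real vendor library,
where near-duplicates are similar rather than identical and the
MW/logP distributions are continuous.

## Numerical choices and degenerate inputs

* Distances below 0.5 Å are evaluated at 0.5 Å everywhere, so clashed
  poses score large-but-finite.
* An isolated atom has occupancy zero and dehydration $S\,O^{max}$.
* An empty fragment library, an empty SMILES file, or a molecule with
  no rotatable bonds all flow through without special cases.
* Interpolation at a grid node reproduces the stored value exactly;
  boxes are snapped outward when built from a bounding box.
* Pose torsions are offsets from the input conformation, applied before
  the rigid transform about the ligand centroid.
* All stochastic components (embedding, search, refinement, finisher)
  are seeded; batches derive per-molecule seeds as `seed + k`.

## Problem sizes

The shipped defaults are sized for a desk-scale study: a 200-molecule
synthetic library (20 unique in-window scaffolds), toy receptors of
~60 atoms, pocket grid boxes of ~30³ nodes at 0.375 Å, searches of 6
starts × 150 annealing steps for library screening and 32 × 400 for
the planted-binder recovery study.  All of these scale up by
configuration; none are hard-coded.

## Known limitations

* The hydration S/V/O^max defaults are illustrative, not fitted; the
  absolute scale of the dehydration term on real molecules should not
  be interpreted until fitted parameters are supplied.
* Receptor protonation and tautomer assignment are taken as given.
* The optimizer is a simple annealer; on rugged landscapes it needs
  the candidate-rescoring and refinement stages to be reliable, and
  very flexible ligands (many rotatable bonds) will need larger search
  budgets than the defaults.
* Fingerprints are topological path fingerprints; stereochemistry is
  not distinguished.
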