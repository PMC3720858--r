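---
title: "Expansive exploration of backbone conformational space: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expansive exploration of backbone conformational space: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and limitations
behind `confexplore`, in the spirit of a methods section: what is
computed, under which assumptions, and where the design was genuinely
open, why the implemented choice was made.

## Backbone model

A protein conformation is reduced to its backbone dihedral angles. Each
residue contributes three atoms (N, CA, C) and two torsional degrees of
freedom, φ and ψ; the peptide torsion ω is held trans (180°) and bond
lengths and angles are fixed at idealized values:

| quantity | default | units |
|---|---|---|
| N–CA, CA–C, C–N | 1.458, 1.525, 1.329 | Å |
| N–CA–C, CA–C–N, C–N–CA | 111.2, 116.2, 121.7 | degrees |
| ω | 180 | degrees |

These are standard idealized peptide values; nothing downstream depends
on the specific constants as long as they are fixed, which is why they
are arguments of `ideal_geometry()` rather than hard-coded. Coordinates
follow from dihedrals by sequential natural-extension placement (each
atom positioned from the previous three by bond length, bond angle and
the governing torsion), with residue 1 at a canonical pose. The inverse
map is the standard four-point torsion; the round trip is exact to
ﬂoating precision, and the torsion sign convention was cross-checked
against two independent implementations (`bio3d::torsion.xyz` and
biotite's `dihedral`). Angles are degrees everywhere at API boundaries
and wrap to (−180, 180], with +180 included so that trans ω is
representable exactly.

All perturbation operators edit torsions *in place* by rotating the
downstream atom block about the bond axis. This keeps the global frame
of untouched atoms bit-identical — important both for testing contracts
("residues outside the subset do not move") and for composing moves in
world coordinates — and preserves ideal geometry exactly, since no
operation ever touches bond lengths or angles.

## Energy model and feasibility

The planner only ever asks one question of an energy function: *is this
conformation's score below the acceptance threshold?* Any deterministic
function of a conformation can be supplied. The built-in score is a
soft-sphere clash energy,

E = Σ over non-excluded pairs with d < 2σ of k(2σ − d)²,

with pairs within 3 bonds along the chain excluded. Defaults: σ = 1.5 Å,
k = 1 (score units/Ų), cutoff 8 Å. The contact radius deserves a note:
an ideal α-helix places C(i) and N(i+2) at ≈ 3.27 Å, and jittered
helices reach ≈ 3.13 Å. These approaches are hydrogen-bond-range
features of real backbones, not collisions, so the contact distance 2σ
must sit below them; σ = 1.5 Å (contact 3.0 Å) keeps Ramachandran-normal
secondary structure clash-free while still penalizing genuine steric
overlap. A carbon-like σ = 1.7 Å would misclassify every helix as
permanently clashed in a backbone-only model.

Feasibility is `energy ≤ threshold` — the boundary is deliberately
inclusive, so a threshold of exactly the start state's energy never
rejects the start. The threshold itself is a user input with no
universal default: it is a property of the energy function and of how
much strain a study tolerates.

`minimize_energy()` is derivative-free coordinate descent: each dihedral
in the subset tries ± step (default 5°), keeps a strict improvement, and
the step halves after a pass with no progress, terminating below 0.1°.
A gradient-free contract keeps the energy interface fully pluggable; the
minimizer is deterministic, monotone and is exposed to the planner as
the whole-protein minimization move with a small pass budget.

## Loop closure

`ccd_close()` implements cyclic coordinate descent: sweeping the loop's
φ/ψ in N→C order, each dihedral is rotated by the closed-form angle
minimizing the summed squared distance of the three anchor atoms (N, CA,
C of the residue immediately after the loop) to their targets, stopping
when the RMS anchor deviation reaches `tol` (default 0.08 Å) or after
`max_iter` sweeps (default 200). The per-step angle was verified against
brute-force one-dimensional minimization. The sweep loop is compiled
(Rcpp), as is the clash energy — these two kernels dominate planner run
time.

Two numerical behaviors of textbook CCD are worth knowing. First,
convergence is linear and can be slow when the remaining error is
rotational: from *fully randomized* loop dihedrals, closure of 5–9
residue loops to 0.08 Å succeeds in roughly half of cases within 200
sweeps, climbing above 95% only near 2000 sweeps. An independent
re-implementation reproduces the same success profile, and neither sweep
order, Ramachandran-restricted starts, nor adding the anchor residue's φ
changes it materially — it is a property of the algorithm, not of this
implementation. Inside the planner this is benign: a failed closure is
simply a rejected move. Second, atoms downstream of the anchors ride
rigidly with the anchor frame, so their displacement after a successful
closure is bounded by the residual deviation amplified by the lever arm
over the anchor triad's radius; tests use exactly that bound.

`loop_sample()` records the current anchor positions, randomizes the
loop uniformly, and closes back onto the recorded *global* positions.
Whether a loop move should close onto fixed global anchors or onto
anchors re-expressed relative to the moved downstream domain is a real
modeling choice; closing onto global positions was chosen because it
makes the "endpoints stay put" contract literal and testable. A subset
containing several disjoint loop regions is sampled as a sequence of
single-loop closures in random order, succeeding only if all close —
the simplest composition that honors the per-loop endpoint constraint.
`rigid_body_move()` reuses the same machinery with transformed targets:
a random rotation (≤ 5°) about the anchor centroid plus a random
translation (≤ 1 Å), which transports the downstream domain rigidly by
exactly the sampled transform when closure succeeds.

## Schemas

A schema is a list of residue subsets, each with a selection weight and
a distribution over move kinds. The automatic schema builds one subset
per maximal secondary-structure run with weights loop 1.0, sheet 0.2,
helix 0.1 — loops move, sheets flex a little, helices mostly hold — and
adds the all-residue subset at a fixed 9% selection probability, with
the remaining 91% split over elements proportionally to weight. Element
subsets draw dihedral/loop/rigid moves uniformly; loop-type moves on
helix and sheet subsets are intentional (they let secondary structure
dissolve), and loop moves on subsets touching the chain terminus simply
fail (no anchor residue exists) and count as rejected iterations.

The all-residue subset's internal move distribution is
{minimize 1/9, dihedral 8/27, loop 8/27, rigid 8/27}. This is the one
place where two published frequencies must hold at once: the all-residue
subset is selected 9% of the time *and* whole-protein minimization is 1%
of all moves. Giving the subset a pure minimization move would make
minimization 9%; the 1/9 share makes it exactly 0.09 × 1/9 = 1% while
keeping whole-protein perturbations available. Both frequencies are
recovered empirically by the test suite and the acceptance script.

Expert schemas are YAML/JSON files with 1-based residue ranges
(`"45-55,87-91"`), per-subset weights or explicit probabilities, move
distributions and parameter overrides. Probabilities that do not sum to
1 are renormalized with a warning rather than rejected — published
expert schemas sometimes list rounded values summing to 0.99, and
silently failing on them would be worse than renormalizing loudly.

## The planner

Density estimation uses a random 2 × 2n projection of the
cosine/sine-encoded dihedral vector: Gaussian entries, row 1 normalized,
row 2 Gram–Schmidt-orthogonalized and normalized. A random projection is
used because no natural projection exists in general and random ones
estimate occupancy well; orthonormal rows make the map non-expansive, so
grid locality is meaningful. One projection is drawn per run from the
run's master seed.

The default grid cell edge is calibrated from the start state: the
projected spread of 100 small random perturbations, divided by 10 per
axis — cells should be small relative to the reachable region but large
enough to accumulate counts; an explicit `cell_size` overrides this.
Interior/exterior flags are maintained incrementally on insertion (a new
cell can flip its occupied neighbors to interior) and are verified in
tests against brute-force 8-neighbor reclassification. Exterior bias
`p_ext` defaults to 0.75 — "heavily biased" without starving interior
refinement — and cell weight within a class is 1/count; selection counts
and cell ages are deliberately *not* part of the weight, keeping the
density model exactly inverse-occupancy.

Directed search replaces the schema move, with probability `goal_bias`
(default 0.05), by a bounded interpolation step: every dihedral moves
toward the goal along the shortest angular arc, at most `max_delta`
(default 10°) per angle. The stopping metric is the mean wrapped
absolute dihedral difference to the goal (default tolerance 5°), with
CA-RMSD reported alongside: the dihedral metric is the planner's native
space and is insensitive to the lever-arm amplification that makes
Cartesian RMSD jumpy for chain molecules. A budget of 0 iterations
returns the root-only tree, which makes the planner's contract easy to
reason about in degenerate configurations.

Runs are single-process and deterministic given (start, schema, config,
seed); two runs with the same seed reproduce the tree node for node.
Independent runs with different seeds can be merged offline from their
JSON-lines archives; there is no shared density state across processes.

## Synthetic test systems

`make_hinge_toy()` emulates a single-hinge two-domain transition: two
helices (φ, ψ ≈ −57, −47) joined by a loop seeded near (−120, 120) with
±5° jitter, the goal differing by a fixed shift (default 40°) of the
loop dihedrals only. `make_triloop_toy()` emulates coordinated
multi-loop motion: four helical blocks separated by three loops, the
goal built by passing one small rigid transform through each loop via
closure moves, so start and goal differ only in loop dihedrals and any
*single* closed-loop perturbation leaves the downstream domain pose
unchanged. Both generators verify clash-freedom of both endpoints at
generation time (regenerating with fresh jitter up to a bounded number
of attempts) and are deterministic per seed. Default sizes (21 and 28
residues) keep full planner runs in the seconds-to-minutes range on one
core; the test suite runs directed searches with budgets up to 20,000
iterations and comparison arms at 3,000.

What the toys do *not* emulate: side-chain packing, real Ramachandran
statistics, hydrogen-bond energetics, solvent, or the size of real
two-domain proteins. Passing tests on them demonstrates that the
kinematics, the constraint machinery and the search logic are correct
and that the planner recovers *designed* mechanisms; it does not
demonstrate biophysical accuracy on real systems, for which a real
energy function should be plugged in.

## Analysis

Torsional activity along a path is D_i = Σ_k |wrap(φ_{i,k+1} − φ_{i,k})|
+ |wrap(ψ_{i,k+1} − ψ_{i,k})|; undefined terminal angles contribute 0,
and the profile is additive under path concatenation. PCA embeds
conformations by superposing each onto a reference (Kabsch on CA atoms),
ﬂattening all backbone atoms, mean-centering and projecting on the top
two principal axes; superposition first makes the embedding invariant to
global rigid motion. Whether the embedding should use all backbone atoms
or CA only is not canonical — all atoms is the default and the choice is
an argument. Basin centroids are per-angle *circular* means of the
selected low-energy conformations, rebuilt through the kinematics:
averaging Cartesian coordinates would break bond geometry, and
averaging angles without circular statistics would fail across the
±180° seam. A degenerate (all-identical) ensemble reports explained
variance 0 rather than erroring.

## Known limitations

- Single chains, standard residues, no insertion codes; cis-proline and
  ω flexibility are out of scope.
- The soft-sphere score has no attractive terms: it measures
  self-collision, not stability, and thresholds are not transferable
  between energy functions.
- CCD closure from fully randomized loops frequently needs more than
  200 sweeps to reach 0.08 Å (see above); planners absorb this as
  rejected moves, but callers relying on high single-shot closure rates
  should raise `max_iter`.
- The projection is random: two runs with different seeds produce
  incomparable grids (merge archives, not grids).
- `explore()` keeps the whole tree in memory; budgets in the tens of
  thousands on small chains are comfortable, hundreds of thousands are
  not.
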