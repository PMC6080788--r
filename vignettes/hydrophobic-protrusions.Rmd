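---
title: "A convex-hull model of hydrophobic protrusions on peripheral membrane proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A convex-hull model of hydrophobic protrusions on peripheral membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prothull)
```

## The model

Peripheral membrane proteins bind bilayers transiently and shallowly, and
their interfacial binding sites (IBS) are hard to tell apart from ordinary
protein surface: both display small hydrophobic patches and basic residues.
This package implements a purely structural model of the hydrophobes that
matter for binding. The protein (or a whole quaternary assembly) is reduced
to its Cα and Cβ atoms, and three nested definitions are computed from that
point cloud:

* **Vertex residues** — residues whose Cβ atom is a vertex of the convex
  hull of all Cα/Cβ points. These are the residues that could touch a flat
  membrane without any other residue being inserted first and without
  backbone deformation.
* **Protrusions** — vertex residues in regions of low *local protein
  density* `d`, where `d` counts the Cα/Cβ atoms within `c = 1` nm of the
  residue's Cβ (own atoms included, boundary inclusive). A density is "low"
  when `d < n` with `n = 22`. Solvent accessibility is a precondition for
  the hydrophobic effect, and sparse neighbourhoods disturb lipid packing
  least on insertion.
* **Co-insertable pairs** — two protrusions whose Cβ points are joined by an
  edge of the hull polygon. Such residues can plausibly insert into a
  locally flat membrane *simultaneously*, which is what a hydrophobic
  binding patch requires.

A residue is a **hydrophobe** when it partitions favourably into the
membrane interface on the Wimley–White interfacial scale: Leu, Ile, Phe,
Tyr, Trp, Cys, Met. The **Likely Inserted Hydrophobe (LIH)** — the
single-residue binding-site prediction — is the protruding hydrophobe with
the largest number of co-insertable protruding hydrophobes; ties are broken
by smallest `d`, and remaining ties by a seeded random draw, so every
protein with at least one protruding hydrophobe has exactly one LIH.

The model deliberately assumes a rigid protein conformer and a locally flat
membrane, and excludes energetics (electrostatics, desolvation) by design:
it isolates the structural component of hydrophobic membrane anchoring.

```{r example}
fx <- make_spiky_protein(fixture_spec(n_spikes = 8,
                                      hydrophobe_placement = 0.6, seed = 1))
fit <- protrusion_model(fx$model)
fit
```

## Parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `density_radius` (`c`) | 1 nm | neighbourhood radius for `d`, around the Cβ |
| `density_threshold` (`n`) | 22 | protrusion requires `d < n` |
| `sasa_probe_radius` | 0.14 nm | solvent probe for side-chain accessibility |
| `sasa_exposure_threshold` | 0.2 nm² | "exposed" requires side-chain SASA strictly above |
| `hydrophobe_set` | 7 residues | Wimley–White interfacial hydrophobes |
| `fragment_min_distance` | 1.5 nm | non-binding fragments lie at least this far outside the hydrocarbon slab |
| `hull_tolerance` | 1e-9 nm | points this close to a facet count as on-hull |
| `facet_merge_tolerance` | 1e-6 rad | adjacent facets with closer normals are one polygon |

All coordinates are converted to nanometres on input (PDB Å ÷ 10).

## Geometry: numerical choices

The convex hull is computed by an incremental algorithm over the full
Cα/Cβ cloud (compiled code). Degenerate inputs — fewer than four points, or
collinear/coplanar clouds — raise errors naming the rank rather than being
joggled. "Edge of the hull polygon" is ambiguous for a triangulated 3-D
hull: a flat face triangulated into several triangles has internal edges
that are artifacts of the triangulation. We therefore drop every edge whose
two adjacent facets have normals within `facet_merge_tolerance` (10⁻⁶ rad)
of each other; what remains are edges of the merged polygonal faces. For
random point clouds in general position this changes nothing; for
symmetric synthetic inputs (a cube, say) it removes the face diagonals.
The test suite checks the vertex *and* edge sets against an independent
brute-force oracle that decides vertexhood and edgehood per point/pair by
linear programming.

Two counting conventions are documented because results depend on them:
the local density includes the residue's own Cα and Cβ (so an isolated
residue has `d = 2`), and the distance test is inclusive (`≤ c`). A vertex
residue with `d = 21` is a protrusion; `d = 22` is not. Glycines (and
residues with disordered side chains) contribute their Cα to the cloud and
to other residues' densities but can never be vertex residues, since
vertices are defined on Cβ atoms.

## Solvent accessibility

Side-chain solvent-accessible areas use Bondi van der Waals radii, a
0.14 nm probe, and deterministic numerical integration: 960 golden-spiral
points per atom; a point is accessible when outside every neighbouring
expanded sphere. The analytic procedure the definition refers to is
approximated numerically — only the 0.2 nm² threshold crossing matters
downstream, and the isolated-atom error is below 2% (checked against the
closed form 4π(r+p)²). Side-chain atoms are all heavy atoms except N, Cα,
C, O and OXT; Cβ counts as side chain (the conventional choice; the
exposure flag of small residues is sensitive to it), and glycine has area
zero.

## Membrane frame and the insertion coordinate

An OPM-style membrane is a planar slab: center, unit normal and hydrocarbon
half-thickness `h` (the planes where the hydrocarbon volume fraction is
one half). The insertion coordinate of an atom is `h − |z|`, with `z` its
along-normal coordinate relative to the slab midplane: positive inside the
hydrocarbon core, zero on either boundary plane, negative on the solvated
side. Both leaflets fold onto one axis, so for transmembrane complexes the
non-binding-fragment rule (insertion coordinate ≤ −1.5 nm, inclusive)
automatically selects the solvated caps on *both* sides. Distance is
measured along the normal, consistent with the infinite-plane membrane
model. Structural annotations (hull, densities, pairs) are always computed
on the entire complex; the fragment restricts only the statistical
selection.

Family-level agreement with a membrane model is summarised by the median
insertion coordinate of the LIH's Cα per family, and the fraction of
families whose median is within a 0.5 nm margin of the membrane
(median ≥ −0.5 nm). The margin absorbs the rigid-protein and flat-membrane
assumptions and the Cα-to-side-chain offset.

## Family-weighted statistics

Protein structure databases are redundant; the statistics therefore weight
each *family* equally. With `G_s` the residues of protein `G` satisfying a
selection `s`, and `C` a family within data set `D`:

* mean fraction within a family: average over members of
  `|G_s ∩ G_r| / |G_r|` (members with no `r`-residues are skipped and the
  mean renormalized);
* weighted count `N̂_s = Σ_C (1/|C|) Σ_G |G_s|`, and the weighted protein
  count `M̂_s` replacing `|G_s|` with the indicator `|G_s| > 0`;
* weighted fraction `F̂_{s|r} = N̂_{s∩r} / N̂_r` and protein fraction
  `Ê_s = M̂_s / |D|`;
* the same constructions over co-insertable pairs, including the
  co-insertion frequency `F̂^pair_{both|one} = N̂^pair_both / N̂^pair_one` —
  the conditional probability that both members of a co-insertable pair are
  protruding hydrophobes given that one is.

Two data sets are compared by the log odds ratio
`ln R = ln[F̂_A(1−F̂_B)] − ln[F̂_B(1−F̂_A)]`, antisymmetric under swapping A
and B. Confidence intervals are 95% Wald intervals throughout, with the
real-valued weighted counts standing in for integer successes and failures
(for fractions, `N̂_r` is the trial count; for the pair comparison the
failures are `N̂^pair_one − N̂^pair_both`). A fraction of exactly 0 or 1
yields a flagged infinite estimate — never a silently clipped one. No
multiple-testing correction is applied anywhere; estimates and intervals
are reported as-is, and users comparing many selections should correct
downstream.

The co-insertion *null model* relocates each protein's hydrophobes
uniformly among its protruding positions (preserving their number),
recomputes the pair counts against the fixed hull adjacency, and assembles
family-weighted null counts with the same weighting; the observed
co-insertion frequency is compared to the null via the odds ratio, with the
permutation-mean counts serving as the null data set's successes and
failures. Permutation streams are keyed by (seed, protein id), so results
do not depend on evaluation order.

One property of this comparison deserves emphasis: because the null
preserves each protein's hydrophobe count, the largest source of sampling
variation is shared between the observed and null sides and cancels in
`ln R`, while the Wald interval prices both sides as independent data sets.
The observed-vs-null interval is therefore *conservative* — in simulations
with uniformly placed hydrophobes it covers zero in essentially all
replicates, not 95% of them. It will understate, never overstate, the
evidence that hydrophobes cluster on co-insertable positions.

## Binding-site evaluation

Predictions are compared to experimentally identified binding residues
coarsely, by direction: `t_I` is the mean Cα position of a residue set `I`
minus the mean Cα position of *all* residues (the plain Cα mean, not a
mass-weighted center), and the evaluation reports the angle between
`t_I(experimental)` and `t_I(LIH)`. Angles below 90° mean prediction and
experiment are on the same side of the protein. Controls take every
protrusion singly; on a spherically symmetric fixture their median angle is
90°. A protein with no protruding hydrophobe has no LIH and is reported at
the 180° sentinel with an explicit flag, following the convention of
plotting such proteins at 180°.

## Synthetic fixtures: what they emulate, and what they do not

Every statistical claim in the test suite runs on synthetic structures with
*known* ground truth: a dense core of residues sampled in a 1 nm ball (so
dense that its surface residues always have `d ≥ 22`) decorated with radial
spikes 1.2 nm long whose tips are hull vertices with low density by
construction — planted protrusions. Spike Cβs sit 0.15 nm outside their Cα
along the spike. Hydrophobes are planted on spike tips deterministically or
with a given probability. Generation verifies its own ground truth (the
planted spikes must be exactly the detected protrusion set) and fails
loudly otherwise; the hull code itself is validated independently against
the LP oracle.

The calibration studies use these layouts, chosen once as representative
desk-scale conditions: enrichment recovery uses two cohorts of 100
single-protein families with 30 protrusions each and hydrophobe
probabilities 0.5 vs 0.2 (true `ln R = ln 4`); null calibration uses 500
cohorts of 30 single-protein families with 10 protrusions each at
probability 0.5, 200 permutation samples per protein.

These fixtures emulate the *geometry* the definitions rely on — hull
vertices, density contrast, hull-edge adjacency, membrane placement — with
exact ground truth. They do not emulate real protein shape: cores are
isotropic, spikes are quasi-uniformly placed (every hull vertex is a
protrusion, and the protrusion adjacency graph is denser and more regular
than on real structures), amino-acid identities are arbitrary, and there is
no secondary structure or full-atom packing. Passing tests therefore
demonstrate correctness of the definitions, the statistics and their
plumbing — not predictive performance on real membrane-binding proteins,
which requires curated structures, membrane orientations and family labels
supplied by the user.

## Degenerate inputs and edge cases

* Structures with fewer than 4 points, or collinear/coplanar clouds:
  errors naming the rank.
* Residues without Cα are dropped (with a warning); residues without Cβ
  are kept but can never be vertices and have undefined density (`NA`).
* Alternate locations: highest occupancy wins, ties to file order. NMR
  ensembles: first model by default. Hydrogens, waters and unmappable
  heteroatoms are excluded; MSE and a few other common modified residues
  are remapped to their parent amino acid.
* Selections with empty reference sets: explicit errors (`weighted_fraction`)
  or skip-and-renormalize with a message (`mean_fraction`).
* Cohorts where every pair count is zero: the co-insertion frequency is
  flagged undefined rather than computed as 0/0.
* DSSP codes are mapped H/G/I→helix, B/E→beta, T→bend, S→turn, rest→loop.
  The T/S labels intentionally mirror the model's published convention even
  though they swap the usual DSSP nomenclature; pass a custom `mapping` to
  `map_secondary_structure()` for the conventional reading.

## Known limitations

* The hull tolerance treats points within 10⁻⁹ nm of a facet as on-hull;
  a residue exactly coplanar with a hull face is not counted as a vertex.
* SASA is numerical; areas carry ~1–2% integration error (the exposure
  *flag* is stable well away from the threshold).
* The observed-vs-null odds-ratio interval is conservative (see above).
* The package consumes membrane orientations and family labels; it does not
  predict orientations, fetch databases, or prune redundancy itself.
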