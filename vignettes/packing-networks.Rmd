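---
title: "Surface contact networks and packing motifs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface contact networks and packing motifs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packnet)
```

This vignette is the package's account of its methods: the models and
conventions, the tunable parameters, what the synthetic generators do and do
not emulate, the numerical choices, and the known limitations. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## Surfaces and burial

Each atom's van der Waals sphere is sampled on a deterministic golden-spiral
lattice at a dot density of 10 points/Å² (configurable), normals pointing
radially outward; a point is discarded when it lies strictly inside any
other atom's sphere (distance < radius − 10⁻⁹ Å). The same occlusion rule
removes the interpenetration points of disulfide-bonded or covalently
linked atoms. The lattice is seedless, so surfaces are reproducible bit for
bit. Solvent accessibility uses the identical machinery with all radii
inflated by the probe radius (1.4 Å, a water molecule) — a Shrake–Rupley
construction on the same lattice, which is why SASA computed at density 10
and 50 agrees to within a few percent.

The burial ratio of residue X is its SASA in the chain divided by the SASA
of X as the middle residue of a fully extended (φ = ψ = 180°) Gly-X-Gly
tripeptide built from ideal internal coordinates with the same radii, probe
and density. Ratios ≤ 0.05 count as completely buried, ≤ 0.3 as partially
buried; anything more exposed is excluded from network node sets. The
reference is computed on demand and memoised; it exists for the residue
types the internal peptide builder covers (Gly, Ala, Val, Leu, Ile, Phe,
Tyr — the hydrophobic set at the centre of the analysis, minus tryptophan,
whose fused indole we have not templated). Radii default to the standard
crystallographic set and are configurable (`vdw_radii()`), since published
all-atom force fields differ in the second decimal. Structures are loaded
from PDB with the usual database policies: one chain (largest or named),
hetero/water dropped, the highest-occupancy conformer per atom (first on
ties), hydrogens used when present. We do not protonate internally; a
residue with missing heavy side-chain atoms is reported and should be
excluded from node sets.

## Surface complementarity and contact

For a side-chain surface point *a* of a target residue, the nearest surface
point *b* of any *other* residue within 3.5 Å defines the score
`S(a,b) = −(n_a·n_b)·exp(−w·d²)`, `w = 0.5` Å⁻². The minus sign makes
+1 the perfect fit: apposed surfaces have opposing outward normals. A
target's matched points are partitioned into patches by neighbour residue;
`Sm` is the patch median (even-length medians average the central pair) and
`Ov` the matched fraction of the target's side-chain points, so the overlaps
of one target sum to at most 1. Main-chain surfaces participate as
environment only; matches within the same residue are never counted.
Nearest-neighbour ties break to the lowest (atom serial, point index).

A **contact** requires reciprocity: both directed pairs must reach
`Sm ≥ 0.4` and `Ov ≥ 0.08` (stricter cutoffs are a parameter). The contact's
`Sm`/`Ov` are the means of the two directions, and the edge weight
`sqrt(Sm² + Ov²)` treats fit and extent as orthogonal components. The
median-based `Sm` has a property worth spelling out: it is a *contextual*
score. An isolated residue pair in vacuum almost never passes 0.4, no matter
how snugly the facing surfaces fit, because every point within 3.5 Å of the
large neighbouring blob joins the patch and the non-facing majority drags
the median to zero. In a crowded interior each neighbour claims only the
points that genuinely face it, patches are small (`Ov` of order 0.1–0.2) and
the median sits in the snug zone. High `Sm` therefore certifies packing *in
context*, which is the point of the measure — and it dictated the design of
the synthetic fixtures (below).

## Networks

Two network types share one container (igraph, vertices keyed by residue
number): the surface contact network (ASCN) over commutative contacts, and
the point-atom network (APCN) linking residues with any inter-side-chain
atom pair strictly below 3.8 Å, weighted by the count of such pairs. Nodes
are non-glycine residues with burial ≤ 0.3; connected components with at
least 3 nodes are the networks ("no standalone node"). Per node we report
degree, strength, the unweighted clustering coefficient
`C_i = |{e_jh}|/C(k_i,2)` and the strength-normalised weighted form of
Barrat and colleagues (through igraph), which reduces exactly to `C_i` at
equal weights — used as a consistency check, not a separate definition. The
maximal clique order is found by growing every ordered triangle with nodes
adjacent to all current members, exploring all extension orders (every
clique contains its lexicographically smallest triangle, so the ordered
search is exhaustive); triangle-free graphs have no clique order. Random
nulls connect each pair with probability equal to the source graph's link
density, weights drawn uniformly from the observed weight multiset. Size
distributions are fitted as `f(x) = k·x^−n` by ordinary least squares on
log–log frequencies with zero-count sizes dropped (no fitting method is
canonical here; OLS is transparent and adequate for the property checks).
Family/class propensities use `P = (N_fC/N_f)/(N_C/N)`.

## Motif identifiers, families, resolution

A motif's identifier concatenates per-node strings — own degree, then
neighbour degrees sorted descending — sorted in descending order as integer
sequences (so degrees ≥ 10 cannot corrupt the order) and joined with "-".
The identifier is invariant under relabelling by construction. It is **not**
a complete invariant: exhaustive enumeration finds collisions from order 6
upward (the triangular prism and K₃,₃ share an identifier, as do the
two-triangles-joined-by-an-edge core and the six-ring with a long
diagonal). The package therefore treats the identifier as a fast key guarded
by an exact-isomorphism oracle (backtracking with degree pruning, n ≤ 10):
enumeration verifies every identifier bucket, warns loudly on a collision,
and separates colliding motifs with a canonical (BLISS) labelling appended
to the string. Catalog lookups verify by isomorphism whenever the entry
carries an adjacency.

Enumeration is exhaustive by vertex extension: every connected graph on n
nodes arises from one on n−1 by attaching a vertex to a non-empty subset
(every connected graph has a non-cut vertex), with optional degree caps
applied during extension.

Families grow from core topologies by the path relation — adding a degree-1
node to exactly one existing node. Classification reduces a motif by
deleting degree-1 nodes (all orders, memoised) until a catalog entry is
reached; a missing intermediate therefore does not break membership, and
ties between reachable cores resolve by catalog order. The catalog
(`inst/extdata/motif_families.json`, editable) seeds f1 (open chains), f2
(triplet cliques), f3a/f3b (4-rings, 0/1 diagonal), f4a/f4b/f4c (5- and
6-rings), f5 (edge-fused triplet strips), f6a/f6b (node-/edge-connected
triplets), f7 (node-linked 4-rings), f8a (embedded 4-cliques with
branching), f8b (other non-planar graphs) and f8c (theta-like double-path
closures), plus the fused-triplet exception identifiers retained in f4a and
f4b. The f8 seeds and the exception list are provisional: their textual
definitions are looser than the rest, and one printed exception identifier
was internally inconsistent (its sole degree-1 node must attach to a
degree-4 node, forcing the terminal string "14"); the catalog carries the
corrected, uniquely realizable form.

`resolve_graph()` explains a graph in terms of the catalog: it cuts bridge
edges only (never an edge on a closed ring), searching bridge subsets
smallest-first and accepting the first cut whose components are all catalog
motifs or family members — the fewest-parts preference. Only when no cut
resolves the graph is the intact graph classified as a whole, and failing
that, maximal catalog cores are reported as induced subgraphs over the
uncovered nodes. A whole-graph check *before* cutting would be wrong for
the catalog cores themselves (two bridged triangles are both "the f6b core"
and "two f2 components"; decomposition is this function's job, so cutting
wins). The bridge-subset search is capped (default 4096 subsets) before
falling back to cutting all bridges.

## Triplet-clique geometry

Residue-internal right-handed frames: aromatics take the ring centroid as
origin and the least-squares ring-plane normal as Z (phenyl for Phe/Tyr,
indole for Trp), X towards the first ring atom projected in-plane; branched
residues take the fork apex and fork plane (Val: CB→CG1/CG2, Leu:
CG→CD1/CD2, Ile: CB→CG1/CG2 — the branch point, not CD1); alanine, which
has no fork, uses origin CB, Z along CA→CB and X as the in-plane component
of CA→N, a deterministic but convention-dependent choice flagged as such.
Degenerate definitions (collinear forks) are errors.

The three origins span a triangle (sides `r_12, r_13, r_23`, angles summing
to 180°). The global frame sits at the centroid, Z along `v1 × v2`
(v1 = R1→R2, v2 = R1→R3), X towards R1. The labelling conventions per
composition class: **C1** (all different) orders by side-chain volume
R1 > R2 > R3 (a shipped standard volume table; only the order matters, and
the Leu/Ile near-tie breaks alphabetically); **C2** (two identical) takes
the unique residue as R1, assigning R2/R3 so R1's tilt is acute, and
superposes same-composition triangles onto a template; **C3** (all
identical) superposes onto an arbitrary template with the best of the 6
label permutations. Tilt `θ_t` is the angle between the global Z and each
residue Z; swivel `φ_s` is the signed angle (0–360°) from the residue X to
the projection of the global Z onto the residue's XY plane, undefined
(flagged) at tilt 0/180°.

Two numerical subtleties deserve a note. First, superposition fits the
three origins by proper-rotation least squares — but a bare triangle is
achiral, so the two label chiralities fit equally well; the residue Z axes
break that tie (a small additive mismatch term that never overrides a
discriminating origin fit). Second, a C3 template's own label order is
arbitrary, and swapping two labels mirrors every tilt (θ → 180° − θ); the
template's normal sign is therefore fixed from its own physics — the
triangle normal must have a non-negative mean projection on the three
residue Z axes. With both conventions, repeating an analysis from a
different starting template changes superposed angle statistics only
marginally, which the test suite checks on noisy copies of a base triplet.

The random null for tilt is the angle between independent random directions,
density `sin θ/2`: a 30° bin `[a, b]` holds `(cos a − cos b)/2` — 6.7, 18.3,
25.0, 25.0, 18.3, 6.7 per cent across six bins, folded to three bins
(13.4/36.6/50.0) for the two-fold symmetric Phe/Tyr rings. Swivel, being
planar, is uniform across bins. χ² = Σ(O−E)²/E with df = bins − 1 against
the 0.05 critical value; the usual validity rule (every expected count ≥ 5)
is reported as a flag rather than hard-coded minimum sample sizes. Sequence
separation ≤ 10 residues marks a clique contact as local.

## Fold signatures, snet and dnet

Given a template's network, homologue networks and one-to-one residue maps
(gaps allowed), each template link's conservation `lp` is the fraction of
homologues in which both mapped endpoints exist and are linked — an
unaligned endpoint counts as absent. Links with `lp ≥ 0.8` form the fold
signature. A candidate's subgraph is induced over the signature nodes in
template order, rows/columns zero-padded for missing nodes.
`snet = N_t/N_s` is the fraction of signature links present;
`dnet = |E Δ E′|/|E ∪ E′|` is the normalised symmetric difference, defined
as 0 when both edge sets are empty (the formula is 0/0 there), and is a
metric on fixed-node-set graphs — the suite verifies all four axioms on
random triples since no proof is given in the literature the measure comes
from. Scoring a candidate set reports per-candidate values and population
mean/σ/min/max; rotamer threading and energy minimisation of decoys are
deliberately out of scope — the package consumes networks and maps produced
by any external tools.

## Synthetic generators: what they emulate

Every generator is deterministic per seed.

* `gen_patch_pair()` — two congruent flat dot grids at separation *d* with
  opposing (or parallel) normals: every point's nearest neighbour is its
  direct opposite, so the analytic patch complementarity is exactly
  `± exp(−0.5 d²)`, the oracle for the scorer.
* `gen_random_graph()` — Bernoulli or exact-edge-count graphs with optional
  degree caps and connectivity (a degree-respecting random spanning tree
  plus feasible extra edges, retried on dead ends).
* `gen_triplet_frames()` — frames with prescribed triangle sides, tilts and
  swivels, recovered exactly by the analysis (round-trip oracle).
* `gen_toy_structure()` — the end-to-end fixture. The packed core is three
  ideal-geometry leucines in a ring, each side-chain tip wedged against the
  next residue's fork face, surrounded by two lid and six wall leucines.
  The shell is not decoration: because `Sm` is contextual (see above), an
  isolated trio cannot pass the 0.4 median no matter how it is posed — the
  crowding focuses each core patch onto its facing neighbour exactly as a
  real protein interior does. The design was verified across seeds: the
  surface network is a single triplet clique with Sm ≈ 0.5 and Ov ≈ 0.15,
  the core comes out partially buried (ratio ≈ 0.12) and the shell exposed,
  and the burial-filtered point-atom network reproduces the same triangle —
  the designed 3.8 Å correspondence. The `loose` layout expands the ring
  beyond contact range. What the toys do **not** emulate: chain
  connectivity between residues (each residue is a free fragment),
  hydrogens, thermal disorder, and the compositional diversity of real
  cores; passing tests on them validates the machinery, not biological
  statistics.
* `gen_tilt_sample()` — isotropic angles (cos θ uniform, the sine null) and
  concentrated alternatives for power checks.

## Problem sizes and test design

The suite runs in about a minute on one CPU with dot density 10 throughout:
exhaustive motif spaces to order 7 (853 classes), 500 random graphs (n ≤ 12)
against the clique oracle, 1000 random triples for the dnet metric, 10⁵
Monte-Carlo tilt draws against the analytic null, 1000 replicates of n = 300
for the 5% type-I calibration, and the 11-residue toy structures for the
end-to-end pipeline. These sizes were chosen as the smallest that make each
property decisive (e.g. the binomial standard error at 1000 replicates is
well inside the 3–7% acceptance band for a nominal 5% rate).

## Known limitations

* The peptide builder covers Gly/Ala/Val/Leu/Ile/Phe/Tyr without hydrogens;
  burial references and toys are limited accordingly (loaded PDB structures
  may contain any residue and keep their hydrogens).
* The f8a/f8b/f8c family definitions and the printed exception identifiers
  are provisional encodings of loose textual descriptions.
* The motif identifier needs its isomorphism guard from order 6 upward; the
  package never trusts it alone.
* `resolve_graph()` prefers fewest cut bridges and is capped, not a proven
  optimal decomposition ("more than one sequence of steps" can exist).
* Sm on van der Waals surfaces is marginally lower than on re-entrant
  (Connolly) surfaces; only the van der Waals variant is implemented.
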