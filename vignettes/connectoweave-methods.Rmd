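---
title: "Methods: connectome conditioning, graph indices and connectogram geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome conditioning, graph indices and connectogram geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectoweave)
```

connectoweave analyzes parcel-based brain networks: an atlas of `N`
gray-matter parcels defines the nodes, and an `N x N` symmetric
non-negative matrix of association weights (for structural connectivity,
typically reconstructed-fiber counts normalized by parcel volume) defines
the edges. This vignette is the package's account of the modelling choices
behind each stage — what is computed, under which conventions, and why the
conventions were chosen where more than one was defensible.

## The three-file contract and display order

A network is assembled from three inputs: an atlas table (ordered parcels
with short legends, optional group tags such as lobes, and arbitrary
attribute columns), a label file giving parcel names in matrix row order,
and the matrix itself. The atlas order is authoritative for everything a
reader sees — the first atlas parcel sits at the top of the connectogram
ring and order proceeds clockwise — while the label order is authoritative
for the matrix. `assemble_network()` computes the permutation between the
two once, and the raw weights are never reordered in place; display-order
views are produced on demand. This separation is what lets one atlas file
serve many matrices whose row orders differ, with a stable circular
layout.

Validation is strict by design: unknown or duplicate labels, non-square
matrices and negative weights are errors, not warnings. Asymmetry up to
`1e-8` (float noise from upstream pipelines) is repaired by averaging
`W` with its transpose; anything larger is treated as a corrupted input
and reported with the worst offending cell. A nonzero diagonal is zeroed
with a warning, since self-connections are meaningless here. Negative
weights are rejected throughout: the package targets structural
connectivity; functional-connectivity matrices with negative correlations
are out of scope.

## Conditioning

**Density thresholding.** The target density `d` is realized by keeping
the `k = round(d · N(N−1)/2)` strongest edges. This is equivalent in
result to iteratively raising an absolute threshold from zero until the
achieved density best approximates the target, but exact and
deterministic: ties at the cutoff weight are broken by lexicographic
`(i, j)` upper-triangle order. Rounding is half away from zero everywhere
in the package (see *Numerical conventions*). Asking for a density at or
above the current one returns the matrix unchanged (with a warning when
strictly above), because thresholding can only remove edges.

**Normalizations.** `normalize_by_parcel_volumes()` divides each weight
by the sum of the two parcel volumes, compensating for parcel-size
differences before group analysis; `normalize_by_max()` rescales to
`[0, 1]`. Max normalization is idempotent and ratio-preserving, and the
weighted metrics apply it internally so their values are invariant to the
overall weight scale.

**Group consensus.** `build_group_matrix()` retains an edge only if it is
nonzero in at least `ceiling(p · S)` of the `S` subjects (default
`p = 0.53`, so 10 of 17 subjects), and sets its weight to the mean across
subjects. Whether the mean should run over all subjects or only those
possessing the edge is genuinely ambiguous in the field; the default is
the mean over all `S` (absent edges contribute zero), `mean_over =
"present"` selects the other reading, and the choice is recorded in the
run manifest so a consensus matrix is always traceable to its convention.
The `ceiling` reading implements "shared by at least a fraction p":
with 17 subjects, a 9/17 edge (52.9%) is dropped and a 10/17 edge kept.

## Sub-network selection

Two complementary logics mirror interactive exploration:

- **Seed–target exploration** keeps only edges joining a seed parcel to a
  target parcel (seeds may appear among targets, enabling seed–seed
  edges). It returns an *edge mask*, never a modified matrix: the full
  node ring stays in place and original weights are preserved, so masked
  views can always be compared side by side with the complete network.
  Masks are symmetric with a false diagonal and compose by elementwise
  AND.
- **Subgraph extraction** physically restricts the network to a selected
  parcel set (at least two parcels), copying the original weights between
  all surviving pairs and preserving atlas order among them. Metrics on
  the extracted network equal metrics on the directly gathered submatrix.

Selection tokens resolve by exact, case-sensitive match with precedence
parcel name > group tag > attribute tag. A token that is not a parcel
name but matches both a group tag and an attribute value is an error
rather than a silent union: scripted selections must be unambiguous to be
reproducible. Case-folding is deliberately not attempted — atlas names are
a controlled vocabulary, and silently matching `fro-l` to `Fro-L` would
mask upstream pipeline bugs.

## The index suite

The suite comprises 20 computed indices: six local families (binary
degree, strength, binary and weighted clustering, binary and weighted
local efficiency), twelve global values (average degree and strength,
mean binary/weighted clustering, binary/weighted characteristic path
length, binary/weighted global efficiency, small-worldness, modularity,
coreness, density), plus the community partition and the core–periphery
assignment as intermediate structure.

Conventions that matter:

- **Weighted distances** are reciprocal max-normalized weights,
  `l_ij = 1/ŵ_ij`: strong connections are short. This is the standard
  connectomics convention of the toolbox lineage these indices come from.
- **Characteristic path length** averages over *reachable* ordered pairs
  only, and the number of unreachable pairs is reported alongside.
  Lesioned or heavily thresholded matrices are often disconnected;
  averaging infinities would poison every downstream comparison, and
  silently dropping the information would hide the disconnection itself.
  Global efficiency needs no such care (unreachable pairs contribute 0)
  and is the more robust integration measure on fragmented networks.
- **Weighted clustering** uses the geometric-mean (cube-root) triangle
  form; **local efficiency** of a node is the global efficiency of the
  subgraph induced by its neighbours (hop lengths for binary, `1/ŵ` for
  weighted). Nodes of degree < 2 take clustering and local efficiency 0
  by default and are *included* in network means; `drop_low_degree =
  TRUE` marks them `NA` and excludes them, for users who prefer the other
  aggregate. All-pairs distances use a vectorized Floyd–Warshall sweep,
  exact for non-negative lengths and fast at parcellation scale.
- **Small-worldness** `σ = (C/C_rand)/(L/L_rand)` uses degree-preserving
  double-edge-swap rewiring, 10 null graphs and 10 swap attempts per edge
  by default, seeded; the seed is recorded in the result. No standard
  null recipe exists, so the recipe is a documented default rather than a
  hidden constant; on degree-matched random graphs σ centres on 1.
- **Modularity** is maximized by a multi-level (Louvain-style) greedy
  algorithm on the weighted matrix with resolution `gamma` (default 1),
  best-of-`repetitions` restarts (default 100) with shuffled node orders,
  deterministic given the seed. Ties during local moving favour staying
  put, which keeps the algorithm stable on symmetric graphs.
- **Coreness.** The classical Borgatti–Everett correlation objective is
  undefined on uniform-weight graphs (the adjacency has zero variance),
  so the package optimizes the density-corrected form
  `q = Σ B_ij Δ_ij / Σ|B_ij|` with `B = W − γ·mean(W_offdiag)` and
  `Δ_ij = 1` unless both endpoints are periphery. This is defined for
  every input, gives `q = 0` to the degenerate all-core and
  all-periphery splits (and to every split of a complete graph), and is
  maximized by greedy label switching over seeded restarts. Isolated
  nodes are barred from the core. On small graphs the search attains the
  exhaustive optimum.
- **Rich club** `φ(k)` is the edge density among nodes of binary degree
  `> k`, reported for `k = 1..max degree` with undefined levels (< 2
  surviving nodes) flagged `NA` rather than 0 — an absent value and an
  empty club are different findings.
- **Delta reports** compute `(Reference − Case)·100/Reference` per index;
  positive deltas mean the case is below the reference. A zero reference
  makes the delta undefined (`NA`), flagged rather than propagated as
  infinity. Raw and 1-decimal display values are both kept.
- **Decile highlighting** selects `k = round(fraction·N)` top and bottom
  nodes (default fraction 0.10; at `N = 165`, `k = 17`). A single ranking
  — value descending, atlas order ascending — defines both classes, so
  they are always disjoint and exactly `k` each even under heavy ties.

## Connectogram geometry

Nodes are placed at equal angular spacing on the unit circle, first atlas
parcel at angle `π/2` and order clockwise, which puts a left-hemisphere
-first atlas on the left half of the ring as in published connectograms.
An edge between boundary points `u` and `v` is drawn as the hyperbolic
geodesic of the Poincaré disk: the arc of the circle through `u` and `v`
orthogonal to the unit circle, whose center solves the linear system
`u·c = 1`, `v·c = 1` with radius `r = √(|c|² − 1)`; antipodal endpoints
(within `1e-9`) degenerate to a straight chord. The drawn arc is the one
inside the disk, selected as the short angular sweep around `c`. Long-
range connections therefore bow through the middle while short-range ones
hug the rim, which is what makes dense connectograms legible. Arcs are
stacked in ascending weight order so strong connections render on top.
Rendering separates geometry (`build_connectogram()`, a data object whose
arc table satisfies the orthogonality identities to `1e-9`) from drawing
(`autoplot()`) and from file output (`render_connectogram()`, SVG via the
cairo device plus rasterized PNG). SVG output is byte-deterministic for
fixed inputs; the device's session-global raster counter is rewritten to
stable identifiers on write.

## Synthetic data: what it does and does not emulate

The generators produce atlases with contiguous lobe-like group blocks and
an L/R hemisphere attribute; weight matrices that are symmetric,
zero-diagonal and hit a requested density *exactly* (edge count
`round(d·E_max)`), with uniform `(0, 1]` weights; subject stacks in which
a core edge set is present in every subject and a variable set in an
exact, chosen number of subjects; and planted block-model graphs with
known communities. Defaults mirror the case study's conditions: 165
parcels, 16 groups (8 lobe-like groups per hemisphere), densities in the
15–50% range with the healthy-control consensus at 47.51%, and 17-subject
stacks for the 53% presence rule. Uniform weights carry none of the
distance dependence, hub structure or heavy-tailed fiber-count
distributions of real tractography, and the generators make no attempt at
them. Consequently, passing tests demonstrate that the *computations* are
correct (selection logic, presence arithmetic, index definitions,
geometry), not that any biological effect is reproduced; conversely the
delta engine is checked against the published case-study table directly,
from its printed values.

## Numerical conventions and degenerate inputs

- Rounding of discrete counts (threshold edge count, highlight class
  size) is half away from zero, consistently: 10% of 165 is 16.5 and must
  give 17 to match decile highlighting at parcellation scale.
- Symmetry repair tolerance `1e-8`; geometry identity tolerance `1e-9`;
  greedy-search improvement threshold `1e-12` (strictly-better moves
  only, so optima never drift on plateaus).
- Degenerate inputs fail loudly with typed errors: fewer than 2 nodes for
  density, fewer than 3 for clustering, edgeless networks for path
  length/communities/core-periphery, all-zero matrices for max
  normalization, empty seed or target sets for exploration.
- Every stochastic routine (rewiring nulls, Louvain restarts,
  core-periphery restarts, all generators) takes an explicit seed,
  defaults included, and records it in its result or filename. Two runs
  with the same seed are identical.

## Problem sizes in the test suite

The suite cross-checks every binary index against an independent
reference implementation (igraph) and every bespoke definition against
brute-force loop oracles on 200 random graphs of 5–12 nodes, where
exhaustive enumeration (all 203 partitions of 6 nodes, all 64
core-periphery assignments) is feasible; stochastic properties use 20
planted-partition seeds at 20 nodes and 25 random graphs at 25 nodes for
σ. These sizes were chosen so the oracles themselves stay trivially
auditable; the implementation runs comfortably at the 165-parcel scale of
real parcellations.

## Known limitations

- Undirected, non-negative networks only; no directed variants and no
  functional-connectivity matrices with negative edges.
- Density thresholding is the only conditioning threshold flavour
  (no absolute-weight or spanning-tree schemes); already-conditioned
  matrices can of course be supplied directly.
- One matrix is analyzed at a time; group comparison is via the consensus
  builder and delta reports, not statistical inference (no permutation
  tests or network-based statistics).
- The bundled 165-parcel atlas is a Destrieux-style *template*
  (FreeSurfer cortical label set plus subcortical structures and
  brainstem, lobes assigned by name heuristics), intended as a realistic
  default and fixture, not as a clinical ground truth.
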