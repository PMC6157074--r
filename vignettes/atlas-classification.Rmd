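---
title: "Coiled-coil detection and Atlas classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coiled-coil detection and Atlas classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccatlas)
```

## The model

A coiled coil is an assembly of two or more alpha-helices held together by
knobs-into-holes (KIH) packing: a side chain on one helix (the knob) inserts
into the diamond framed by four side chains (the hole) on a partner helix.
ccatlas operationalises this geometrically. Every residue is reduced to its
side-chain centroid — the unweighted mean of its heavy side-chain atoms (CB
and beyond; glycine falls back to CA). For each ordered pair of helices and
each residue on the first, the four nearest centroids on the second are
found; if all four distances are strictly below a cutoff, a KIH interaction
is recorded.

Two parameters then turn raw interactions into a graph:

* **scut** (Angstrom) — the maximum knob-to-hole centroid distance. All
  detection runs once at a deliberately generous *collection cutoff* of
  10 Angstrom; any stricter scut is applied afterwards by filtering, so a
  whole cutoff scan costs one pass over the coordinates.
* **kcut** (count) — a helix pair counts as interacting only when its total
  number of KIH interactions, knobs in both directions summed, is strictly
  greater than kcut. At the default scut = 7.0, kcut = 2, a pair must share
  three or more interactions.

Helices become nodes, retained pairs become edges; the multigraph is
collapsed to a simple undirected graph, isolated nodes are dropped, and each
connected component — one coiled coil — is named by isomorphism against the
Atlas of simple graphs (below). Cyclic components (connected, all degrees
two) are alpha-helical barrels; the conventional barrel definition keeps
cycles of five or more helices, and smaller cycles are reported with a flag
rather than suppressed.

## Helix assignment

The classification needs maximal alpha-helical segments but no external
secondary-structure program. Residue `i` opens a helical window when the
CA(i)–CA(i+4) distance lies in 5.0–6.5 Angstrom and the virtual dihedral
over CA(i..i+3) lies in +35 to +75 degrees (the ideal helix sits near 6.2
Angstrom and +50 degrees; strands and left-handed turns fall far outside).
A maximal run of window starts `a..b` yields the segment `a..b+4`, kept when
at least `min_helix_length` (default 7) residues long. Chain continuity is
decided by consecutive CA–CA distance (4.5 Angstrom), never by residue
numbering, so insertion codes and numbering gaps are treated as identity.
A per-residue `H`/other override can be supplied instead, for parity with an
external DSSP run. Axes are least-squares lines through twice-smoothed
4-CA window midpoints (two smoothing passes shrink the off-axis residual of
the midpoint trace below 0.05 Angstrom, giving axis directions accurate to
about 1e-3 on ideal geometry); a pair is *parallel* when its axis dot
product is non-negative — perpendicular axes count as parallel by this
boundary convention.

These geometric criteria are this package's own convention: borderline
helices may differ from assignments made by other tools, which is one reason
published census numbers are not exactly reproducible here.

## The Atlas and its ordering

There are exactly 1253 isomorphism classes of simple graphs on at most
seven nodes. `enumerate_atlas()` generates them by incremental node
extension — every graph on `n` nodes arises from a graph on `n - 1` nodes
plus one new node with some neighbour subset — deduplicated by an exhaustive
canonical certificate: the lexicographically minimal adjacency bit-string
over all node permutations (5040 permutations at `n = 7`; the certificate
also yields the automorphism count as the number of permutations fixing the
bit-string). Entries are sorted by

1. node count, ascending;
2. edge count, ascending;
3. degree sequence, sorted ascending and compared lexicographically;
4. automorphism-group size, ascending;
5. the canonical certificate, as a deterministic residual tie-break.

Levels 1–4 reproduce every classically named position used here: G3 (the
dimer edge), G7 (the triangle), G16/G38/G105/G353 (the cycles C4–C7), G94
(triangle with three pendants), G163 (the six-helix bundle of viral fusion
proteins: a trimer core with each outer helix bridging two core helices),
and G1252 (the complete graph K7). The published book ordering is itself
irregular in a handful of tied positions (it occasionally violates its own
degree-sequence ordering, e.g. at positions 55/56), so no rule can reproduce
it entry-for-entry; level 5 is this package's documented convention for the
residual ties, and none of the named anchors depends on it. The generated
table ships with the package as a small JSON fixture so results are stable
across releases; `enumerate_atlas(rebuild = TRUE)` regenerates it from
scratch (about half a minute) and the test suite asserts the two agree.

The classification display subset — `connected_bounded_degree_subset()` —
keeps atlas graphs that are connected, have at least two nodes, and whose
every node has degree at most four. That convention gives exactly 461
graphs; including the single-node graph would give 462, and the count pins
the choice to exclude it.

## Isomorphism and the U-registry

`is_isomorphic()` screens node count, edge count and sorted degree
sequence, refines node labels by iterated neighbourhood-degree hashing
(1-dimensional Weisfeiler–Leman colouring), and finishes with backtracking
seeded by the label partition. For graphs of at most seven nodes the
verdict is certified against exhaustive permutation search in the tests;
the backtracking also handles the large cycles produced by many-helix
barrels (a 39-helix cycle is routine).

Components with more than seven helices fall outside the atlas and are
named on first encounter: the first becomes `U1`, and every later graph
either matches a registered one by isomorphism or opens the next category.
The registry persists as JSON when given a path, making names stable across
runs; concurrent writers are outside its contract (single process assumed).

## Exact counting

`count_graphs(n)` counts isomorphism classes without enumeration, as the
number of orbits of the symmetric group acting on 2-colourings of the
C(n, 2) node pairs: a sum over the partitions of `n` of `2^c(lambda)`
weighted by the number of permutations of each cycle type, divided by `n!`,
where `c(lambda) = sum floor(a_i / 2) + sum_{i<j} gcd(a_i, a_j)`. The
counts overflow double precision from 14 nodes, so the arithmetic runs on an
internal exact base-10000 big-integer representation; divisions are done
factor-by-factor, each partial quotient provably integral. The 17-node
count is a 27-digit integer about 408 times Avogadro's number — the reason
the atlas stops at seven nodes and larger graphs are registered on demand.
The per-size counts for 0–7 nodes double as an independent oracle for the
enumerator (two entirely different code paths must agree).

## The synthetic bundle generator

Real coiled-coil structure files are deliberately not required anywhere.
`make_bundle()` builds ideal poly-alanine helix bundles with a prescribed
interaction topology: CA atoms on an ideal helix (radius 2.3 Angstrom, rise
1.5 Angstrom per residue, 100 degrees of twist), CB placed radially at
3.83 Angstrom, one chain per helix, 25 residues (about three and a half
heptads) by default. Topology nodes are laid out in the plane with
interacting pairs at 8.6 Angstrom axis separation, each helix phased so its
side chains face the centroid of its neighbours, orientations alternating
up/down as in antiparallel coiled coils.

The spacing and CB radius are calibrated constants, frozen once against the
detector: at 8.6 Angstrom every adjacent pair across the whole fixture suite
(edge, paths, triangle, C4–C8, star, pendant topologies) yields 4–10 KIH
interactions at scut 7.0 — comfortably above kcut 2 — while every non-edge
pair yields zero at scut 7.0 and 8.0. Wider spacings fail: at 9.5 Angstrom
rotated-phase cycle neighbours drop to two interactions and fall below the
kcut threshold. Connected layouts cannot hold non-edges at arbitrarily
large distances (a cycle's diagonals are fixed by its polygon; a path's
second neighbours sit at twice the edge spacing), so the enforced floor is
1.4 times the edge spacing, which the calibration shows is already silent
territory for the detector.

What the generator does *not* emulate: supercoiling (axes are straight, not
Crick-parameterised), real rotamers (side chains are a single CB
pseudo-atom), sequence variety (poly-alanine), crystallographic noise
(coordinates are exact unless jitter is requested), and register/heptad
structure. Passing round-trip tests therefore demonstrate that the
detector, graph builder and classifier compose correctly — not that the
geometric thresholds match any particular experimental ensemble. One
sharper caveat found during calibration: for pendant topologies (`net`,
`g163`) an all-parallel orientation shifts the z-register of the pendant
interface enough to lose its interactions — a core helix cannot
phase-face two core partners and a pendant simultaneously — so orientation
invariance is asserted for the cycle fixtures (the barrel case), and the
pendant fixtures pin the calibrated alternating orientation.

## Numerical choices and degenerate inputs

* All distance comparisons are strict (`<`), at both the collection cutoff
  and scut; kcut is a strict `>` on the summed pair count.
* Ties among fourth-nearest hole candidates keep the residue earlier in
  sequence order (stable ordering, deterministic output).
* Alternate locations resolve per atom name to the highest occupancy, ties
  alphabetically by altloc; only model 1 of multi-model files is used;
  selenomethionine is treated as methionine with its selenium included in
  the centroid; other HETATM-coded residues are kept only when they carry a
  CA atom; waters are always dropped.
* Nearest-neighbour search is an exhaustive vectorised distance
  computation; the tests pin it against an independent scalar double-loop
  implementation, so a spatial index could be swapped in without changing
  any contract.
* Empty results are valid everywhere (no helices, no interactions, no
  components); errors are reserved for unreadable files, structures with no
  polymer residues, invalid parameters (negative kcut, scut above the
  collection cutoff) and unrealizable synthetic layouts.

## Problem sizes

The test and validation suites run entirely on generated inputs: bundles of
2–8 helices of 25 residues, random centroid clouds of up to ten points per
helix, 400 random graph pairs on up to six nodes checked against exhaustive
permutation search, and one full atlas regeneration (1253 classes, about
half a minute). These sizes keep the complete suite in the low minutes on a
single core while still exercising every code path end to end.

## Known limitations

* Helix assignment is a geometric convention, not a DSSP reimplementation;
  kinked helices are not split and 3-10/pi helices are not distinguished.
* The knob-type, interdigitation-depth, packing-angle and complementarity
  descriptors of classical KIH analysis are out of scope; only the
  distance-based detection that the graph classification needs is
  implemented.
* The input file is taken as the biological unit to analyse; no assembly
  generation or symmetry expansion is attempted.
* Hole residues are exactly the four nearest centroids, with no
  sequence-locality requirement — the literal reading of the detection
  rule; older implementations may have applied additional hole-geometry
  checks, so borderline interactions can differ.

## A worked example

```{r example, eval = FALSE}
b <- make_bundle("C6")                  # antiparallel hexameric barrel
comp <- classify_structure(b$structure) # scut 7.0, kcut 2
comp$components
#>   name n_helices n_edges     helices
#>   G105         6       6 0+1+2+3+4+5
find_barrels(comp)$n_helices
#> [1] 6
```
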