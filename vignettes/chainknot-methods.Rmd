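---
title: "chainknot: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chainknot: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A knotted protein, RNA or chromatin model is hard to recognise by eye: the
entanglement is buried in hundreds of residues.  `chainknot` reduces an
open chain of backbone beads to the minimal number of points that preserve
its topology — with the termini pinned in place — and then names the knot
from the reduced chain's planar diagram.  Because an open chain is not a
closed curve, the package works in the implicit-closure setting: the
smoothing tightens the entanglement and improves the protrusion of the
ends, after which a closure that adds no crossing exists, and the
Dowker-Thistlethwaite numbering can simply wrap around.  Every result is
deterministic for a given input — no random closures, no probabilities.

## Smoothing model

The state is a list of chains, each an ordered bead sequence (Angstrom
coordinates).  One *pass* treats the chains round-robin; while one chain
moves, every other chain is a frozen obstacle.  For the active chain each
interior bead is evaluated against the frozen configuration:

* **deletion** — bead $i$ is removable when the triangle
  $(i-1,\,i,\,i+1)$ is pierced by no non-adjacent segment of any chain;
* **displacement** — otherwise the bead proposes moving toward the
  midpoint of its neighbours; the two triangles swept by the displacement,
  $(i-1,\,i_{old},\,i_{new})$ and $(i_{old},\,i_{new},\,i+1)$, must both
  be unpierced.  The full midpoint step is tried first, then halved
  fractions down to $1/8$; the largest admissible step wins.  The
  fractional fallback matters in crowded conformations where the full
  step is blocked but the chain is far from its fixed point.

Within a pass, deletions are iterated to a fixed point before a single
displacement round, so a straight run of beads disappears at once.

### Why the accepted moves commute

A simultaneous batch of moves could, in principle, let two strands pass
through each other even if each move is individually safe.  The engine
prevents this by construction:

1. proposals are evaluated against the *frozen* configuration;
2. a pairwise non-adjacent subset is selected (no two moving beads are
   chain neighbours), ordered by a reversal-invariant priority — distance
   to the nearest fixed end, ties broken by the bead's coordinates;
3. each selected action is re-guarded against the union of *pre- and
   post-action* segments of every other selected action.

Step 3 makes the batch order-free: applying the survivors in any sequence
keeps every intermediate segment inside a set the guards already cleared,
so no ordering can produce a strand passage.  Order-freeness is also what
makes the whole trajectory invariant under chain reversal, bit for bit:
no step of the algorithm references the traversal direction (the midpoint,
the triangles, the priority and the guards are all direction-symmetric).
This orientation independence is forced whenever a single chain is
smoothed.

Bulk passes repeat as long as they make progress into configurations not
seen before (coordinates compared on a $10^{-4}$ Å grid,
direction-canonicalised).  When the bulk dynamics stalls or cycles, the
engine takes bounded *novelty steps*: the single highest-priority guarded
action — drawn from an escalating repertoire of targets (fractional
contractions, the perpendicular foot on the neighbour chord, rotational
side-steps about that chord, and bounded expansions away from it) — whose
resulting configuration is genuinely new.  The visited set itself rules
out cycles, and every target is confined to a ball around the input
structure (twice the bounding-box half-diagonal), so exploration can
never blow the geometry up to a scale where later contractions could
slip a strand around the fixed termini.  In multi-chain systems the
implicit closure chords are additional obstacles for exploration moves,
so a chain cannot slip out of a link through a terminus gap.  The run
ends when no admissible action leads anywhere new, the novelty budget
(60 steps) is exhausted, or an iteration cap (`10 ×` bead count) is
reached — an unconverged result is flagged, reduced and returned, never
silently truncated.  A final deletion-only sweep (`reduce_beads`)
removes any remaining superfluous beads; surviving beads keep their
coordinates.  The trajectory records the input, one frame per accepted
round, and the reduced system; termini are identical in every frame.

A dense self-avoiding walk whose termini are buried deep in the coil is
the hardest input: its implied closure is genuinely ambiguous until the
ends work free, and for a small fraction of such chains (about 3% in
internal sweeps at 50-500 beads) the exploration budget ends above two
beads.  Such a result is reported honestly by its bead count; the
certified generator seeds shipped with the test suite all reduce fully.

### The piercing guard

The kernel predicate is conservative: a segment pierces a triangle when it
properly crosses the interior *or* approaches the closed triangle within
`eps` (default $10^{-9}$ Å; PDB data carries $10^{-3}$ Å, leaving six
orders of slack).  A doubtful move is refused — the smoother can only
under-move, never change topology.  The triangle's own side segments are
excluded; a segment sharing one vertex with the triangle is tested with a
$10^{-4}$ Å neighbourhood of the shared vertex trimmed away, because such
a neighbour may genuinely thread the triangle interior away from the
shared point (skipping it entirely would be unsound).  Degenerate
(zero-area) triangles are handled as their edge hull.

## Diagram and code

`choose_projection` scans a deterministic candidate list (identity, then a
golden-angle spiral of viewing directions) for a *generic* projection: no
near-parallel overlaps, no crossing within tolerance of another crossing
or of a bead image, every crossing pairing an odd and an even passage, and
both termini able to reach the outside of the drawing along their outward
rays — the operational test that the implicit closure adds no crossing.
Crossings are enumerated (vectorised over all segment pairs), over/under
is decided by projection depth, and each crossing stores its local
handedness, which fixes the rotation system of the diagram.

The DT code lists, for odd passage labels $1, 3, 5, \dots$, the paired
even label, negated when the even passage runs over (a pinned convention;
the tabulation collapses mirror images, but the signed code is reported
for direction-aware use).  `validate_dt` checks the even-permutation
syntax and, up to 12 crossings, realizability as a closed curve by
searching for a handedness assignment whose traced faces satisfy Euler's
formula.

## Reidemeister calculus

Simplification operates on the combinatorial map (passage sequence,
over/under flags, per-crossing handedness).  Faces are traced from the
rotation system; the moves are face-anchored, hence always genuine:

* **R1** removes a crossing bounding a monogon face;
* **R2** removes the two crossings of a bigon face when one strand is
  over at both;
* **R3** flips a trigon face when one strand crosses the other two
  uniformly (over both or under both); combinatorially the flip swaps the
  passage pair across each of the three face edges.

Greedy R1/R2 run to a fixed point; when stuck, a bounded breadth-first
search through R3 flips looks for a state where a reduction unlocks.  The
final code is canonicalised over all cyclic relabelings, traversal
reversals and mirror reflection.  The determinant $|\Delta(-1)|$ — exposed
as `knot_determinant` and computed from the Alexander matrix at $t=-1$ —
is the independent invariant used throughout the test suite to certify
that every move and every smoothing frame preserves topology; it is never
consulted on the production path.

## The knot table

`classify_knot` looks the canonical code up in a packaged table of prime
knots through 8 crossings.  Every entry was verified against the
determinant oracle, and the 5-8 crossing entries were additionally
cross-checked by exhaustively enumerating all realizable prime reduced
alternating shadows at each crossing number, identifying names by
determinant uniqueness within a crossing number, by the writhe invariance
of reduced alternating diagrams, and by amphichirality where two knots
share a determinant.  Several knots admit more than one flype class of
minimal diagrams; all classes are keyed.  Two non-alternating 8-crossing
knots (8_20, 8_21) have no verified code in the table and classify as
`unknown_8` — an honest failure is preferred to a wrong name.  Composite
codes are likewise absent by design: composites are factored through the
subentanglement scan instead.

## Slipknots, composites, links

* `smooth_subchain` pins a residue range; only its interior moves, the
  flanks act as obstacles.  A slipknot shows up as: full chain reduces to
  two beads, the subchain does not and classifies as a knot.
* `find_subentanglements` scans contiguous ranges of the reduced chain,
  shortest first, keeping ranges that stay irreducible in isolation.
  Accepted ranges have disjoint interiors but may share an endpoint: on a
  fully reduced connected sum the two factor cores meet at a single
  junction bead, which strict disjointness could not represent.
* `detect_links` counts inter-chain crossings of the jointly smoothed
  pair over several generic projections, keeping the minimum, after
  cancelling provably-empty inter-chain bigons (two crossings consecutive
  with respect to *every* passage on both chains, one chain over at both
  — any strand inside such a bigon would have to cross its boundary,
  which the adjacency condition excludes).  Chains are implicitly closed
  by the last-to-first chord so an open ring's terminus gap does not read
  as an escape route; exactly straight chains (no generic closed
  projection exists) fall back to open counting, which is sound because a
  straight chain threads nothing.  A pair is linked at two or more
  residual crossings; the Gauss linking integral (`gauss_linking`,
  evaluated in closed form per segment pair) is the oracle in tests.

## Synthetic fixtures

`make_chain` provides the ground-truth generators the whole test suite
builds on: open $(2,q)$ torus curves (40 beads per crossing keeps generic
projections well separated), the parametric figure-eight, a certified
minimal-stick trefoil hexagon, a twist-knot representative for $6_1$
certified through the full pipeline, a slipknot (an open trefoil whose
final arc retraces back through the loop, radially offset), composites
(factors rotated to face their connector, joined through empty space),
helices with an incommensurate 12.37 beads per turn, planar zigzags,
seeded self-avoiding walks certified trivial by the determinant before
being emitted, and threaded/stacked open ring pairs.  Sampled parametric
curves receive a deterministic $10^{-2}$ Å jitter: exact trigonometric
sampling otherwise creates exact affine coincidences (segments meeting in
3D, projections degenerate in every view).  These fixtures are
topological, not biophysical: they exercise the geometry and the
invariants, and say nothing about force fields, solvent, or experimental
coordinate error beyond the PDB-precision tolerances above.

What passing them shows: the guard never allows a strand passage, trivial
chains of every tested family collapse to their end points, and the
classifier recovers the forced knot types.  What they cannot show:
behaviour on chains with large gaps (the reader warns on suspicious
virtual bonds instead of guessing) and naming beyond 8 crossings
(`unknown_n`).

## Numerical and interface choices

* Tolerances: piercing `eps` $10^{-9}$ Å; point identity $10^{-6}$ Å;
  configuration grid and minimal displacement $10^{-4}$ Å; projection
  degeneracy $10^{-7}$ with a $10^{-4}$ parameter-space margin at segment
  ends.
* Altloc: highest occupancy wins, ties to the lexicographically smallest
  id.  Multi-model files: model 1, with a notice.  HETATM beads join the
  trace only when their residue number links into the polymer numbering.
  A consecutive-bead distance above twice the typical virtual bond
  (15.2 Å for CA) triggers a gap warning — a gap can silently untie a
  structure, so the tool warns rather than guesses.
* Problem sizes in the shipped suites — 50 trivial chains of 50-500
  beads, fixtures of 100-280 beads, 200+ conservation frames — were
  chosen as the smallest sets that exercise every code path with clear
  statistics.
* The command line tool prints the reduced backbone as PDB (multi-MODEL
  for trajectories); `-k` appends AB notation, the simplified DT code and
  link lines; `--json` adds a machine-readable sidecar (an extension).

## Known limitations

* Chirality is not resolved: the table collapses mirror images, as the
  signed DT code alone is reported for direction-aware users.
* The implicit-closure reading requires the smoothed termini to protrude;
  for pathological inputs whose termini stay buried, open-chain topology
  is genuinely ambiguous and the per-frame determinant certification is
  only meaningful for fixtures with unambiguous closure.
* `unknown_n` labels beyond the table are honest but uninformative; the
  raw minimal DT code is always reported alongside.
* Re-running the smoother on an already reduced knot is stable at the
  level of invariants (bead-count scale, determinant, name) but not bit
  for bit: the exploration endgame walks relative to a per-run visited
  set, so a fresh run may wiggle a reduced knot before stopping.  A
  trivial chain's two end points are a true fixed point.
* Smoothing is geometric, not physical: no energies, no ensembles.
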