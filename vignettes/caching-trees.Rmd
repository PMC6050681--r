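---
title: "Oak, Pine and withering: multiscale caching for track display"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oak, Pine and withering: multiscale caching for track display}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oakpine)
```

## The problem

A genome browser shows a window of a chromosome at screen resolution.
Three facts make naive data handling wasteful: only the data inside the
window are needed; successive windows overlap heavily (shifts, zooms);
and a screen of `w` pixels cannot display more than `w` distinct
columns, so dense signal only needs to be transferred at about
`view length / w` bases per pixel. `oakpine` implements a client-side
cache built around those three facts: fetch only the queried region,
reuse everything already fetched, and fetch dense data only at the
resolution the screen can show. An in-process backend stands in for the
remote track server and meters every simulated transfer in a ledger
(logical records and bases, never bytes, so the accounting is
hardware-independent), which is what lets the test suite *prove* the
reuse properties rather than assume them.

Coordinates are 0-based half-open throughout (the BED convention);
rendering converts to 1-based labels only when drawing axis text.
Zero-length intervals are rejected at parse time rather than silently
widened. Strand is carried but never used for tree placement.

## Oak: the sparse-record cache

Sparse tracks (BED: peaks, genes, interaction anchors) are cached per
chromosome in an Oak. Its leaf fringe is a sequence of *keys* — half-open
coordinate pairs — that partitions the entire chromosome exactly. A data
key holds two lists: records whose start equals the key's left
coordinate (the start list) and records that span across that left
coordinate (the span list), so every key answers overlap queries for its
own span without consulting neighbours. Genome outside the loaded
regions is covered by *placeholder* keys, one per maximal unloaded gap.
A record spanning several keys is stored in each of their span lists and
deduplicated at retrieval by full-field identity
(chrom, start, end, name, score, strand, trailing columns); two
byte-identical BED rows are treated as one record, i.e. the cache treats
the file as a set.

Above the fringe sits a binary weight-balanced branch structure under
the classic BB[α] criterion with α = 0.292: at every branch,
`min(w_left, w_right) >= α · (w_left + w_right)` where weights count
leaves. We rebuild the branch structure from the fringe on every
structural change (a whole-tree rank rebuild by recursive median split)
rather than rebuilding locally at the topmost violating node; at
session scale (hundreds to thousands of keys) the global rebuild is
both simpler and faster than bookkeeping for local rebuilds, and a
median-split tree satisfies BB[0.292] by construction.
`check_weight_balance()` evaluates the criterion directly, and
`oak_build(..., balance = FALSE)` builds a degenerate left-deep chain so
tests can confirm the checker rejects unbalanced shapes.

Two representation choices deserve a note:

* **The fringe is a pure function of state.** The cache state is the
  loaded interval set plus the deduplicated record table; the key
  layout (boundaries at record starts inside loaded segments, gaps as
  placeholders) is recomputed from that state after every update or
  eviction. Because the backend returns every record overlapping a
  fetched region, any record re-entering view after a partial eviction
  is re-supplied by the fetch and deduplicated against the table, so
  rebuild-from-state and incremental editing give identical structures.
* **Life spans live on fringe keys.** A branch's span is the union of
  its children's, so a branch overlaps a query exactly when some
  descendant leaf does; ticking every node (as the eviction rule is
  stated) and deriving branch life as the maximum over descendant
  leaves are therefore the same function. We store the per-leaf number
  only.

Oak performs no coarsening on zoom-out: a wide view over a sparse track
returns all overlapping records, and any per-pixel capping is a concern
of the render layer. The structure defines no summarization operator,
so granularity adjustment is deliberately left to Pine-managed tracks.

## Pine: the multiscale signal cache

Dense tracks (bedGraph here; the piecewise-constant text dialect plays
the role a binary bigWig plays in production, behind the same
region-to-summary contract) are cached in a Pine: a fixed-branching
tree whose root spans the chromosome. The depth is set by the viewing
resolution `r = view length / pixel width`:

```
depth = ceiling( log_n(chromosome length) − log_n(r) )
```

with `n = 20` children per partition. Two numerical guards matter. An
epsilon (`1e-9`) inside the ceiling keeps exact powers of `n` from
rounding up a level (the floating log of `20^3/1` is not exactly `3`).
And the depth is floored at 1 because the formula yields zero or
negative values for whole-chromosome views; a one-level tree keeps the
load path uniform. `pine_depth()` is checked against an
exact-arithmetic oracle (smallest `d` with
`n^d · view ≥ L · pixels`, evaluated in integers) over random views.

Partitioning is "equal with indivisible remainders": child `k` of a
node of length `len` spans `[floor(k·len/n), floor((k+1)·len/n))`, which
tiles any length exactly. When `len < n` this yields fewer than `n`
children (one per base); zero-width child slots are not materialised.
The 20-way split is therefore exact on spans of at least `n` bases and
degrades gracefully to base resolution below that.

Every node carries the five-metric summary — covered bases, sum of
per-base values, sum of squares, maximum, minimum — over the data-covered
bases of its span (gap bases contribute nothing, matching the "valid
bases" semantics of bigWig summaries). Summaries merge by componentwise
addition (extremes by max/min) with the empty summary as identity, so a
parent's summary equals the merge of its children's. The sum of squares
is carried through the whole pipeline for variance-style displays but is
not used by the default renderer, which draws the per-pixel **mean**
(max and min are kept alongside for envelope display).

Structure building expands only lineages overlapping the query; children
that do not overlap are placeholders (empty key list, empty summary).
Loading fetches summaries for the target-depth nodes in the query and
aggregates upward. On a new query the tree extends to
`max(old depth, new depth)`, placeholder lineages overlapping the query
are partitioned, and summaries are fetched **only** for target-depth
nodes that lack one. Filling a node reuses whatever its subtree already
holds: children with summaries are merged, and only placeholder child
spans are fetched, so zooming out over a partially explored window
re-fetches nothing that was transferred before, and conservation
(node = merge of children) holds at every summary-bearing node with
children. When the new depth is smaller than the current depth the tree
is never pruned — withering, not zooming, is the only eviction path.

Per-pixel profiles merge the summaries of the depth-appropriate nodes
overlapping each pixel span. Node spans at the chosen depth are at most
one resolution unit wide, but they need not align with pixel
boundaries; a node straddling two pixels contributes to both. This is a
deliberate display approximation — exact when spans nest inside pixels
(as in the aligned test scenarios) and visually indistinguishable
otherwise. Pixels whose spans carry no covered bases get an explicit gap
marker rather than a zero.

## The session engine and withering

A session owns one tree per (track, chromosome), a global query counter,
and the backend handle. Each query computes the uncovered sub-regions of
the viewport with `subtract_covered()` (plain half-open sweep
arithmetic, cross-checked in the tests against both a per-base brute
force and IRanges), fetches exactly those, updates the tree, and reads
the payload from the cache — never from the files.

Interaction tracks (paired intervals with an intensity) are served with
the same machinery: a record is fetched when either anchor overlaps a
requested viewport, and the session keeps two Oaks per chromosome for
such a track, one keyed by each anchor, so repeated double-layer queries
hit the cache like any other track.

After the payload is assembled, one *withering* tick ages the cache:
every node overlapping the query region (and hence all its ancestors)
has its life span reset to 10; every other node loses 1; nodes reaching
0 are replaced by placeholders, their data leave the loaded set, and a
later query over that span re-fetches it. A node untouched for ten
consecutive queries therefore dies on exactly the tenth tick. Two scope
decisions: the tick applies to trees on the queried chromosome(s) only —
decrementing idle chromosomes would silently evict them wholesale after
ten unrelated queries — and the query counter is per session, not per
track. Oak placeholder replacement merges adjacent placeholder keys and
re-balances, preserving the fringe partition invariant. The record
table backing an Oak is not garbage-collected when keys wither (the
loaded set alone decides what is served and refetched); a long-lived
session could reclaim it by rebuilding the tree, which the design
leaves to the caller.

## Rendering

`render_tracks()` is a pure function of payload and layout: a
coordinate ruler (1-based labels), sparse records as boxes with names
where space allows, dense profiles as per-pixel mean bars, and
interaction tracks as a double-layer panel. The panel plots two
independently scaled axes (anchor 1 on top by default, a flag swaps
them); every record whose top anchor is visible on the top axis and
bottom anchor on the bottom axis becomes a straight-edged quadrilateral
from the top span to the bottom span — no invented curvature — filled on
a linear green-to-red RGB ramp, green weakest, red strongest. Intensity
bounds default to the range of the visible records and can be fixed in
the layout; degenerate bounds map to the midpoint colour. All numbers
in the SVG are printed with fixed two-decimal formatting, so identical
input yields byte-identical output.

## Synthetic data: what it covers and what it does not

The generator (`fixture_spec()` / `gen_tracks()`) emulates a compact
browsing scenario: three 5 kb chromosomes; ~500 sparse records with
geometric lengths (mean 80 bp, peak-like); ~200 disjoint signal
segments with log-normal values (meanlog 0, sdlog 1) separated by gaps,
built from sorted random breakpoints so disjointness holds by
construction; and ~100 interactions, 70% intra-chromosomal, anchors
20–60 bp, log-normal intensities. Sub-seeds are derived per track kind,
so adding one kind never perturbs another's files, and the same spec and
seed give byte-identical output. The random browsing traces mix
half-view shifts, 4× zooms and jumps across chromosomes.

These fixtures exercise every structural path — partial overlap, gaps,
chromosome edges, cross-chromosome pairs, eviction and re-fetch — but
they are small and uniform compared with real data: no megabase
chromosomes, no heavy-tailed record clustering, no bigWig binaries.
Passing tests therefore demonstrate the correctness of the caching
semantics, not production-scale throughput.

## Verification strategy and problem sizes

Every cache answer has an independent brute-force counterpart computed
directly from the parsed files: overlap scans for sparse and
interaction tracks, and base-exact span summaries assembled on the same
depth grid for profiles (the grid arithmetic is shared; what the
equivalence test exercises is the caching, reuse and eviction logic,
while the grid itself is pinned by hand-computed cases). The shipped
test suite replays 200-step random traces over three tracks and checks
every payload against the oracle, audits the transfer ledger for
zero-delta repeats, exact set-difference shifts and single-level
zoom-in fetches, verifies BB[α] balance after every step, checks
conservation at 1e-9 relative tolerance, and compares `pine_depth`
against the exact oracle on 10,000 random views. Those sizes keep the
whole suite in a few minutes while covering every operation path; the
structures themselves have no intrinsic size limits beyond R numerics
(coordinates are doubles, exact up to 2^53).

## Known limitations

* Oak-managed tracks have no granularity adjustment on zoom-out by
  design; very wide views over very dense sparse tracks return many
  records.
* Per-pixel profile values are approximate where node spans straddle
  pixel boundaries (see above).
* The backend is in-process and single-session; there is no wire
  format, concurrency contract, or cross-session shared cache.
* bigWig files are not read directly; convert to bedGraph text first.
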