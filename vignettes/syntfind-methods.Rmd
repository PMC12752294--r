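---
title: "Minimizer-graph multi-genome synteny detection: methods and design"
author: "syntfind maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-graph multi-genome synteny detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Macrosynteny analysis asks which large-scale segments of two or more genome
assemblies are conserved — same content, same order, same orientation —
while tolerating small internal differences. Alignment-based approaches
scale poorly beyond pairwise comparisons; `syntfind` instead maps all input
genomes onto one another simultaneously through *minimizer sketches*,
producing one set of blocks in which every block has exactly one oriented
interval per genome.

# The method

## Common k-mer Bloom filter

The sketches of different genomes are only comparable if they are built
from k-mers all genomes share. A cascade of Bloom filters captures this
intersection cheaply: level 1 receives every canonical k-mer of genome 1;
level *i* receives the k-mers of genome *i* that query positive in level
*i − 1*; the final level approximates the n-genome intersection. Each level
is sized as

$$\mathrm{bfsize} = \left\lceil \frac{-\,\mathrm{genome\_size}}
{\ln(1-\mathrm{fpr})} \right\rceil$$

bits, with `genome_size` the largest total assembly length and `fpr` the
target false-positive rate (default 0.025). This is the single-hash sizing
formula, so the default hash count is 1 (configurable). Only two levels are
resident in memory at any time. Bloom filters have no false negatives, so
the true intersection is always preserved; false positives add occasional
genome-private minimizers that downstream intersection steps remove.
K-mers containing any non-ACGT symbol are never inserted and never match:
assembly gaps must not manufacture shared k-mers.

Hashing is canonical (strand-invariant): the hash of a k-mer equals the
hash of its reverse complement, implemented as the minimum of a rotate-xor
hash of the forward k-mer and of its reverse complement, with fixed
published per-base seed constants. Sketch entries are *reported* under a
second hash (a splitmix64 finalizer of the canonical hash), decorrelating
selection order from node identity.

## Bloom-filter-restricted minimizer sketches

For each contig, a window of `w` consecutive k-mer start positions slides
along the sequence (defaults `k = 24`, `w = 1000`; the window therefore
spans `w + k − 1` bases). Within a window, only k-mers present in the
common filter are candidates, and the candidate with the smallest canonical
hash is the window's minimizer; a new sketch entry is emitted only when the
selected *occurrence* changes. Two deliberate conventions:

* ties on the minimal hash go to the leftmost occurrence (deterministic);
* deduplication is by occurrence `(hash, pos)`, not by hash value, because
  downstream adjacency is positional.

A sequence holding fewer than `w` k-mers forms a single window; windows
with no eligible k-mer contribute nothing.

## The minimizer graph

Only hashes found in **all** genomes and **unique within each** genome
become nodes. For every genome, consecutive retained minimizers on the same
contig contribute an undirected edge; the edge weight is the number of
supporting genomes (`1 … n`).

Simplification removes "noisy" nodes that disrupt linear paths. Nodes are
*fully anchored* (degree 2, incident weight sum `2n`), *partially anchored*
(degree 3 with an incident weight-`n` edge — read as *at least one* such
edge; the defining description is ambiguous on exactly-one), or
*unanchored*. For an edge `(u, v)` between two partially anchored nodes
with an alternate length-two path `(u, z, v)`, every such `z` is removed
and `weight(u, v)` is promoted to `n`. Candidate edges are scanned in
ascending `(min(hash), max(hash))` order with immediate effect, which makes
the outcome deterministic; a single pass is the default (`iterateSimplify`
re-scans to a fixpoint, which on all constructed fixtures changes nothing —
the single pass is idempotent there). After simplification every edge with
weight below `n` is dropped, then isolated nodes.

Connected components that are simple paths (degrees ≤ 2, acyclic) become
candidate blocks. The filtering rules do *not* guarantee maximum degree 2,
so residual branched or cyclic components can survive; they are counted,
warned about, and conservatively dropped rather than traversed greedily.

## From paths to blocks

Paths are first split at any edge whose endpoint minimizers sit on
different contigs in any genome. Per genome, the block orientation is `+`
(`−`) when at least 90% of consecutive position steps increase (decrease);
otherwise the path is unorientable and rejected (counted in the run
report). The fraction is computed over consecutive node pairs, not all
pairs. Because a path has no intrinsic direction, orientation is
normalized so the first (reference) genome reads `+`. Coordinates are
0-based half-open: `start` = smaller terminal k-mer start, `end` = larger
terminal k-mer start + `k` — a BED-like convention.

Large insertions or deletions are detected through the *indel score* of an
edge: per genome, the interarrival distance `|pos_u − pos_v|`; the score is
`max − min` of the interarrivals across genomes. Edges scoring above the
`indel` threshold are removed and remembered: the recorded pair later
(a) blocks any merge across it and (b) labels the discontinuity `indel`.
Re-scoring the gap at merge time is not possible — the removed edge has no
shared minimizers left — hence provenance, not re-scoring.

## Multi-round refinement (`wRounds`)

Block termini at window size `w` stop up to roughly one window short of
the true discontinuity. Each refinement round recomputes minimizers at a
smaller window over only the regions not covered by current blocks (same
k, same common filter; coordinates lifted back to contig space) and merges
them into the active minimizer universe. Two rules keep this stable:

* a new occurrence whose hash already belongs to a retained path node is
  dropped — the established occurrence wins;
* shared-unique selection is re-evaluated within the active universe
  (round-1 multiplicities at `w` say nothing about the denser sketch).

Graph construction, simplification, filtering, contig- and indel-breaking
are re-run over the extended universe. New minimizers appear only in
uncovered regions, so within-block adjacencies are untouched and the
effect is exactly extension of existing paths at their termini, in both
directions. Recorded indel breaks persist across rounds. Coverage is
asserted non-decreasing over rounds on every fixture. Refinement is most
visible around breakpoints flanked by diverged sequence, where the round-1
terminus sits far from the junction.

## Size filter, merging, reasons

After the final round, blocks whose *minimum* extent length across genomes
is not strictly greater than `blockSize` are dropped (strict inequality:
exactly-threshold blocks go). Blocks consecutive in the reference ordering
(first genome's contig, start) merge when in *every* genome they lie on
the same contig and strand, are adjacent in that genome's own block
ordering (no third block between them — the operationalization of
"consistent positions"), follow each other in strand order, sit at most
`merge` bases apart, and are not separated by a recorded indel break.
Terminal k-mers of abutting blocks may overlap by up to `k − 1` bases, so
gaps down to `−(k−1)` still count as order-consistent. Merging is applied
once at the end by default (`mergePerRound` adds per-round merging; the
final output is unchanged on all fixtures tried, so the cheaper default
stands). Merged extents span both parts and minimizer counts add.

Between consecutive output blocks the discontinuity reason is the first
applicable of `contig` > `strand` > `indel` > `position` >
`merge-distance` (a deliberate precedence — the underlying causes are not
mutually exclusive); the final block carries `none`. In the serialized
TSV the reason sits on the last row of each block.

## Parameters

| parameter   | default | unit  | role |
|-------------|--------:|-------|------|
| `k`         | 24      | bases | k-mer length; smaller k = more sensitivity at divergence |
| `w`         | 1000    | k-mer starts | sketch density; boundary resolution ~ half a window |
| `fpr`       | 0.025   | —     | Bloom filter false-positive rate per level |
| `indel`     | preset  | bases | maximum tolerated interarrival spread |
| `merge`     | 100000  | bases | maximum gap bridged when merging collinear blocks |
| `blockSize` | 10000   | bases | strict minimum block size |
| `wRounds`   | `w/2, w/10` | k-mer starts | decreasing refinement windows |

The divergence presets pick `indel` = 50 kbp below 2.5% divergence,
100 kbp from 2.5–10%, and 500 kbp above 10%, mirroring published
invocations at divergences 1.7, 7.1 and 18.8%; any explicit setting
overrides its preset. Raising `merge`/`indel` yields broader, more
contiguous blocks; lowering them yields a more granular picture.

# The simulator and what it does (not) emulate

`simulateGenome` draws i.i.d. bases at a target GC. `applyRearrangements`
plants non-overlapping inversions, deletions, insertions (novel random
sequence) and translocations (segment moved to another contig), placed
uniformly with rejection sampling; the default spec is 2 translocations of
10–50 kbp, 20 inversions of 10–50 kbp, and 20 large indels of 50–100 kbp
split evenly between insertions and deletions — the published simulation
design — and desk-scale fixtures pass explicitly scaled-down counts.
`applyPointVariants` substitutes each base independently (SNV rate) and
plants 1–10 bp indels (uniform length) at the small-indel rate; small
indels shift coordinates, so the ground-truth lift map is only used on
fixtures without them.

The truth object stores a piecewise segment map between original and
rearranged coordinates (a bijection outside inserted/deleted bases).
Evaluation statistics: *synteny coverage* = mean per-genome summed block
length over the smallest genome length (it can exceed 1 when the smallest
genome lost sequence to deletions); *block NG50* = largest L such that
blocks ≥ L cover half the genome, reported as missing below 50% coverage;
*block accuracy* = fraction of blocks whose per-genome extents, lifted to
original coordinates, agree in contig, orientation, and boundaries within
a tolerance. Lifted pieces no longer than the tolerance are treated as
boundary slop (a terminal k-mer can coincidentally match across an event
junction and overhang it by up to `k − 1` bases); agreement is only ever
asserted to within the tolerance. The accuracy matching rule is this
package's own operationalization, with tolerance an explicit parameter.

I.i.d. genomes contain no repeats, no compositional bias and no
centromeres; real assemblies lose most coverage in exactly such regions.
Passing tests on these fixtures therefore validates the algorithmic
contracts (no false negatives in the filter, exact window selection, graph
rules, breakpoint resolution, coordinate bookkeeping), not the empirical
coverage levels reachable on real genomes.

A consequence worth stating explicitly: with identical coordinates (SNVs
only, no indels), the retained shared-unique minimizers keep identical
order in every genome, all edges reach weight `n`, and blocks simply
bridge diverged islands — substitution-only divergence does not fragment
blocks. Fixtures that exercise refinement or coverage loss therefore
include coordinate-changing events (a deletion inside the diverged island
of the refinement fixture; rearrangements plus small indels in the trend
fixture).

# Numerical and fixture choices

* 64-bit hashes cross into R as fixed-width hex strings (lexicographic
  order = numeric order); R doubles cannot hold 64-bit integers.
* Window minimum uses a monotone deque (O(n)); the test oracles recompute
  per-window argmins by direct scan and by an independent block
  prefix/suffix cumulative-minimum construction.
* Problem sizes in the tests and acceptance script — 1 Mbp identity pairs,
  a 5 Mbp rearrangement fixture, five 2 Mbp genomes, 1 Mbp divergence-trend
  pairs over four rates — are the package's chosen desk-scale study
  conditions; they keep every documented contract measurable in minutes on
  one CPU.
* The divergence-trend fixture uses `k = 48`: on uniform-random Mbp-scale
  pairs at ≤ 5.5% divergence, `k = 24` leaves shared k-mers so dense that
  coverage barely responds to the variant rate (the published declines are
  dominated by repeat-rich regions absent from i.i.d. sequence). A longer
  k-mer makes sketch density — and hence breakpoint-flank coverage —
  respond to divergence through the same mechanism the method documents
  (sensitivity scales inversely with k), so the qualitative trend is
  measurable at this scale.
* The translocation destination avoids the source contig whenever the
  genome has more than one contig, giving the junction its `contig`
  discontinuity signature.

# Known limitations

* Duplications are invisible by construction: a duplicated minimizer fails
  the uniqueness test and leaves the graph.
* Highly diverged genomes thin the common filter; coverage declines, and
  smaller `k` is the documented mitigation.
* Residual non-path components are dropped, trading a little recall for
  never emitting an ambiguous traversal.
* The simulator's event placement is uniform-with-rejection; it does not
  reproduce any external simulator's placement model bit-for-bit.
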