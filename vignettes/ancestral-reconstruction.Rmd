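---
title: "Reconstructing ancestral genomes with local DCJ similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral genomes with local DCJ similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancar)
```

## The problem

Ancestral genome reconstruction asks two questions about an extinct genome:
what was in it (the *content* — how many members of each marker family), and
how was it laid out (the *architecture* — the order of markers along
chromosomes). Both are hard in plants, where repeated rounds of whole-genome
duplication (WGD) and triplication (WGT) followed by *fractionation* (random
loss of redundant copies) leave every extant genome a scrambled mosaic of
partial copies of its ancestor.

`ancar` implements a rearrangement-aware, synteny-based reconstruction
workflow. Its stages, each usable on its own:

1. **Segmentation** (`segment()`, `assign_families()`): cut genome sequences
   into *atoms* — alignment-boundary-consistent segments of a minimum length
   — grouped into families; this replaces gene annotations as the source of
   markers.
2. **Synteny** (`discover_blocks()`): find reference-based approximate
   common intervals across the marker sequences, tolerating bounded numbers
   of inserted and missing markers.
3. **Local DCJ similarity** (`local_dcj_similarity()`): score how coherently
   each occurrence of a block can be rearranged into the reference
   occurrence — the package's core measure.
4. **Family refinement** (`refine_families()`): split marker families into
   positional sub-families using the one-to-one assignments of step 3.
5. **CAR assembly** (`reconstruct_cars()`): greedily insert weighted
   candidate intervals into a PQ-tree and read off contiguous ancestral
   regions (CARs).

A polyploidy-aware simulator (`simulate_dataset()`) generates datasets with
known ground truth so every stage is testable without external data.

## The DCJ model and its local similarity

A non-duplicated genome is a set of *adjacencies* between marker extremities
(each marker `g` has a tail `g^t` and head `g^h`; telomeres are singleton
adjacencies). The *adjacency graph* of two balanced genomes decomposes into
cycles and paths, and the classic double-cut-and-join (DCJ) distance over
`n` markers is `n - c - o/2` with `c` cycles and `o` odd paths
(`dcj_distance()`; `dcj_distance_search()` is an exhaustive BFS used as an
independent check).

A *distance* is the wrong instrument for comparing syntenic substrings: it
favors trivially short (even empty) substring pairs. The local similarity
instead rewards structure and penalizes losses. For substrings `S`, `T`:

1. Choose subsequences realizing the maximal balanced content — family `g`
   is matched `min(m_S(g), m_T(g))` times (`balanced_content()`).
2. Choose a per-family one-to-one assignment of occurrences; relabelling
   matched pairs with unique ids yields a non-duplicated balanced pair
   `S''`, `T''`.
3. Score
   `s = sum_C f(|C|) + 1/2 (sum_O f(|O|+1) + sum_E f(|E|+2)) - d p`
   over cycles, odd and even paths of the adjacency graph of `S''`, `T''`,
   where `d` is the number of unmatched (deleted) markers. Path lengths are
   corrected by +1/+2 so structures with equal sorting distance have equal
   length.
4. Maximize over all choices in 1–2.

The component reward is linear: `f(l) = (2 - l)/(L - 2) + 1`, so the
shortest structures score `f(2) = 1`, structures of length `L` score zero,
and longer ones score negative. Defaults are `p = 0.25` and `L = 8`:
deletion is cheap enough that diverged occurrences still match where they
can, and only cycles shorter than 8 count as positive evidence.

```{r}
local_dcj_similarity(c(1, 2, 3), c(1, -2, 3))$score  # one inversion: 5/3
local_dcj_similarity(c(1, 4, 2, 3), c(1, 2, 3))$score # one deletion: 3 - p
```

### How the maximization is carried out

Once the balanced content is fixed (and constraint 1 fixes it), the number
of deleted markers `d` is a constant, so only the component structure is
optimized. The search enumerates per-family occurrence bijections
depth-first in a fixed deterministic order (families with few options
first), keeping the first optimum encountered — this makes co-optimal
tie-breaking reproducible for the refinement stage. Because the attainable
component score is bounded by the number of matched pairs (every edge can
contribute at most half an `f(2)`), the search stops early when the
incumbent reaches that bound; an identity-like matching therefore returns
immediately. An explicit admissible bound per partial assignment adds
nothing here, since the deletion term is constant and the component bound
does not tighten until an assignment is complete; deep search spaces are
instead cut off by a node budget (default 1e5 evaluated assignments), and
results that hit the budget carry `exact = FALSE` so downstream consumers
can exclude them. In the intended regime — syntenic blocks of tens of
markers with low within-block multiplicity — the search is exhaustive.

## Segmentation

The genome segmentation problem — decompose sequences into families of
non-overlapping atoms of at least a minimum length such that no alignment
boundary falls strictly inside an atom, minimizing nucleotides in *waste*
regions — is intractable, so `segment()` is a heuristic with the same
objective and constraints: close the breakpoint set under strand-aware
proportional propagation through alignments to a fixed point (integer
snapping guarantees termination), form candidate atoms between consecutive
breakpoints, discard short or uncovered segments as waste, then greedily
drop alignments whose induced breakpoints cost more waste than the
alignment covers, re-closing after each drop. Waste never exceeds the
keep-all baseline by construction; on small instances the test suite
compares against exhaustive enumeration over alignment subsets and reports
the optimality gap. Proportional mapping ignores alignment gap structure
(CIGARs are not part of the input format); with boundary-closed atoms this
only matters for families of near-threshold atoms. Orientation within a
family is assigned by breadth-first sign propagation; an inconsistent
inversion cycle keeps the first assignment, a documented arbitrary choice.

## Synteny discovery

`discover_blocks()` takes one genome as reference scaffold. Candidate
contents are the maximal intervals of the reference (not extendable without
changing content); windows in all genomes — including additional windows in
the reference — qualify as occurrences when they begin and end with a
content member and deviate by at most `delta_add` inserted, `delta_loss`
missing, `delta_sum` total markers, with thresholds growing with content
size. Occurrences are maximal (not strictly contained in another valid
window), the quorum counts distinct genomes including the reference, and
block sets with identical content and occurrences are deduplicated.

The two shipped threshold profiles (`default`: add = loss = `size/4`,
sum = `size/3`; `relaxed`: `size/3` and `size/2`, all floored) are
conservative house choices — measured tables tuned to a particular dataset
can be supplied as custom tables. The pipeline additionally caps candidate
reference content size (`max_ref_size`, default 10): candidate enumeration
is quadratic in reference length without it, and CAR assembly only needs
interval constraints at modest scale. Uncapped discovery is available
(`max_ref_size = Inf`) and is what the oracle-equivalence tests exercise.
When more than `overlap_cap` (default 30) block sets mutually overlap, only
the highest-weight ones are kept, with summed local DCJ scores as weights.

## Family refinement

Block sets that share a marker occurrence form *overlap components*.
Rule (i): occurrences of family `F` inside component `O` become family
`F@O` when they are a proper subset of `F` — a family wholly inside one
component is left alone, which is exactly what makes the rule idempotent.
Rule (ii): for a reference occurrence `m1`, if every non-reference genome
that ever matches `m1` matches it to a single distinct occurrence across
all local DCJ computations, the matched set becomes a new family `F@O#k`.
Being unmatched in some computation does not break consistency — only
conflicting partners do; and a partner claimed by two different reference
anchors is dropped from both, keeping the assignment a partition.
Refinement only ever splits families; content recruitment can only grow.

## CAR assembly

Ancestral content: a (refined) family is recruited when it spans at least
two genomes — or, with a configured two-clade split, one genome on each
side. Candidates are (a) adjacencies observed on content-restricted extant
chromosomes in at least two genomes, weighted by genome support, and (b)
block contents restricted to ancestral families, weighted by summed local
DCJ scores (or genome support with `weight_mode = "occurrence"`).
Candidates are inserted into a PQ-tree in decreasing weight (ties: smaller
content, then lexicographic) with the standard reduction; incompatible
candidates are skipped. Children of the root are the CARs; P-node children
are emitted sorted by smallest leaf for reproducibility, and the mean
Q-node child count quantifies how much of the ancestral order is fixed.
Marker orientations in CARs are not reconstructed — the input constraints
(sets) carry no orientation information.

## The simulator and what passing tests mean

`simulate_dataset()` draws an ancestor of unique signed markers on linear
chromosomes, walks a phylogeny applying per-branch whole-genome events
(chromosome complement copied, each *new* copy of a marker lost
independently with probability `loss_rate`; pre-event copies survive, so
every marker keeps a descendant and `loss_rate = 1` restores pre-event
multiplicities) followed by random DCJ operations (uniform over adjacency
pairs plus single-adjacency fissions; circular excisions and no-ops are
redrawn). Whole-genome events precede rearrangements on a branch, so
post-polyploidy rearrangement shuffles the copies, as fractionated genomes
require.

The reference conditions used by the end-to-end tests and the acceptance
script are a five-leaf eudicot-shaped phylogeny (`eudicot_phylogeny()`):
one rosid-like outgroup, four asterid-like leaves, a WGT on the asterid
stem and a WGD on one terminal branch, `loss_rate = 0.6`, five DCJ
operations per internal branch and ten per terminal branch (internal
branches of this phylogeny are short relative to terminal ones), ancestor
of 200 markers on five chromosomes. At this size the full pipeline runs in
about a minute on one core; the problem sizes of all oracle comparisons
(BFS DCJ distance at n <= 5, exhaustive matchings at lengths <= 7,
permutation enumeration at <= 7 leaves) are chosen so the oracles remain
exact.

What the simulator does **not** model: sequence-level mutation (segmentation
is tested on constructed alignment fixtures instead), unequal marker
lengths, biased fractionation (loss is uniform and copy-protected), gene
conversion, and tandem duplication. Passing recovery tests therefore shows
the machinery is sound under the stated rearrangement model, not that any
particular biological dataset will reach the same recovery rate.

## Numerical and degenerate-input choices

* Balance/content comparisons are exact set/multiset operations on opaque
  string identifiers; no hashing of numeric ids.
* `f_score()` rejects odd lengths — odd cycles cannot occur in an adjacency
  graph, so an odd input always indicates a caller bug.
* Empty balanced content yields score `-(|S|+|T|) p` with an empty
  assignment; empty genomes have distance 0 and empty adjacency sets.
* Chromosomes are linear throughout; circular chromosomes are rejected
  (the marker-table representation cannot express them, and the simulator
  redraws operations that would excise circles).
* All orderings that matter (P-child emission, candidate processing,
  block/CAR numbering) are fixed by radix sorts, so identical inputs give
  byte-identical outputs everywhere.

## Limitations

* The local DCJ optimizer is exponential in within-block duplication; the
  node budget turns pathological blocks into flagged heuristic results
  rather than stalls.
* Synteny discovery matches the input/output semantics of
  reference-based approximate common interval finders, not their indexing
  algorithms; very long reference genomes need the content-size cap.
* Rule (ii) is reference-anchored: positional orthologies invisible from
  the reference genome are not recovered.
* CARs are unsigned and telomeres are not modelled; the PQ-tree root is an
  unconstrained P-node.
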