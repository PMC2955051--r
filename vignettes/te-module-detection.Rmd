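---
title: "Detecting modules in transposable-element families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting modules in transposable-element families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TEmodules)
```

## The model

TEmodules describes a family of transposable-element sequences as a
succession of *modules*: conserved blocks built from exact maximal
repeats (MRs) separated by short variable spacers. The design rests on
three definitions.

An MR is a word with two occurrences whose left flanking letters differ
and whose right flanking letters differ; sequence boundaries behave as
per-sequence unique sentinels, so a word touching two different sequence
ends is maximal. MRs are enumerated over a generalized suffix array with
a unique sentinel code between sequences (and for every ambiguous base N,
which therefore breaks repeats); maximality is decided per LCP interval
by left-diversity of the preceding letters.

A *flexible repeat* chains two flexible repeats A and B through spacers
x: per occurrence the length condition |x| ≤ |A| · Maxratio/100 holds (A
being the seed occurrence's span), and across occurrences the distance
condition e(x, y) ≤ min(b_x, b_y) holds, where e is the unit-cost
Levenshtein distance and b the size of the MR being attached. The guiding
principle is that flexibility can never exceed the parts it links: a
spacer may be as variable as the anchors are long, no more. Spacers may
be empty.

A *module* is a flexible repeat with occurrences of at least
`MinSizeModule` nt in at least `MinSequences` sequences, placed so that
no two module occurrences overlap (partition condition).

## The detection loop

Assembly is greedy, largest structures first. At each support level
(`MinSequences` sweeping n down to 1, or a fixed user value) the working
list L of MRs — sorted by decreasing length, then occurrence count, then
word — is scanned for a seed that can be paired: for each candidate
partner, every admissible association (A x B or B x A) becomes a vertex
of a compatibility graph whose edges join spacer-compatible associations
of the same orientation; a clique covering `MinSequences` distinct
sequences certifies the pair. Cliques are found heuristically (vertices
filtered by cross-sequence neighbourhood, then greedy highest-degree
extension with deterministic tie-breaks); the heuristic may miss an
existing clique, which is the documented contract. A successful pair
consumes the participating occurrences and the chain is extended left or
right until no partner qualifies; the chain is a module if every
occurrence reaches `MinSizeModule`, otherwise it is discarded and the
level's pair search ends. Lone MRs meeting the size and support
conditions are emitted after the pair search of each level, so conserved
solitary blocks (e.g. TE termini) are kept. Composite chains always
require at least two distinct supporting sequences; within a single
sequence only lone-MR modules (e.g. tandem units) arise.

Reverse (palindromic) occurrences are searched immediately after a module
is accepted: the reverse-complemented MRs in reversed order, with each
spacer's reverse complement required to sit within edit distance of an
observed direct spacer (at most the smaller flanking part). Support at
discovery counts both directions. Truncated occurrences are added in a
second step once all complete modules are placed: anchored at exact
matches of the module's largest MR on uncovered regions, other parts are
attached greedily in their original relative order within the observed
spacer-length windows (widened by a Maxratio-proportional slack); the
conserved fraction is the summed length of present MRs over the module's
total MR length, and the largest MR is mandatory.

### Shielding rules

Three package-level rules keep the greedy loop from fragmenting conserved
cores; the underlying definitions do not legislate here, and without them
the second-step truncated semantics could not arise (leftover cores would
be re-consumed as new modules first):

* *failure shield* — when a module-sized seed cannot pair at a level,
  occurrences of other repeats overlapping its loci are withheld, so its
  interior cannot be claimed piecemeal while it waits for a lower support
  level;
* *pending-core shield* — while a repeat of at least part scale
  (length ≥ `MinSizeModule`/2) has support below the current level,
  fragments shorter than half its length cannot claim its loci at this
  level. This blocks chains of interior sub-words whose support has been
  propped up to the current level by a chance match elsewhere;
* *truncated-pass shield* — once a module is accepted (truncated search
  on), every sequence match of its parts of length ≥ `MinSizeModule`/2,
  and of their reverse complements when the reverse search is on, is
  reserved for the reverse/truncated passes.

## Parameters

* `minSizeModule` (nt, default: the smallest word size at which some
  word over A, C, G, T is absent from the family). This is the crucial
  tuning knob. It should sit *between* the typical size of a single
  conserved word and the size of the blocks of interest: below that
  range the segmentation is overly detailed; far above it, small
  conserved blocks disappear. All desk-scale analyses in this package
  use values in the 18–25 nt range for part sizes of 12–20 nt.
* `maxratio` (percent, default 100): bounds each spacer at that fraction
  of the seed occurrence's span. 100 reproduces the plain length
  condition; lower values trade module size for spacer similarity.
* `minSequences` (default: sweep n → 1): fixed support level if given.
* `reverse`, `truncated`: enable the palindromic and truncated searches.

## Clustering

Each sequence becomes a vector of occurrence counters — one per module,
or three per module (`Mi`, `rMi`, `Mi|rMi`) when the reverse option is
on; truncated occurrences contribute their conserved fraction instead of
1 (a complete plus a half-conserved occurrence gives 1.5 on the total
attribute). Ward hierarchical agglomeration starts from singletons of
weight 1/n with Δ(x, y) = (1/2n) Σᵢ (xᵢ − yᵢ)² and updates merge costs by
the Lance–Williams recurrence with additive weights. The 1/(2n) scaling
affects heights only, never the topology. Ties on the minimal Δ are
broken toward the pair whose sorted smallest leaf indices are lowest;
merge order and heights are checked in the test suite against an
independent implementation that recomputes Δ from cluster centroids and
weights at every step. The tree is serialized to Newick with branch
lengths equal to differences of merge heights.

## The synthetic-family generator

`plantedArchitecture()` / `generateFamily()` emulate the aspects of TE
family evolution the method is designed for: exact conserved blocks
(each 1–3 parts of 12–20 nt, or a single 28–34 nt part) separated inside
a block by 4–8 nt spacers and between blocks by fully diverged regions
whose length exceeds the largest block span, with per-copy deletion,
tandem duplication, inversion and truncation events. Spacers are drawn
independently per copy — a saturated-divergence regime. This choice is
deliberate: were spacers near-identical across copies they would merge
into the flanking exact repeats, the planted parts would no longer be
the MR inventory, and the conserved-fraction arithmetic of truncated
occurrences could not be validated. Block parts are drawn mutually
dissimilar (pairwise edit distance above half the shorter part, no
containment) and generation is seed-deterministic.

What the generator does *not* emulate: point mutations inside conserved
blocks (the method's parts are exact words — a mutated block boundary
shifts or splits detected parts), realistic indel processes,
transposition machinery, or nested insertions of one family into
another. Passing recovery tests therefore demonstrate correctness of the
assembly logic under the model's own assumptions, not performance on
heavily decayed natural families.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open; every user-facing table is
1-based inclusive. All tie-breaks (working-list order, clique vertex
choice, Ward merges) are deterministic, so identical inputs give
byte-identical output files. A family whose sequences are all shorter
than `minSizeModule` yields an empty catalog with a warning; an empty
catalog clusters on a zero-column matrix (all merge heights 0). A module
occurrence set in a single sequence (tandem array) is restricted to a
non-overlapping left-to-right subset. Perfect-palindrome MRs are counted
once, on the plus strand.

## Problem sizes used in the shipped analyses

The test suite and the acceptance script run on families of 8–15 copies
of 300–900 nt (2–5 blocks), 104 oracle fixtures of up to ~220 nt total,
and Ward fixtures of up to 12 sequences; `MinSizeModule` is 22 with the
12–20 nt part pool. These sizes were chosen so that each property is
exercised at full strength (all support levels, every event type, both
strand modes) while a complete run stays in the minutes range.

## Known limitations

* The clique search is heuristic; a qualifying support clique can be
  missed (inherited, documented behaviour).
* Support attained by a *combination* of direct and reverse copies is
  credited after discovery: a module whose direct support alone is below
  a level is discovered later than its combined support would allow.
* If `minSizeModule` is chosen at or below the size of a module's
  largest part, a truncated copy can prop that part into a module of its
  own one support level early, and the truncated occurrence is then
  reported as a complete occurrence of the smaller module. Choosing
  `minSizeModule` above the part scale (previous section) avoids this.
* Module composition is greedy: a conserved region may be reported as a
  chain of sub-words with empty spacers rather than one long MR when
  chance flank agreements shorten or extend the maximal repeat; module
  *boundaries* are unaffected.
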