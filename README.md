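# TEmodules

Segmentation of transposable-element (TE) families into **modules** —
flexible assemblies of exact maximal repeats — with classification of the
sequences by their modular profiles.

## The problem

Non-autonomous transposable elements (MITEs, Helitron derivatives,
degenerated retroposons) accumulate deletions, duplications and
inversions until only their conserved extremities and a shuffled set of
internal blocks remain. Multiple alignment handles point mutations well
but cannot represent duplicated or inverted blocks, so the internal
architecture of such families stays invisible to alignment-based tools.
TEmodules is for curators and genome annotators who have a set of family
members (tens of sequences, hundreds to thousands of nt) and want a
structural description: which conserved blocks exist, in what order and
orientation each copy carries them, and how the copies group by content.

## The model

A word *w* is a **maximal repeat** (MR) in sequences S₁…Sₙ if it has two
occurrences *awc* and *bwd* with *a* ≠ *b* and *c* ≠ *d* (sequence
boundaries act as unique sentinel letters). A **flexible repeat** is an
ordered chain of MRs A x B whose spacers *x* satisfy, per occurrence, the
length condition |xᵢ| ≤ max(|Aᵢ|, |Bᵢ|) (tunable as
|xᵢ| ≤ |Aᵢ| · Maxratio/100) and, across occurrences, the distance
condition e(xᵢ, xⱼ) ≤ min(|Aᵢ|, |Aⱼ|, |Bᵢ|, |Bⱼ|) with *e* the
Levenshtein distance — flexibility can never exceed the parts it links. A
**module** is a flexible repeat whose occurrences all span at least
MinSizeModule nt and which is supported by at least MinSequences
sequences; module occurrences never overlap (partition condition).

Detection enumerates all MRs with a generalized suffix array, then
greedily seeds and extends flexible repeats at decreasing support levels
(MinSequences = n … 1), certifying each assembly step by a clique of
spacer-compatible associations. Reverse (palindromic) occurrences — the
reverse-complemented, order-reversed composition — are searched after
each module is accepted, and truncated occurrences (which must retain the
module's largest MR) are added in a second step, contributing their
conserved fraction of the module's MR length. Sequences are finally
clustered by Ward hierarchical agglomeration on the module incidence
matrix, Δ(x, y) = (1/2n) Σᵢ (xᵢ − yᵢ)², with the Lance–Williams update
Δ(x∪y, z) = ((n_x+n_z)Δ(x,z) + (n_y+n_z)Δ(y,z) − n_zΔ(x,y)) / (n_x+n_y+n_z).

## A worked example

```r
library(TEmodules)

arch <- plantedArchitecture(
    list(c(20, 10), c(20, 12), 28),
    events = list(list(copy = 3, block = 1, type = "invert"),
                  list(copy = 4, block = 1, type = "truncate"),
                  list(copy = 5, block = 2, type = "delete")),
    seed = 11)
g   <- generateFamily(arch, nCopies = 9, seed = 11)
res <- runPipeline(g$family, "fb_demo", minSizeModule = 22,
                   reverse = TRUE, truncated = TRUE)
moduleTable(res$catalog)
```

```
  module                                            parts totalMRLength support occurrences
1      1                     ATCTCACGAATGTCCATCCCACAGTGTG            28       9           9
2      2                GGGCTACGCTCGCATTGTTA|TGTAAATCATCG            32       8           8
3      3                  CCTATAATCTACCCGCAGAG|GACAGTGGCC            30       8           9
4      4 C|G|GT|T|AA|G|T|G|A|C|G|C|CA|T|GT|TGCACACCCT|CGC            32       2           2
```

Module 3 is the planted (20, 10) block: present once per copy, absent
from none, found as a `reverse` occurrence in the inverted copy 3, and as
a `truncated_direct` occurrence with conserved fraction 0.667 (= 20/30 of
its MR length) in copy 4, where the 10-mer was deleted:

```r
subset(compositionTable(res$catalog), kind != "direct")
```

```
   sequence_id module_id start end             kind conserved_fraction
7       copy03         3    65 101          reverse          1.0000000
10      copy04         3    54  73 truncated_direct          0.6666667
```

`runPipeline()` writes the composition table (`fb_demo_modules.tsv`), the
Ward classification in Newick format (`fb_demo_tree.nwk`), an SVG of the
segmentation aligned with the tree (`fb_demo_graph.svg`; reverse
occurrences carry a triangle, truncated ones are crossed boxes) and a
JSON run manifest. The same pipeline is available from the shell via
`exec/temodules`:

```sh
temodules --min-size-module 22 --reverse --truncated \
          --out-prefix fb_demo family.fasta
```

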