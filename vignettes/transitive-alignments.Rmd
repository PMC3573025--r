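---
title: "Transitive alignments: composition, scoring and consensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transitive alignments: composition, scoring and consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transalign)
```

## The model

`transalign` treats a pairwise alignment as a partial function between the
coordinates of two sequences: an ordered set of pairs $(q_k, t_k)$ with two
invariants. It is *one-to-one* — no query or target position appears in two
pairs, so the mapping is invertible — and *monotonic* (colinear): sorted by
$q$, the $t$ values strictly increase. Nucleotide matches on the reverse
strand are accommodated by storing minus-strand positions negated, which
makes the monotonicity criterion uniform: a descending run of positions
$p_1 > p_2 > \dots$ becomes the ascending $-p_1 < -p_2 < \dots$.

Under this model, an alignment $f$ from A to B and an alignment $g$ from B
to C compose to $g \circ f$ from A to C: every B position touched by both
contributes the pair $(f^{-1}(b),\, g(b))$. Both invariants survive
composition — a fact the test suite checks property-style on thousands of
random valid pairs rather than taking on faith.

Composition is the engine of intermediate-database searching: a query hit
file (query vs intermediate database) and a target hit file (intermediate
vs curated targets) yield a transitive alignment for every
query→intermediate→target chain that shares intermediate positions.

## Scoring

BLAST reports one score per HSP, but composition operates per position. The
package therefore distributes each HSP's bit score $s$ evenly over its $n$
aligned residue pairs, $w_k = s/n$; gap columns align nothing and carry no
score. A composed pair scores the *minimum* of the two per-pair scores it
chains through — a conservative choice: a transitive link is only as strong
as its weaker leg. Summing per-pair scores recovers $s$ exactly for a
single alignment (floating-point error is bounded by `1e-6` in every
contract here, and measured at ~`1e-13` in practice), which keeps
transitive and direct scores on one scale.

The bit score, not the raw alignment score, is the distributed quantity: it
is the score column of the BLAST tabular format and is comparable across
HSPs and searches, which is what ranking needs.

## Consensus

Routes through different intermediates rarely agree everywhere. For one
(query, target) pair the package pools every pair $(q, t, w)$ from every
transitive alignment and keeps the cell-wise maximum $M(q, t)$. The
consensus is the subset of cells maximizing $\sum M$ subject to the two
alignment invariants — exactly the alignment recurrence without gap
penalties:

$$T(i,j) = \max\big(T(i-1,j),\; T(i,j-1),\; T(i-1,j-1) + M(i,j)\big)$$

Two solvers implement it. `consensus_dense()` fills the grid row by row
(vectorized with a cumulative maximum, so R-level cost is one pass per
row). `consensus_sparse()` treats the problem as maximum-weight strictly
increasing chaining of the occupied cells, with a Fenwick tree of prefix
maxima over target ranks — $O(n \log n)$ in the number of cells and
independent of sequence length. `consensus_alignment()` picks dense when
the pool's bounding box has at most $4 \times 10^6$ cells and sparse
otherwise; both are always exported so tests can cross-check them, and they
agree exactly on the optimum.

Numerical choices worth stating:

* **Strictness.** The chosen pairs must increase strictly in both
  coordinates; the one-to-one invariant already forbids ties, so the
  diagonal move requires both $i$ and $j$ to advance.
* **Tie-breaking.** Traceback prefers the pair-taking diagonal move, then
  the move advancing the target coordinate. Ties in the optimum therefore
  resolve deterministically, and toward longer alignments.
* **Equality tests in traceback** compare values produced by the identical
  floating-point operations as the forward pass, so exact `==` is safe; no
  tolerance is needed inside the DP.
* **Strands.** A colinear chain cannot mix strands, so pools are split by
  coordinate sign, each block solved separately, and the best-scoring
  block reported. One row per (query, target) pair.
* **Empty pools** yield an empty consensus with score 0 rather than an
  error; empty compositions are dropped (with a debug log line), since a
  query and target may simply share no route.
* **Duplicated pairs** from different intermediates are not deduplicated
  before pooling; the cell-wise maximum absorbs them.

Useful consequences, each a test: the consensus score never falls below
the score of any single contributing alignment (each is itself a feasible
subset); adding a pair to the pool never decreases the optimum; and
consensus over a singleton returns the original alignment and score — so
when the intermediate→target file contains only perfect self-alignments,
the whole pipeline degenerates to the direct query→intermediate results.

## Input handling

The interchange format is BLAST tabular, `-outfmt '6 std btop'` (13
columns) or `'6 std qseq sseq'` (14 columns; converted to BTOP
internally). BTOP encodes the HSP column by column; expansion emits one
$(q, t)$ pair per match/mismatch column and advances only the ungapped
side through gaps. Translated nucleotide queries (blastx-like) advance the
query coordinate by 3 per column — the codon's first base — and are
detected per row from the ratio of coordinate span to consumed columns, so
protein and translated rows can share a file. Negative frames and
minus-strand subjects are negated at parse time, per the strand
convention. Composition always happens on the protein-coordinate
(intermediate) side, so the query step affects only reported coordinates.

Defensive checks live at the boundary: rows whose coordinate spans
disagree with their expanded traceback, with unparseable fields or with
negative scores are rejected with their line numbers; a file matching
neither column dialect is refused outright naming the expected `outfmt`
string. The E-value threshold is applied at parse time (default `1e-4`,
the annotation-style setting; `0.1` suits sensitive structure-screening
runs); lowering it can only shrink the output.

## The fixture generator

`generate_tripartite()` fabricates target "proteins" over the 20-letter
amino-acid alphabet, derives intermediates from targets and queries from
intermediates by point substitution (`mutation_rate`, default 0.1) and
indels (`gap_rate`, default 0.02, split evenly between insertions and
deletions), and emits the two hit files with coordinates, BTOP strings,
column counts and scores consistent by construction, plus the true
query→target correspondence. Scores come from a match/mismatch model
(default +2/−1) rather than a substitution matrix: the tool consumes
scores, it never re-derives them, so fixtures need only internal
consistency. E-values are placeholders (`1e-30`) below any default
threshold. Defaults (5 queries, 5 intermediates, 3 targets, lengths
80–150) keep the full pipeline test in milliseconds while leaving room for
several indels per sequence.

`split_coverage_fixture()` builds the scenario where transitive alignment
genuinely adds information: two intermediates each derived from one half
of the target, so every single route covers half the query and only the
consensus spans all of it. This fixture uses substitutions only, keeping
its ground truth the identity and the "coverage doubles" measurement
exact; the indel path is exercised by the general generator.

What the generator does **not** emulate: BLAST's E-value statistics,
compositional biases, paralogy (each query descends from exactly one
intermediate), and local-alignment edge effects (fixture HSPs are
full-length). Passing tests therefore demonstrate the correctness of
composition, scoring and consensus on well-formed inputs — not search
sensitivity on real databases, which depends on the BLAST stage upstream.

## Problem sizes and verification

The acceptance-style checks run at: 1,000 random HSPs for score
conservation and for BTOP round-trips; 500 random pools of up to 12 pairs
on an 8×8 grid against an exhaustive brute-force enumeration of all
colinear subsets; 200 random pools of up to 500 pairs for dense/sparse
equivalence; 10,000 random alignment pairs for invariant preservation
under composition; a 50-query identity-bridge fixture; and the
split-coverage fixture at `mutation_rate = 0.1`. These sizes give the
brute-force oracle full coverage of small instances and the property
checks enough trials to catch rare violations, while the whole suite stays
in tens of seconds.

## Limitations

* No affine gap model anywhere: composition inherits gaps from its inputs
  and the consensus recurrence is deliberately gap-penalty-free.
* Per-pair scores have no probabilistic calibration; consensus scores rank
  hits but are not E-values.
* One consensus row per (query, target): alignments on the minority strand
  are discarded rather than reported separately.
* The uniform score distribution flattens position-specific conservation;
  a strongly conserved motif and a weak flank in one HSP get the same
  per-pair weight.
* The pipeline holds one query's composition pool in memory plus an index
  of the intermediate→target file; the latter is read fully, so extremely
  large target-hit files are the practical bound.
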