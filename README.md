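# transalign

Transitive sequence alignments from pairwise BLAST hits.

Remote homologs are often invisible to a direct search against a curated
database, yet detectable through a much larger *intermediate* database: the
query aligns to an intermediate sequence, and that intermediate aligns to a
curated target. `transalign` turns those two pairwise alignments into an
indirect query→target alignment and reconciles the many alternative routes
through different intermediates into a single best alignment. It is aimed
at annotation workflows (e.g. transcripts searched against UniRef-scale
databases and then linked to SwissProt-quality targets) and at anyone who
already has the two BLAST tabular files and wants the composed result.

## The method

An alignment is modelled as a partial function between sequence
coordinates: a set of position pairs *(q, t)* that is **one-to-one** (no
position used twice) and **monotonic** (sorted by *q*, the *t* values
strictly increase; minus-strand coordinates are stored negated so the same
criterion covers both strands). Two alignments *f* : A→B and *g* : B→C
compose to the transitive alignment *g∘f* : A→C over the B positions they
share, and the composition is automatically one-to-one and monotonic.

Scoring distributes each alignment's bit score *s* evenly over its *n*
aligned residue pairs (each pair carries *s/n*; gap columns carry nothing)
and scores a composed pair by the **minimum** of the two per-pair scores it
passes through. Summing per-pair scores recovers the original bit score
when an alignment is used alone, so transitive scores stay comparable to
direct BLAST scores.

Different intermediates yield different — possibly contradictory —
transitive alignments for the same (query, target) pair. Let *M(i, j)* be
the maximal per-pair score over all of them that aligns query position *i*
to target position *j*. The consensus is the colinear, one-to-one subset of
pairs maximizing the summed score, computed with the gap-penalty-free
recurrence

    T(i, j) = max( T(i-1, j), T(i, j-1), T(i-1, j-1) + M(i, j) )

solved by dynamic programming over the coordinate grid, or equivalently by
sparse weighted colinear chaining over only the occupied cells when the
grid is large. Both solvers are provided and agree exactly.

## Worked example

The built-in generator fabricates the classic split-coverage scenario: two
intermediates that each cover one half of the homology between a query and
a target, so no single route spans the whole sequence:

```r
library(transalign)

fix <- split_coverage_fixture(fixture_spec(rng_seed = 42L))
dir <- tempfile(); paths <- write_fixture(fix, dir)

cfg <- run_config(query_hits = paths[1], target_hits = paths[2],
                  output = file.path(dir, "report.tsv"))
transalign_run(cfg)
#> 1 queries, 2 intermediates, 1 targets; 2 transitive alignments -> 1 consensus rows
```

The report:

```
#query_id  target_id  score  n_pairs  q_start  q_end  t_start  t_end  n_intermediates  best_intermediate
Q001       T001       195.0  150      1        150    1        150    2                B002
```

One consensus row covers the full 150-residue target (`n_pairs = 150`,
span 1–150) even though each transitive alignment covered only half;
`n_intermediates = 2` records that both bridges contributed, with `B002`
supplying the larger share of the score. The score 195.0 is the summed
per-pair score of the chosen pairs, on the same scale as the input bit
scores.

The same run works from a shell via the thin CLI:

```sh
Rscript inst/exec/transalign.R --query-hits query_hits.tsv \
    --target-hits target_hits.tsv --out report.tsv --max-evalue 1e-4
```

Inputs must be BLAST tabular with a traceback column, i.e.
`-outfmt '6 std btop'` (or `'6 std qseq sseq'`).

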