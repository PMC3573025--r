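#' transalign: transitive sequence alignments from pairwise BLAST hits
#'
#' Homology search against a curated database often misses remote
#' relationships that a much larger intermediate database can bridge: if a
#' query aligns to an intermediate sequence and that intermediate aligns to
#' a curated target, composing the two pairwise alignments yields an
#' indirect ("transitive") query-to-target alignment. This package
#' implements that composition, a per-position scoring heuristic
#' (distribute each alignment's bit score evenly over its aligned pairs;
#' take the minimum under composition), and a dynamic-programming consensus
#' that reconciles many mutually inconsistent transitive alignments into a
#' single maximum-score colinear alignment. BLAST tabular files (outfmt 6
#' with a BTOP traceback column, or with qseq/sseq columns) are the
#' interchange format; a fixture generator fabricates consistent tripartite
#' homology scenarios so the whole pipeline runs without BLAST.
#'
#' @section Main entry points:
#' * [read_blast_hits()] / [hsp_to_record()] — parse BLAST tabular output
#'   into alignment records.
#' * [compose_alignments()] — compose two alignments through a shared
#'   intermediate sequence.
#' * [consensus_alignment()] — merge all transitive alignments between one
#'   query and one target into the optimal colinear consensus.
#' * [transalign_run()] — the end-to-end pipeline over two hit files.
#' * [generate_tripartite()] / [split_coverage_fixture()] — synthetic test
#'   data.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Position mappings
# ---------------------------------------------------------------------------

#' Construct a position mapping
#'
#' An alignment is modelled as a partial function between sequence
#' coordinates: an ordered set of `(q, t, w)` triples where `q` is a
#' position in the first sequence, `t` the aligned position in the second,
#' and `w` a non-negative per-pair score. A valid mapping is one-to-one (no
#' `q` and no `t` repeats) and monotonic: sorted by `q`, the `t` values are
#' strictly increasing. Reverse-strand nucleotide coordinates are stored
#' negated (position `p` on the minus strand is stored as `-p`), which makes
#' the monotonicity criterion uniform across strands.
#'
#' @param q,t integer positions (1-based; negative for reverse strand).
#' @param w non-negative per-pair scores, recycled to length of `q`.
#' @param validate check the one-to-one and monotonicity invariants and
#'   throw on violation. Set `FALSE` only when validity is guaranteed by
#'   construction.
#' @return a `position_mapping`: a data frame with columns `q`, `t`, `w`,
#'   sorted by `q`.
#' @seealso [validate_mapping()], [compose_alignments()]
#' @export
#' @examples
#' position_mapping(1:3, c(5L, 6L, 9L), 2.0)
position_mapping <- function(q, t, w = 1.0, validate = TRUE) {
  q <- as.integer(q)
  t <- as.integer(t)
  w <- rep_len(as.numeric(w), length(q))
  stopifnot(length(t) == length(q))
  if (any(w < 0)) {
    stop("per-pair scores must be non-negative", call. = FALSE)
  }
  ord <- order(q)
  m <- data.frame(q = q[ord], t = t[ord], w = w[ord])
  class(m) <- c("position_mapping", "data.frame")
  if (validate) {
    v <- validate_mapping(m)
    if (!v$ok) {
      stop("invalid position mapping: ", v$message, call. = FALSE)
    }
  }
  m
}

#' Validate a position mapping
#'
#' Checks the two defining invariants of an alignment mapping: one-to-one
#' (no duplicated `q`, no duplicated `t`) and monotonic (sorted by `q`, `t`
#' strictly increases). Validation reports the first violation found; it
#' never throws.
#'
#' @param m a `position_mapping` or a data frame with columns `q`, `t`.
#' @return a list with elements `ok` (logical), and on failure `violation`
#'   (one of `"duplicate_q"`, `"duplicate_t"`, `"non_monotonic"`),
#'   `positions` (the offending coordinate values) and `message`.
#' @export
#' @examples
#' validate_mapping(data.frame(q = 1:2, t = c(6L, 5L)))
validate_mapping <- function(m) {
  if (nrow(m) == 0L) {
    return(list(ok = TRUE))
  }
  ord <- order(m$q)
  q <- m$q[ord]
  t <- m$t[ord]
  dq <- q[duplicated(q)]
  if (length(dq)) {
    return(list(
      ok = FALSE, violation = "duplicate_q", positions = unique(dq),
      message = paste0("query position(s) repeated: ",
                       paste(unique(dq), collapse = ", "))
    ))
  }
  dt <- t[duplicated(t)]
  if (length(dt)) {
    return(list(
      ok = FALSE, violation = "duplicate_t", positions = unique(dt),
      message = paste0("target position(s) repeated: ",
                       paste(unique(dt), collapse = ", "))
    ))
  }
  bad <- which(diff(t) <= 0L)
  if (length(bad)) {
    i <- bad[1L]
    return(list(
      ok = FALSE, violation = "non_monotonic",
      positions = c(q[i], q[i + 1L]),
      message = sprintf(
        "target positions not strictly increasing at q = %d -> %d (t: %d -> %d)",
        q[i], q[i + 1L], t[i], t[i + 1L])
    ))
  }
  list(ok = TRUE)
}

# ---------------------------------------------------------------------------
# Scoring heuristic
# ---------------------------------------------------------------------------

#' Distribute an alignment score evenly over its position pairs
#'
#' The per-position scoring heuristic assumes a uniform score distribution:
#' an alignment of score `s` over `n` aligned residue pairs assigns `s / n`
#' to every pair. Summing the per-pair scores back recovers the original
#' alignment score, which is the property that makes consensus scores
#' comparable to direct BLAST scores. Gap columns carry no position pair
#' and are excluded from `n_pairs`.
#'
#' @param raw_score total alignment score (bit score), non-negative.
#' @param n_pairs number of aligned residue pairs (match + mismatch
#'   columns), at least 1.
#' @return the per-pair score, `raw_score / n_pairs`.
#' @export
#' @examples
#' distribute_score(100, 50)  # 2
distribute_score <- function(raw_score, n_pairs) {
  if (length(n_pairs) != 1L || is.na(n_pairs) || n_pairs < 1) {
    stop("invalid alignment: no aligned residue pairs (n_pairs must be >= 1)",
         call. = FALSE)
  }
  if (length(raw_score) != 1L || is.na(raw_score) || raw_score < 0) {
    stop("raw_score must be a single non-negative number", call. = FALSE)
  }
  raw_score / n_pairs
}

# ---------------------------------------------------------------------------
# Alignment records
# ---------------------------------------------------------------------------

#' Construct an alignment record
#'
#' Bundles a position mapping with the identifiers of the two sequences it
#' relates, its total score (the sum of per-pair scores), and provenance:
#' either a direct HSP from a BLAST result file, a transitive alignment
#' composed through a named intermediate, or a consensus over several
#' transitive alignments.
#'
#' @param query_id,target_id sequence identifiers.
#' @param mapping a [position_mapping()].
#' @param provenance a list with element `type` in
#'   `c("direct", "transitive", "consensus")`; for `"direct"` an `hsp`
#'   index, for `"transitive"` the `intermediate` sequence ID.
#' @param total_score total alignment score; defaults to the sum of the
#'   mapping's per-pair scores and must agree with it to within `1e-6`.
#' @return an object of class `alignment_record`.
#' @export
alignment_record <- function(query_id, target_id, mapping,
                             provenance = list(type = "direct", hsp = NA_integer_),
                             total_score = sum(mapping$w)) {
  stopifnot(inherits(mapping, "position_mapping"))
  if (abs(total_score - sum(mapping$w)) > 1e-6) {
    stop("total_score does not match the sum of per-pair scores", call. = FALSE)
  }
  structure(
    list(query_id = as.character(query_id),
         target_id = as.character(target_id),
         mapping = mapping,
         total_score = total_score,
         provenance = provenance),
    class = "alignment_record"
  )
}

#' @export
print.alignment_record <- function(x, ...) {
  prov <- switch(x$provenance$type,
    direct = "direct HSP",
    transitive = paste0("transitive via ", x$provenance$intermediate),
    consensus = "consensus",
    x$provenance$type)
  cat(sprintf("<alignment_record> %s -> %s (%s)\n",
              x$query_id, x$target_id, prov))
  cat(sprintf("  %d aligned pairs, total score %.4g\n",
              nrow(x$mapping), x$total_score))
  if (nrow(x$mapping)) {
    cat(sprintf("  q: %d..%d  t: %d..%d\n",
                min(x$mapping$q), max(x$mapping$q),
                min(x$mapping$t), max(x$mapping$t)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Composition
# ---------------------------------------------------------------------------

#' Compose two alignments into a transitive alignment
#'
#' Given an alignment `f` from sequence A to sequence B and an alignment
#' `g` from B to C, the transitive alignment is the function composition
#' `g(f(.))`: for every B position that both alignments touch, the A
#' position is mapped to the corresponding C position. Because each input
#' mapping is one-to-one and monotonic, so is the composition. The
#' per-pair score of a composed pair is the minimum of the two
#' contributing per-pair scores.
#'
#' @param f an [alignment_record()] from A to B.
#' @param g an [alignment_record()] from B to C; `g$query_id` must equal
#'   `f$target_id`.
#' @return an `alignment_record` from A to C with transitive provenance
#'   naming B, or `NULL` when the two alignments share no B position.
#' @export
#' @examples
#' f <- alignment_record("a", "b", position_mapping(1:2, 10:11, 2))
#' g <- alignment_record("b", "c", position_mapping(10:11, 5:6, c(1, 3)))
#' compose_alignments(f, g)
compose_alignments <- function(f, g) {
  stopifnot(inherits(f, "alignment_record"), inherits(g, "alignment_record"))
  if (!identical(f$target_id, g$query_id)) {
    stop(sprintf("cannot compose: f targets '%s' but g queries '%s'",
                 f$target_id, g$query_id), call. = FALSE)
  }
  idx <- match(f$mapping$t, g$mapping$q)
  keep <- !is.na(idx)
  if (!any(keep)) {
    return(NULL)
  }
  m <- position_mapping(
    q = f$mapping$q[keep],
    t = g$mapping$t[idx[keep]],
    w = pmin(f$mapping$w[keep], g$mapping$w[idx[keep]]),
    validate = FALSE
  )
  alignment_record(
    query_id = f$query_id, target_id = g$target_id, mapping = m,
    provenance = list(type = "transitive", intermediate = g$query_id)
  )
}

# ---------------------------------------------------------------------------
# Hit sets
# ---------------------------------------------------------------------------

#' Index a collection of alignment records
#'
#' A hit set holds alignment records together with lookup indices from
#' source (query) sequence ID and from destination (target) sequence ID to
#' the records that involve them, so both directions of the tripartite
#' composition can be walked efficiently.
#'
#' @param records a list of [alignment_record()] objects.
#' @return an object of class `hit_set` with elements `records`,
#'   `by_source` and `by_dest` (named lists of record indices).
#' @export
hit_set <- function(records) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "alignment_record")))
  qids <- vapply(records, `[[`, character(1), "query_id")
  tids <- vapply(records, `[[`, character(1), "target_id")
  structure(
    list(records = records,
         by_source = split(seq_along(records), qids),
         by_dest = split(seq_along(records), tids)),
    class = "hit_set"
  )
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("<hit_set> %d records, %d source IDs, %d destination IDs\n",
              length(x$records), length(x$by_source), length(x$by_dest)))
  invisible(x)
}
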