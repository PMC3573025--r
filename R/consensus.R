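# Consensus of transitive alignments: maximum-score colinear subset of
# position pairs, solved by dynamic programming (dense grid) or by weighted
# colinear chaining over the occupied pairs only (sparse).

#' Pool the position pairs of several alignments
#'
#' Different intermediates yield different, possibly mutually inconsistent,
#' transitive alignments between the same query and target. The pair pool
#' collects every `(q, t, w)` triple from every contributing alignment and
#' keeps, for each distinct `(q, t)` cell, the maximal score `M(q, t)`
#' observed there, remembering which intermediate supplied it.
#'
#' @param alignments a list of [alignment_record()]s, all relating the same
#'   `query_id` and `target_id`.
#' @return an object of class `pair_pool`: a data frame with columns `q`,
#'   `t`, `w` (the maximum score per cell) and `source` (the provenance
#'   label of the alignment achieving it), with attributes `query_id`,
#'   `target_id` and `n_alignments`.
#' @export
build_pair_pool <- function(alignments) {
  stopifnot(is.list(alignments),
            all(vapply(alignments, inherits, logical(1), "alignment_record")))
  if (length(alignments) == 0L) {
    pool <- data.frame(q = integer(), t = integer(), w = numeric(),
                       source = character())
  } else {
    qid <- unique(vapply(alignments, `[[`, character(1), "query_id"))
    tid <- unique(vapply(alignments, `[[`, character(1), "target_id"))
    if (length(qid) != 1L || length(tid) != 1L) {
      stop("all alignments in a pool must share one (query_id, target_id) pair",
           call. = FALSE)
    }
    src <- vapply(alignments, function(a) {
      switch(a$provenance$type,
             transitive = a$provenance$intermediate,
             direct = a$query_id,
             consensus = "consensus")
    }, character(1))
    pool <- do.call(rbind, lapply(seq_along(alignments), function(i) {
      m <- alignments[[i]]$mapping
      data.frame(q = m$q, t = m$t, w = m$w, source = src[[i]])
    }))
    # keep the max-scoring entry per (q, t) cell
    ord <- order(pool$q, pool$t, -pool$w)
    pool <- pool[ord, , drop = FALSE]
    pool <- pool[!duplicated(pool[c("q", "t")]), , drop = FALSE]
    rownames(pool) <- NULL
  }
  attr(pool, "query_id") <- if (length(alignments)) alignments[[1L]]$query_id else NA_character_
  attr(pool, "target_id") <- if (length(alignments)) alignments[[1L]]$target_id else NA_character_
  attr(pool, "n_alignments") <- length(alignments)
  class(pool) <- c("pair_pool", "data.frame")
  pool
}

#' @export
print.pair_pool <- function(x, ...) {
  cat(sprintf("<pair_pool> %s -> %s: %d distinct (q,t) cells from %d alignment(s)\n",
              attr(x, "query_id"), attr(x, "target_id"),
              nrow(x), attr(x, "n_alignments")))
  invisible(x)
}

# Shift a same-strand block of pairs onto a compact 1-based grid.
# Negative (reverse-strand) coordinates keep their stored order, so a plain
# offset preserves monotonicity.
.normalize_block <- function(pool) {
  qoff <- min(pool$q) - 1L
  toff <- min(pool$t) - 1L
  list(qi = pool$q - qoff, ti = pool$t - toff, qoff = qoff, toff = toff)
}

#' Consensus by dense dynamic programming
#'
#' Solves the consensus recurrence over the full coordinate grid: the best
#' total score `T(i, j)` for aligning prefixes ending at query position `i`
#' and target position `j` is the maximum of skipping `i`, skipping `j`, or
#' pairing `i` with `j` for a reward of `M(i, j)`. There is no gap penalty;
#' unpaired positions cost nothing. Traceback prefers the pair-taking
#' diagonal move, then the move advancing the target, which makes the
#' reported alignment deterministic and favours longer alignments among
#' score ties.
#'
#' All pool coordinates must lie on a single strand (uniform sign);
#' [consensus_alignment()] handles strand splitting and is the usual entry
#' point.
#'
#' @param pool a [build_pair_pool()] result (or data frame with `q`, `t`,
#'   `w`), single-strand.
#' @param qlen,tlen optional grid extents; the bounding box of the pool is
#'   always sufficient and is used by default.
#' @return a list with `score` (the DP optimum) and `chosen` (row indices
#'   into `pool` of the selected pairs, in ascending `q` order).
#' @seealso [consensus_sparse()], [consensus_alignment()]
#' @export
consensus_dense <- function(pool, qlen = NULL, tlen = NULL) {
  if (nrow(pool) == 0L) {
    return(list(score = 0, chosen = integer()))
  }
  if (length(unique(sign(pool$q))) != 1L || length(unique(sign(pool$t))) != 1L) {
    stop("consensus_dense requires a single-strand pool", call. = FALSE)
  }
  nb <- .normalize_block(pool)
  nq <- max(nb$qi)
  nt <- max(nb$ti)
  M <- matrix(0, nq, nt)
  has <- matrix(FALSE, nq, nt)
  # later assignment wins; order ascending w so the max lands last
  ow <- order(pool$w)
  M[cbind(nb$qi[ow], nb$ti[ow])] <- pool$w[ow]
  has[cbind(nb$qi, nb$ti)] <- TRUE
  idx_of <- matrix(0L, nq, nt)
  idx_of[cbind(nb$qi, nb$ti)] <- seq_len(nrow(pool))

  # T is (nq+1) x (nt+1) with a zero boundary; row update via cummax:
  # T[i,j] = max(T[i-1,j], T[i,j-1], T[i-1,j-1] + M[i,j])
  Tm <- matrix(0, nq + 1L, nt + 1L)
  for (i in seq_len(nq)) {
    prev <- Tm[i, ]
    cand <- pmax(prev[-1L], prev[-(nt + 1L)] + M[i, ])
    Tm[i + 1L, ] <- cummax(c(0, cand))
  }

  chosen <- integer()
  i <- nq; j <- nt
  while (i > 0L && j > 0L) {
    if (has[i, j] && Tm[i + 1L, j + 1L] == Tm[i, j] + M[i, j]) {
      chosen <- c(chosen, idx_of[i, j])
      i <- i - 1L; j <- j - 1L
    } else if (Tm[i + 1L, j + 1L] == Tm[i + 1L, j]) {
      j <- j - 1L
    } else {
      i <- i - 1L
    }
  }
  chosen <- rev(chosen)
  list(score = Tm[nq + 1L, nt + 1L], chosen = chosen)
}

#' Consensus by sparse weighted colinear chaining
#'
#' Computes the same optimum as [consensus_dense()] while visiting only the
#' occupied `(q, t)` cells: the problem is a maximum-weight strictly
#' increasing chain of 2-D points (a weighted longest-increasing-subsequence
#' variant), solved in `O(n log n)` with a Fenwick tree holding prefix
#' maxima over target ranks. Preferred when the coordinate bounding box is
#' large relative to the number of pairs.
#'
#' @inheritParams consensus_dense
#' @return a list with `score` and `chosen`, as [consensus_dense()].
#' @export
consensus_sparse <- function(pool) {
  n <- nrow(pool)
  if (n == 0L) {
    return(list(score = 0, chosen = integer()))
  }
  if (length(unique(sign(pool$q))) != 1L || length(unique(sign(pool$t))) != 1L) {
    stop("consensus_sparse requires a single-strand pool", call. = FALSE)
  }
  tr <- match(pool$t, sort(unique(pool$t)))  # rank of t
  ntr <- max(tr)
  fen_val <- numeric(ntr)   # prefix-max Fenwick over chain scores
  fen_idx <- integer(ntr)   # pair index achieving each stored max

  fen_query <- function(p) {
    best <- 0; bi <- 0L
    while (p > 0L) {
      if (fen_val[p] > best) { best <- fen_val[p]; bi <- fen_idx[p] }
      p <- p - bitwAnd(p, -p)
    }
    list(val = best, idx = bi)
  }
  fen_update <- function(p, v, i) {
    while (p <= ntr) {
      if (v > fen_val[p]) { fen_val[p] <<- v; fen_idx[p] <<- i }
      p <- p + bitwAnd(p, -p)
    }
  }

  score <- numeric(n)
  pred <- integer(n)
  ord <- order(pool$q, pool$t)
  groups <- split(ord, pool$q[ord])
  for (grp in groups) {
    for (k in grp) {
      if (tr[k] > 1L) {
        qr <- fen_query(tr[k] - 1L)
        score[k] <- qr$val + pool$w[k]
        pred[k] <- qr$idx
      } else {
        score[k] <- pool$w[k]
        pred[k] <- 0L
      }
    }
    for (k in grp) fen_update(tr[k], score[k], k)
  }

  best <- which.max(score)
  chosen <- integer()
  k <- best
  while (k != 0L) {
    chosen <- c(chosen, k)
    k <- pred[k]
  }
  list(score = score[best], chosen = rev(chosen))
}

#' Consensus alignment of a set of transitive alignments
#'
#' Reduces all (possibly inconsistent) alignments between one query and one
#' target to the single colinear, one-to-one subset of position pairs that
#' maximizes the summed per-pair scores. Mixed-strand pools are split by
#' coordinate sign — a colinear chain cannot mix strands — and the
#' best-scoring strand's consensus is reported. Consensus over a single
#' alignment returns that alignment's pairs and recovers its original total
#' score, so consensus scores are directly comparable to direct BLAST
#' scores.
#'
#' @param alignments a list of [alignment_record()]s sharing one
#'   `(query_id, target_id)` pair, or a prebuilt [build_pair_pool()].
#' @param method `"auto"` (dense when the coordinate bounding box has at
#'   most `dense_limit` cells, sparse otherwise), `"dense"` or `"sparse"`.
#' @param dense_limit cell-count threshold for the automatic choice.
#' @return an object of class `consensus_result`: a list with `record` (an
#'   [alignment_record()] of the chosen pairs, consensus provenance),
#'   `intermediates` (data frame of contributing intermediate IDs and their
#'   score mass in the chosen subset, descending) and `method` used.
#' @export
#' @examples
#' f <- alignment_record("u", "t", position_mapping(1:3, 4:6, 2),
#'                       provenance = list(type = "transitive", intermediate = "b1"))
#' consensus_alignment(list(f))
consensus_alignment <- function(alignments,
                                method = c("auto", "dense", "sparse"),
                                dense_limit = 4e6) {
  method <- match.arg(method)
  pool <- if (inherits(alignments, "pair_pool")) {
    alignments
  } else {
    build_pair_pool(alignments)
  }
  qid <- attr(pool, "query_id")
  tid <- attr(pool, "target_id")

  empty <- function() {
    structure(
      list(record = alignment_record(
             query_id = if (is.null(qid)) NA_character_ else qid,
             target_id = if (is.null(tid)) NA_character_ else tid,
             mapping = position_mapping(integer(), integer(), numeric()),
             provenance = list(type = "consensus")),
           intermediates = data.frame(intermediate = character(),
                                      score_mass = numeric()),
           method = method),
      class = "consensus_result")
  }
  if (nrow(pool) == 0L) {
    return(empty())
  }

  strand <- paste0(ifelse(pool$q > 0L, "+", "-"), ifelse(pool$t > 0L, "+", "-"))
  best <- NULL
  best_rows <- NULL
  used_method <- method
  for (s in sort(unique(strand))) {
    rows <- which(strand == s)
    block <- pool[rows, , drop = FALSE]
    m <- method
    if (m == "auto") {
      cells <- as.numeric(diff(range(block$q)) + 1L) *
               as.numeric(diff(range(block$t)) + 1L)
      m <- if (cells <= dense_limit) "dense" else "sparse"
    }
    sol <- if (m == "dense") consensus_dense(block) else consensus_sparse(block)
    if (is.null(best) || sol$score > best$score) {
      best <- sol
      best_rows <- rows
      used_method <- m
    }
  }

  sel <- pool[best_rows[best$chosen], , drop = FALSE]
  mapping <- position_mapping(sel$q, sel$t, sel$w, validate = FALSE)
  rec <- alignment_record(qid, tid, mapping,
                          provenance = list(type = "consensus"))
  mass <- if (nrow(sel)) {
    agg <- stats::aggregate(sel$w, by = list(intermediate = sel$source), FUN = sum)
    names(agg)[2L] <- "score_mass"
    agg[order(-agg$score_mass, agg$intermediate), , drop = FALSE]
  } else {
    data.frame(intermediate = character(), score_mass = numeric())
  }
  rownames(mass) <- NULL
  structure(list(record = rec, intermediates = mass, method = used_method),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> %s -> %s: %d pairs, score %.4g (%s solver)\n",
              x$record$query_id, x$record$target_id,
              nrow(x$record$mapping), x$record$total_score, x$method))
  if (nrow(x$intermediates)) {
    cat("  intermediates:",
        paste(sprintf("%s (%.3g)", x$intermediates$intermediate,
                      x$intermediates$score_mass), collapse = ", "), "\n")
  }
  invisible(x)
}
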