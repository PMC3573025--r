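# Synthetic tripartite homology fixtures: target "proteins", intermediates
# derived from targets, queries derived from intermediates, emitted as
# internally consistent BLAST-tabular-with-BTOP files plus the ground-truth
# query->target position correspondence.

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Parameters for the synthetic tripartite generator
#'
#' @param n_queries,n_intermediates,n_targets counts of sequences at each
#'   tier. Intermediates are derived from targets (cycled) and queries from
#'   intermediates (cycled), so every query has a homologous target.
#' @param seq_length length range (min, max) for target sequences; at
#'   least 10.
#' @param mutation_rate per-residue substitution probability on each
#'   derivation step, in `[0, 1)`.
#' @param gap_rate per-residue indel probability on each derivation step
#'   (split evenly between insertions and deletions), in `[0, 1)`.
#' @param score_model `c(match, mismatch)`: per-column match reward and
#'   mismatch penalty used to synthesize HSP scores.
#' @param rng_seed integer seed; generation is reproducible given the seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_queries = 5L, n_intermediates = 5L, n_targets = 3L,
                         seq_length = c(80L, 150L), mutation_rate = 0.1,
                         gap_rate = 0.02, score_model = c(match = 2, mismatch = 1),
                         rng_seed = 42L) {
  stopifnot(n_queries >= 1, n_intermediates >= 1, n_targets >= 1,
            length(seq_length) == 2L, all(seq_length >= 10L),
            seq_length[1L] <= seq_length[2L],
            mutation_rate >= 0, mutation_rate < 1,
            gap_rate >= 0, gap_rate < 1,
            length(score_model) == 2L, all(score_model >= 0))
  structure(list(n_queries = as.integer(n_queries),
                 n_intermediates = as.integer(n_intermediates),
                 n_targets = as.integer(n_targets),
                 seq_length = as.integer(seq_length),
                 mutation_rate = mutation_rate, gap_rate = gap_rate,
                 score_model = score_model, rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

# Derive a child sequence from a parent by point substitution and indels,
# recording the alignment columns. Returns the child sequence (character
# vector) and a column table: type "m" (aligned), "ins" (child only),
# "del" (parent only), with child/parent positions and characters.
.derive <- function(parent, mutation_rate, gap_rate) {
  L <- length(parent)
  cap <- 2L * L + 2L
  type <- character(cap); qc <- character(cap); tc <- character(cap)
  tpos <- integer(cap)
  k <- 0L
  for (i in seq_len(L)) {
    if (stats::runif(1) < gap_rate / 2) {        # insertion before i
      k <- k + 1L
      type[k] <- "ins"; qc[k] <- sample(.AA, 1L); tc[k] <- "-"; tpos[k] <- NA_integer_
    }
    k <- k + 1L
    if (stats::runif(1) < gap_rate / 2) {        # deletion of parent residue i
      type[k] <- "del"; qc[k] <- "-"; tc[k] <- parent[i]; tpos[k] <- i
    } else if (stats::runif(1) < mutation_rate) { # substitution
      type[k] <- "m"; qc[k] <- sample(setdiff(.AA, parent[i]), 1L)
      tc[k] <- parent[i]; tpos[k] <- i
    } else {                                      # conserved
      type[k] <- "m"; qc[k] <- parent[i]; tc[k] <- parent[i]; tpos[k] <- i
    }
  }
  type <- type[seq_len(k)]; qc <- qc[seq_len(k)]; tc <- tc[seq_len(k)]
  tpos <- tpos[seq_len(k)]
  qpos <- ifelse(qc != "-", cumsum(qc != "-"), NA_integer_)
  list(child = qc[qc != "-"],
       cols = data.frame(type = type, qpos = as.integer(qpos), tpos = tpos,
                         qchar = qc, tchar = tc))
}

# BTOP string for a column table (child is the query side).
.cols_to_btop <- function(cols) {
  is_match <- cols$type == "m" & cols$qchar == cols$tchar
  piece <- ifelse(is_match, "1", paste0(cols$qchar, cols$tchar))
  r <- rle(is_match)
  out <- character(length(r$lengths))
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    out[i] <- if (r$values[i]) {
      as.character(r$lengths[i])
    } else {
      paste0(piece[pos:(pos + r$lengths[i] - 1L)], collapse = "")
    }
    pos <- pos + r$lengths[i]
  }
  paste0(out, collapse = "")
}

# One BLAST tabular line (13-column std + btop dialect) for a child-vs-
# parent alignment given its column table.
.cols_to_hsp_line <- function(qid, sid, cols, score_model,
                              q_offset = 0L, s_offset = 0L) {
  aligned <- cols$type == "m"
  n_cols <- nrow(cols)
  n_match <- sum(aligned & cols$qchar == cols$tchar)
  n_mismatch <- sum(aligned & cols$qchar != cols$tchar)
  gap_runs <- rle(cols$type)
  gapopen <- sum(gap_runs$values != "m")
  score <- score_model[[1L]] * n_match - score_model[[2L]] * n_mismatch
  score <- max(score, 1)
  qpos <- cols$qpos[!is.na(cols$qpos)] + q_offset
  tpos <- cols$tpos[!is.na(cols$tpos)] + s_offset
  paste(qid, sid,
        sprintf("%.2f", 100 * n_match / n_cols), n_cols, n_mismatch, gapopen,
        min(qpos), max(qpos), min(tpos), max(tpos),
        "1e-30", sprintf("%.1f", score), .cols_to_btop(cols),
        sep = "\t")
}

#' Generate a synthetic tripartite homology fixture
#'
#' Fabricates target protein sequences, derives each intermediate from a
#' target and each query from an intermediate by point substitution and
#' indels, and emits the two hit files the pipeline consumes:
#' query-vs-intermediate and intermediate-vs-target, as BLAST tabular lines
#' with BTOP tracebacks whose coordinates, column counts and scores are
#' internally consistent. The ground truth records the true query-to-target
#' residue correspondence (the composition of the two derivation
#' alignments). E-values are placeholders (`1e-30`) below any default
#' threshold; scores come from the match/mismatch score model, since the
#' pipeline consumes scores rather than deriving them.
#'
#' @param spec a [fixture_spec()].
#' @return a list with `query_hits` and `target_hits` (character vectors of
#'   file lines), `truth` (data frame `query_id`, `target_id`, `q`, `t`),
#'   and `sequences` (the generated sequences, for inspection).
#' @export
generate_tripartite <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$rng_seed)

  targets <- lapply(seq_len(spec$n_targets), function(i) {
    L <- sample(seq(spec$seq_length[1L], spec$seq_length[2L]), 1L)
    sample(.AA, L, replace = TRUE)
  })
  names(targets) <- sprintf("T%03d", seq_len(spec$n_targets))

  target_lines <- character(spec$n_intermediates)
  inter <- vector("list", spec$n_intermediates)
  inter_parent <- rep_len(seq_len(spec$n_targets), spec$n_intermediates)
  inter_cols <- vector("list", spec$n_intermediates)
  names(inter) <- sprintf("B%03d", seq_len(spec$n_intermediates))
  for (i in seq_len(spec$n_intermediates)) {
    d <- .derive(targets[[inter_parent[i]]], spec$mutation_rate, spec$gap_rate)
    inter[[i]] <- d$child
    inter_cols[[i]] <- d$cols
    target_lines[i] <- .cols_to_hsp_line(names(inter)[i],
                                         names(targets)[inter_parent[i]],
                                         d$cols, spec$score_model)
  }

  query_lines <- character(spec$n_queries)
  query_parent <- rep_len(seq_len(spec$n_intermediates), spec$n_queries)
  truth <- vector("list", spec$n_queries)
  qnames <- sprintf("Q%03d", seq_len(spec$n_queries))
  for (i in seq_len(spec$n_queries)) {
    b <- query_parent[i]
    d <- .derive(inter[[b]], spec$mutation_rate, spec$gap_rate)
    query_lines[i] <- .cols_to_hsp_line(qnames[i], names(inter)[b],
                                        d$cols, spec$score_model)
    # true query -> target correspondence: compose the derivation alignments
    qb <- d$cols[d$cols$type == "m", c("qpos", "tpos")]        # query -> inter
    bt <- inter_cols[[b]][inter_cols[[b]]$type == "m", c("qpos", "tpos")]
    idx <- match(qb$tpos, bt$qpos)
    keep <- !is.na(idx)
    truth[[i]] <- data.frame(
      query_id = qnames[i],
      target_id = names(targets)[inter_parent[b]],
      q = qb$qpos[keep], t = bt$tpos[idx[keep]]
    )
  }

  list(query_hits = query_lines,
       target_hits = target_lines,
       truth = do.call(rbind, truth),
       sequences = list(targets = targets, intermediates = inter))
}

#' Fixture where two intermediates each cover half of the homology
#'
#' Builds the scenario in which no single intermediate spans the query's
#' full homologous region: one target, one query derived from it (point
#' substitutions only), and two intermediates each derived from one half of
#' the target, optionally overlapping in the middle. The direct
#' query-to-target relationship is recoverable only by combining the two
#' transitive alignments; the consensus row must span both halves while
#' each single composed alignment covers one.
#'
#' @param spec a [fixture_spec()]; `n_*` counts are ignored (the scenario
#'   fixes 1 query, 2 intermediates, 1 target).
#' @param overlap number of positions by which the two halves overlap.
#' @return as [generate_tripartite()].
#' @export
split_coverage_fixture <- function(spec = fixture_spec(), overlap = 0L) {
  stopifnot(inherits(spec, "fixture_spec"), overlap >= 0L)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$rng_seed)

  L <- max(spec$seq_length[2L], 40L)
  target <- sample(.AA, L, replace = TRUE)
  half <- L %/% 2L
  regions <- list(B001 = seq_len(half + overlap),
                  B002 = seq.int(half + 1L - overlap, L))

  mutate_pts <- function(s, rate) {
    hit <- stats::runif(length(s)) < rate
    s[hit] <- vapply(s[hit], function(ch) sample(setdiff(.AA, ch), 1L), character(1))
    s
  }
  query <- mutate_pts(target, spec$mutation_rate)
  inter <- lapply(regions, function(r) mutate_pts(target[r], spec$mutation_rate))

  cols_between <- function(a, b, apos, bpos) {
    data.frame(type = "m", qpos = apos, tpos = bpos, qchar = a, tchar = b)
  }
  query_lines <- character(2L)
  target_lines <- character(2L)
  for (i in 1:2) {
    r <- regions[[i]]
    bid <- names(regions)[i]
    # query region vs intermediate (intermediate coords 1..len)
    query_lines[i] <- .cols_to_hsp_line(
      "Q001", bid,
      cols_between(query[r], inter[[i]], r, seq_along(r)),
      spec$score_model)
    # intermediate vs target region
    target_lines[i] <- .cols_to_hsp_line(
      bid, "T001",
      cols_between(inter[[i]], target[r], seq_along(r), r),
      spec$score_model)
  }
  list(query_hits = query_lines,
       target_hits = target_lines,
       truth = data.frame(query_id = "Q001", target_id = "T001",
                          q = seq_len(L), t = seq_len(L)),
       sequences = list(target = target, query = query, intermediates = inter))
}

#' Write a fixture to disk
#'
#' @param fix a fixture from [generate_tripartite()] or
#'   [split_coverage_fixture()].
#' @param dir output directory (created if needed); writes
#'   `query_hits.tsv`, `target_hits.tsv` and `truth.tsv`.
#' @return invisibly, the three file paths.
#' @export
write_fixture <- function(fix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("query_hits.tsv", "target_hits.tsv", "truth.tsv"))
  writeLines(fix$query_hits, paths[1L])
  writeLines(fix$target_hits, paths[2L])
  utils::write.table(fix$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
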