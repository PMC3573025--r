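# End-to-end pipeline: load query->intermediate and intermediate->target
# hit files, compose every transitive alignment, reduce per (query, target)
# to a consensus, rank, and write the report.

#' Pipeline run configuration
#'
#' @param query_hits path to the query-vs-intermediate BLAST tabular file.
#' @param target_hits path to the intermediate-vs-target BLAST tabular file.
#' @param output path for the ranked report ([write_report()] format).
#' @param max_evalue drop HSPs above this E-value at parse time. The
#'   default `1e-4` suits annotation-style searches; relax to `0.1` for
#'   sensitive remote-homology screens.
#' @param min_score drop consensus rows scoring below this (default 0:
#'   report everything, filter downstream).
#' @param max_intermediates keep only the top-scoring k query-vs-intermediate
#'   HSPs per query before composition (`Inf` = unlimited); a tractability
#'   knob for very large intermediate databases.
#' @param top_n report at most this many consensus rows per query.
#' @param log_level `"debug"`, `"info"` or `"quiet"`.
#' @return a `run_config` list.
#' @export
run_config <- function(query_hits, target_hits, output,
                       max_evalue = 1e-4, min_score = 0,
                       max_intermediates = Inf, top_n = Inf,
                       log_level = c("info", "debug", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(max_evalue >= 0, min_score >= 0,
            max_intermediates >= 1, top_n >= 1)
  structure(list(query_hits = query_hits, target_hits = target_hits,
                 output = output, max_evalue = max_evalue,
                 min_score = min_score, max_intermediates = max_intermediates,
                 top_n = top_n, log_level = log_level),
            class = "run_config")
}

.log <- function(config, level, ...) {
  lv <- c(debug = 1L, info = 2L, quiet = 3L)
  if (lv[[level]] >= lv[[config$log_level]]) {
    message(sprintf(...))
  }
}

#' Rank the report rows of one query
#'
#' Stable sort by score descending, ties broken by target ID
#' lexicographically so that the ranking is a deterministic function of the
#' row set (permuting the input leaves the output unchanged).
#'
#' @param rows report rows sharing one `query_id`.
#' @return the rows reordered, with a `rank` column `1..n`.
#' @export
rank_hits <- function(rows) {
  stopifnot(length(unique(rows$query_id)) <= 1L)
  rows <- rows[order(-rows$score, rows$target_id), , drop = FALSE]
  rows$rank <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

# One report row from a consensus result.
.consensus_to_row <- function(cr) {
  m <- cr$record$mapping
  data.frame(
    query_id = cr$record$query_id,
    target_id = cr$record$target_id,
    score = cr$record$total_score,
    n_pairs = nrow(m),
    q_start = min(abs(m$q)), q_end = max(abs(m$q)),
    t_start = min(abs(m$t)), t_end = max(abs(m$t)),
    n_intermediates = nrow(cr$intermediates),
    best_intermediate = if (nrow(cr$intermediates))
      cr$intermediates$intermediate[1L] else "."
  )
}

#' Run the transitive-alignment pipeline
#'
#' For each query with a hit to an intermediate sequence, and each hit of
#' that intermediate to a target, the two alignments are composed into a
#' transitive query-to-target alignment (compositions sharing no
#' intermediate position are dropped). All transitive alignments per
#' (query, target) pair are pooled and reduced to one consensus row, rows
#' are ranked per query by score, and the report is written. The
#' intermediate-to-target file is indexed by intermediate ID once; queries
#' are then processed one at a time.
#'
#' @param config a [run_config()].
#' @return invisibly, a `transalign_summary` with counts of queries,
#'   intermediates, targets, transitive alignments and report rows, plus
#'   the report data frame in `$report`.
#' @export
transalign_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  qh <- read_blast_hits(config$query_hits, max_evalue = config$max_evalue)
  th <- read_blast_hits(config$target_hits, max_evalue = config$max_evalue)

  target_index <- split(seq_len(nrow(th)), th$qseqid)
  target_records <- lapply(seq_len(nrow(th)), function(i) {
    hsp_to_record(th[i, , drop = FALSE], hsp_index = i)
  })

  queries <- unique(qh$qseqid)
  q_index <- split(seq_len(nrow(qh)), qh$qseqid)

  all_rows <- list()
  n_transitive <- 0L
  used_intermediates <- character()
  used_targets <- character()

  for (qid in queries) {
    qi <- q_index[[qid]]
    if (is.finite(config$max_intermediates) &&
        length(qi) > config$max_intermediates) {
      qi <- qi[order(-qh$bitscore[qi])][seq_len(config$max_intermediates)]
    }
    pools <- list()  # per target: list of transitive records
    for (i in qi) {
      f <- hsp_to_record(qh[i, , drop = FALSE], hsp_index = i)
      bridge <- target_index[[f$target_id]]
      if (is.null(bridge)) next
      for (j in bridge) {
        g <- target_records[[j]]
        tr <- compose_alignments(f, g)
        if (is.null(tr)) {
          .log(config, "debug",
               "dropped empty composition %s -> %s -> %s",
               f$query_id, f$target_id, g$target_id)
          next
        }
        n_transitive <- n_transitive + 1L
        used_intermediates <- c(used_intermediates, f$target_id)
        pools[[g$target_id]] <- c(pools[[g$target_id]], list(tr))
      }
    }
    if (length(pools) == 0L) next
    rows <- do.call(rbind, lapply(sort(names(pools)), function(tid) {
      .consensus_to_row(consensus_alignment(pools[[tid]]))
    }))
    rows <- rows[rows$score >= config$min_score, , drop = FALSE]
    if (nrow(rows) == 0L) next
    rows <- rank_hits(rows)
    if (is.finite(config$top_n) && nrow(rows) > config$top_n) {
      rows <- rows[seq_len(config$top_n), , drop = FALSE]
    }
    used_targets <- c(used_targets, rows$target_id)
    all_rows[[qid]] <- rows
  }

  report <- if (length(all_rows)) {
    do.call(rbind, all_rows[order(names(all_rows))])
  } else {
    warning("no transitive alignments survived; writing empty report",
            call. = FALSE)
    data.frame(query_id = character(), target_id = character(),
               score = numeric(), n_pairs = integer(), q_start = integer(),
               q_end = integer(), t_start = integer(), t_end = integer(),
               n_intermediates = integer(), best_intermediate = character(),
               rank = integer())
  }
  rownames(report) <- NULL
  write_report(report, config$output)

  out <- structure(
    list(n_queries = length(queries),
         n_intermediates = length(unique(used_intermediates)),
         n_targets = length(unique(used_targets)),
         n_transitive = n_transitive,
         n_rows = nrow(report),
         report = report),
    class = "transalign_summary")
  .log(config, "info",
       "%d queries, %d intermediates, %d targets; %d transitive alignments -> %d consensus rows",
       out$n_queries, out$n_intermediates, out$n_targets,
       out$n_transitive, out$n_rows)
  invisible(out)
}

#' @export
print.transalign_summary <- function(x, ...) {
  cat(sprintf(paste0("<transalign_summary> %d queries, %d intermediates, ",
                     "%d targets\n  %d transitive alignments -> %d report rows\n"),
              x$n_queries, x$n_intermediates, x$n_targets,
              x$n_transitive, x$n_rows))
  invisible(x)
}
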