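# Reading BLAST tabular results (outfmt 6 "std btop" or "std qseq sseq")
# into alignment records, and the tool's ranked tabular report.

.BLAST_STD_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore")

#' Expand a BTOP traceback string into aligned position pairs
#'
#' BTOP (BLAST traceback operations) encodes an HSP column by column: a run
#' of digits is that many identical match columns; a two-character token is
#' one column, either a mismatch (`query_char` `subject_char`) or a gap
#' (`-` on the gapped side). Match and mismatch columns align one query
#' position with one subject position and emit a pair; a gap column
#' advances only the ungapped side and emits nothing. The query advances by
#' `q_step` per consumed column — 1 for protein queries, 3 for translated
#' nucleotide queries, where a column's query coordinate is the first base
#' of its codon.
#'
#' Reverse-strand or negative-frame coordinates are handled by the caller
#' passing negated, ascending start positions (see [hsp_to_record()]).
#'
#' @param btop BTOP string.
#' @param q_start,s_start coordinates of the first aligned column.
#' @param q_step query advance per query-consuming column (1 or 3).
#' @return a data frame with columns `q` and `t`, one row per aligned
#'   (match or mismatch) column, plus attributes `q_span` and `s_span`
#'   giving the total coordinate extent consumed on each side.
#' @export
#' @examples
#' expand_btop("2A-2", 1, 10)  # the "A-" column consumes the query only
expand_btop <- function(btop, q_start, s_start, q_step = 1L) {
  toks <- regmatches(btop, gregexpr("[0-9]+|[A-Za-z*-][A-Za-z*-]", btop))[[1L]]
  if (sum(nchar(toks)) != nchar(btop)) {
    stop(sprintf("malformed BTOP string near offset %d: '%s'",
                 sum(nchar(toks)) + 1L, btop), call. = FALSE)
  }
  is_run <- grepl("^[0-9]", toks)
  first <- substr(toks, 1L, 1L)
  second <- substr(toks, 2L, 2L)
  if (any(!is_run & first == "-" & second == "-")) {
    stop("malformed BTOP string: '--' column (gap on both sides)", call. = FALSE)
  }
  # column type: "m" match/mismatch, "qg" gap in query (consumes t only),
  # "tg" gap in subject (consumes q only)
  tok_type <- ifelse(is_run, "m",
                     ifelse(first == "-", "qg",
                            ifelse(second == "-", "tg", "m")))
  reps <- rep(1L, length(toks))
  reps[is_run] <- as.integer(toks[is_run])
  type <- rep(tok_type, reps)
  consume_q <- type != "qg"
  consume_t <- type != "tg"
  qpos <- ifelse(consume_q, q_start + q_step * (cumsum(consume_q) - 1L), NA_integer_)
  tpos <- ifelse(consume_t, s_start + (cumsum(consume_t) - 1L), NA_integer_)
  emit <- type == "m"
  out <- data.frame(q = as.integer(qpos[emit]), t = as.integer(tpos[emit]))
  attr(out, "q_span") <- sum(consume_q) * abs(q_step)
  attr(out, "s_span") <- sum(consume_t)
  attr(out, "n_gap_cols") <- sum(!emit)
  out
}

# Convert aligned (gapped) query/subject strings into an equivalent BTOP
# string, so both input dialects share one expansion path.
.aligned_to_btop <- function(qseq, sseq) {
  qc <- strsplit(qseq, "", fixed = TRUE)[[1L]]
  sc <- strsplit(sseq, "", fixed = TRUE)[[1L]]
  if (length(qc) != length(sc)) {
    stop("aligned query and subject strings differ in length", call. = FALSE)
  }
  match_col <- qc == sc & qc != "-"
  out <- character(length(qc))
  out[match_col] <- "1"
  out[!match_col] <- paste0(qc[!match_col], sc[!match_col])
  # collapse match runs into counts
  r <- rle(match_col)
  pieces <- character(length(r$lengths))
  pos <- 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i]) {
      pieces[i] <- as.character(r$lengths[i])
    } else {
      pieces[i] <- paste0(out[pos:(pos + r$lengths[i] - 1L)], collapse = "")
    }
    pos <- pos + r$lengths[i]
  }
  paste0(pieces, collapse = "")
}

#' Read a BLAST tabular hit file
#'
#' Accepts the tab-separated `outfmt 6` dialect with the 12 standard
#' columns followed by either a `btop` column (13 columns) or `qseq` and
#' `sseq` columns (14 columns); `#` comment lines are ignored. Each data
#' line becomes one HSP row. Lines that are malformed — wrong field count,
#' unparseable numbers, negative scores, or coordinate spans inconsistent
#' with the expanded traceback — are rejected with a warning naming the
#' line number and reason; the remaining rows are returned. A file whose
#' column count matches neither dialect raises an unsupported-dialect
#' error.
#'
#' @param path file path (or connection) to read.
#' @param max_evalue drop HSPs with E-value above this threshold.
#' @return a data frame of HSP rows with the standard columns plus `btop`
#'   (aligned-sequence input is converted to BTOP on the fly) and `line`
#'   (source line number). Rejected lines are recorded in the `rejected`
#'   attribute as a data frame of `line` and `reason`.
#' @export
read_blast_hits <- function(path, max_evalue = Inf) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    out <- .empty_hsp_frame()
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  n_expected <- unique(nf[nf %in% c(13L, 14L)])
  if (length(n_expected) == 0L) {
    stop("unsupported BLAST tabular dialect: expected 12 standard columns ",
         "plus 'btop' (13 columns) or 'qseq sseq' (14 columns); ",
         "use -outfmt '6 std btop'", call. = FALSE)
  }

  rej_line <- integer()
  rej_reason <- character()
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (!(length(f) %in% c(13L, 14L))) {
      rej_line <- c(rej_line, lineno[i])
      rej_reason <- c(rej_reason, sprintf("expected 13 or 14 fields, got %d",
                                          length(f)))
      next
    }
    num <- suppressWarnings(as.numeric(f[c(3L, 11L, 12L)]))
    ints <- suppressWarnings(as.integer(f[4:10]))
    if (anyNA(num) || anyNA(ints)) {
      rej_line <- c(rej_line, lineno[i])
      rej_reason <- c(rej_reason, "unparseable numeric field")
      next
    }
    if (num[3L] < 0) {
      rej_line <- c(rej_line, lineno[i])
      rej_reason <- c(rej_reason, "negative bit score")
      next
    }
    btop <- if (length(f) == 13L) f[13L] else
      tryCatch(.aligned_to_btop(f[13L], f[14L]), error = function(e) NA_character_)
    if (is.na(btop)) {
      rej_line <- c(rej_line, lineno[i])
      rej_reason <- c(rej_reason, "inconsistent qseq/sseq columns")
      next
    }
    row <- data.frame(
      qseqid = f[1L], sseqid = f[2L], pident = num[1L], length = ints[1L],
      mismatch = ints[2L], gapopen = ints[3L], qstart = ints[4L],
      qend = ints[5L], sstart = ints[6L], send = ints[7L],
      evalue = num[2L], bitscore = num[3L], btop = btop, line = lineno[i]
    )
    chk <- tryCatch(.check_hsp_spans(row), error = function(e) conditionMessage(e))
    if (is.character(chk)) {
      rej_line <- c(rej_line, lineno[i])
      rej_reason <- c(rej_reason, chk)
      next
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else .empty_hsp_frame()
  rownames(out) <- NULL
  if (length(rej_line)) {
    warning(sprintf("rejected %d malformed line(s): %s", length(rej_line),
                    paste(sprintf("line %d (%s)", rej_line, rej_reason),
                          collapse = "; ")), call. = FALSE)
  }
  out <- out[out$evalue <= max_evalue, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- data.frame(line = rej_line, reason = rej_reason)
  out
}

.empty_hsp_frame <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = integer(), mismatch = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             btop = character(), line = integer())
}

# Infer query step (1 = protein-coordinate query, 3 = translated nucleotide
# query) and verify that the HSP's coordinate spans agree with its expanded
# traceback; errors with a coordinate-inconsistency message otherwise.
.check_hsp_spans <- function(h) {
  exp1 <- expand_btop(h$btop, 1L, 1L, q_step = 1L)
  s_span <- abs(h$send - h$sstart) + 1L
  q_span <- abs(h$qend - h$qstart) + 1L
  if (attr(exp1, "s_span") != s_span) {
    stop(sprintf(
      "coordinate inconsistency: subject span %d but traceback consumes %d",
      s_span, attr(exp1, "s_span")), call. = FALSE)
  }
  q_cols <- attr(exp1, "q_span")  # query-consuming columns at step 1
  if (q_span == q_cols) {
    q_step <- 1L
  } else if (q_span == 3L * q_cols) {
    q_step <- 3L
  } else {
    stop(sprintf(
      "coordinate inconsistency: query span %d matches neither %d protein columns nor %d nucleotides",
      q_span, q_cols, 3L * q_cols), call. = FALSE)
  }
  q_step
}

#' Convert an HSP row into an alignment record
#'
#' Expands the HSP's traceback into per-column `(q, t)` pairs, assigns each
#' pair the evenly distributed bit score ([distribute_score()]), and
#' normalizes strand: descending subject coordinates (minus-strand
#' nucleotide hits) and descending query coordinates (negative-frame
#' translated queries) are stored negated so every mapping is monotonically
#' increasing. The query step is inferred from the coordinate spans: a
#' translated nucleotide query consumes 3 bases per column and its
#' coordinates are the first base of each codon.
#'
#' @param h a single row from [read_blast_hits()].
#' @param hsp_index provenance index stored on the record.
#' @return an [alignment_record()] whose `total_score` reproduces the HSP
#'   bit score to within `1e-6`.
#' @export
hsp_to_record <- function(h, hsp_index = NA_integer_) {
  stopifnot(nrow(h) == 1L)
  q_step <- .check_hsp_spans(h)
  q_rev <- h$qstart > h$qend
  s_rev <- h$sstart > h$send
  q0 <- if (q_rev) -h$qstart else h$qstart
  s0 <- if (s_rev) -h$sstart else h$sstart
  pairs <- expand_btop(h$btop, q0, s0, q_step = q_step)
  n_pairs <- nrow(pairs)
  if (n_pairs == 0L) {
    stop("invalid alignment: HSP has no aligned residue pairs", call. = FALSE)
  }
  w <- distribute_score(h$bitscore, n_pairs)
  alignment_record(
    query_id = h$qseqid, target_id = h$sseqid,
    mapping = position_mapping(pairs$q, pairs$t, w),
    provenance = list(type = "direct", hsp = hsp_index),
    total_score = h$bitscore
  )
}

#' Convert a parsed hit table into a hit set
#'
#' @param hsps a data frame from [read_blast_hits()].
#' @return a [hit_set()] with one record per HSP row.
#' @export
hits_to_records <- function(hsps) {
  hit_set(lapply(seq_len(nrow(hsps)), function(i) {
    hsp_to_record(hsps[i, , drop = FALSE], hsp_index = i)
  }))
}

.REPORT_COLS <- c("query_id", "target_id", "score", "n_pairs", "q_start",
                  "q_end", "t_start", "t_end", "n_intermediates",
                  "best_intermediate")

#' Write the ranked transitive-alignment report
#'
#' Tab-separated with one `#`-prefixed header line naming the columns.
#' Rows are grouped by query and sorted by score descending within each
#' query (ties broken by target ID); scores are printed with one decimal
#' place. [read_report()] parses the format back to identical values.
#'
#' @param rows a data frame of report rows (see [transalign_run()]).
#' @param path output file path or connection.
#' @return `invisible(rows)` as written (reordered).
#' @export
write_report <- function(rows, path) {
  stopifnot(all(.REPORT_COLS %in% names(rows)))
  rows <- rows[order(rows$query_id, -rows$score, rows$target_id), .REPORT_COLS,
               drop = FALSE]
  lines <- c(
    paste0("#", paste(.REPORT_COLS, collapse = "\t")),
    if (nrow(rows)) {
      paste(rows$query_id, rows$target_id, sprintf("%.1f", rows$score),
            rows$n_pairs, rows$q_start, rows$q_end, rows$t_start, rows$t_end,
            rows$n_intermediates, rows$best_intermediate, sep = "\t")
    }
  )
  writeLines(lines, path)
  invisible(rows)
}

#' Read a transitive-alignment report written by [write_report()]
#'
#' @param path file path or connection.
#' @return a data frame with the report columns.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(), target_id = character(),
                      score = numeric(), n_pairs = integer(),
                      q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      n_intermediates = integer(),
                      best_intermediate = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(f) == length(.REPORT_COLS)))
  m <- do.call(rbind, f)
  data.frame(
    query_id = m[, 1L], target_id = m[, 2L], score = as.numeric(m[, 3L]),
    n_pairs = as.integer(m[, 4L]), q_start = as.integer(m[, 5L]),
    q_end = as.integer(m[, 6L]), t_start = as.integer(m[, 7L]),
    t_end = as.integer(m[, 8L]), n_intermediates = as.integer(m[, 9L]),
    best_intermediate = m[, 10L]
  )
}
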