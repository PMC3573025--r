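# Shared generators and independent oracles for the test suite.

# A random valid position mapping: distinct sorted q and t guarantee the
# one-to-one and monotonicity invariants by construction.
random_valid_mapping <- function(n, qmax = 4L * n, tmax = 4L * n,
                                 wmax = 10, negate_q = FALSE, negate_t = FALSE) {
  q <- sort(sample.int(qmax, n))
  t <- sort(sample.int(tmax, n))
  if (negate_q) q <- sort(-q)
  if (negate_t) t <- sort(-t)
  position_mapping(q, t, stats::runif(n, 0, wmax))
}

random_record <- function(query_id, target_id, n, ...) {
  alignment_record(query_id, target_id, random_valid_mapping(n, ...))
}

# A random pair pool on a grid: distinct (q, t) cells with random weights.
random_pool_df <- function(n, qmax, tmax, wmax = 10) {
  if (n == 0L) {
    pool <- data.frame(q = integer(), t = integer(), w = numeric(),
                       source = character())
    attr(pool, "query_id") <- "q"
    attr(pool, "target_id") <- "t"
    attr(pool, "n_alignments") <- 1L
    class(pool) <- c("pair_pool", "data.frame")
    return(pool)
  }
  cells <- sample.int(qmax * tmax, n)
  q <- ((cells - 1L) %% qmax) + 1L
  t <- ((cells - 1L) %/% qmax) + 1L
  pool <- data.frame(q = q, t = t, w = stats::runif(n, 0, wmax),
                     source = "x")
  pool <- pool[order(pool$q, pool$t), , drop = FALSE]
  rownames(pool) <- NULL
  attr(pool, "query_id") <- "q"
  attr(pool, "target_id") <- "t"
  attr(pool, "n_alignments") <- 1L
  class(pool) <- c("pair_pool", "data.frame")
  pool
}

# Independent brute-force oracle for the consensus optimum: exhaustively
# enumerates every subset of pool pairs that forms a strictly increasing
# chain in both coordinates, and returns the maximum summed weight.
# Exponential; only for small pools.
brute_force_consensus <- function(pool) {
  n <- nrow(pool)
  if (n == 0L) return(0)
  ord <- order(pool$q, pool$t)
  q <- pool$q[ord]; t <- pool$t[ord]; w <- pool$w[ord]
  best <- 0
  rec <- function(i, lq, lt, s) {
    if (s > best) best <<- s
    if (i > n) return()
    rec(i + 1L, lq, lt, s)                       # skip pair i
    if (q[i] > lq && t[i] > lt) {
      rec(i + 1L, q[i], t[i], s + w[i])          # take pair i
    }
  }
  rec(1L, -Inf, -Inf, 0)
  best
}

# A random HSP as a BLAST tabular line (13-column std + btop), built from a
# random column structure so coordinates, btop and counts are consistent by
# construction. Returns the line plus the quantities a parser must recover.
random_hsp_line <- function(qid = "q1", sid = "s1", n_cols = 30L,
                            gap_prob = 0.1, mismatch_prob = 0.15,
                            q_start = NULL, s_start = NULL) {
  aa <- LETTERS[!LETTERS %in% c("B", "J", "O", "U", "X", "Z")]
  type <- sample(c("m", "mm", "qg", "tg"), n_cols, replace = TRUE,
                 prob = c(1 - gap_prob - mismatch_prob, mismatch_prob,
                          gap_prob / 2, gap_prob / 2))
  type[1L] <- "m"; type[n_cols] <- "m"   # BLAST HSPs never end in a gap
  piece <- character(n_cols)
  piece[type == "m"] <- "1"
  nmm <- sum(type == "mm")
  piece[type == "mm"] <- paste0(sample(aa, nmm, TRUE), sample(aa, nmm, TRUE))
  piece[type == "qg"] <- paste0("-", sample(aa, sum(type == "qg"), TRUE))
  piece[type == "tg"] <- paste0(sample(aa, sum(type == "tg"), TRUE), "-")
  # collapse runs of "1" into counts
  r <- rle(piece == "1")
  btop <- character(length(r$lengths)); pos <- 1L
  for (i in seq_along(r$lengths)) {
    btop[i] <- if (r$values[i]) as.character(r$lengths[i]) else
      paste0(piece[pos:(pos + r$lengths[i] - 1L)], collapse = "")
    pos <- pos + r$lengths[i]
  }
  btop <- paste0(btop, collapse = "")
  n_pairs <- sum(type %in% c("m", "mm"))
  q_cols <- sum(type != "qg")
  t_cols <- sum(type != "tg")
  if (is.null(q_start)) q_start <- sample.int(100L, 1L)
  if (is.null(s_start)) s_start <- sample.int(100L, 1L)
  score <- round(stats::runif(1, 20, 500), 1)
  line <- paste(qid, sid, "50.00", n_cols, nmm,
                sum(rle(type)$values %in% c("qg", "tg")),
                q_start, q_start + q_cols - 1L,
                s_start, s_start + t_cols - 1L,
                "1e-30", sprintf("%.1f", score), btop, sep = "\t")
  list(line = line, btop = btop, score = score, n_pairs = n_pairs,
       q_cols = q_cols, t_cols = t_cols, n_cols = n_cols)
}

# Replace a fixture's intermediate->target file with perfect full-length
# self-alignments of each intermediate, under a very large score.
identity_bridge_lines <- function(fix) {
  inter <- fix$sequences$intermediates
  vapply(names(inter), function(b) {
    L <- length(inter[[b]])
    paste(b, b, "100.00", L, 0L, 0L, 1L, L, 1L, L, "1e-30", "1e6",
          as.character(L), sep = "\t")
  }, character(1))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
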