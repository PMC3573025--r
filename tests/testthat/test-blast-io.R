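test_that("BTOP expansion walks matches, mismatches and gaps correctly", {
  e <- expand_btop("5", 1, 10)
  expect_identical(e$q, 1:5)
  expect_identical(e$t, 10:14)
  # gap in subject consumes the query only
  e <- expand_btop("2A-2", 1, 10)
  expect_identical(e$q, c(1L, 2L, 4L, 5L))
  expect_identical(e$t, 10:13)
  # gap in query consumes the subject only
  e <- expand_btop("2-G2", 1, 10)
  expect_identical(e$q, 1:4)
  expect_identical(e$t, c(10L, 11L, 13L, 14L))
  # mismatch emits a pair
  e <- expand_btop("1AG1", 1, 1)
  expect_identical(nrow(e), 3L)
  # translated query advances three bases per column
  e <- expand_btop("3", 10, 5, q_step = 3)
  expect_identical(e$q, c(10L, 13L, 16L))
  expect_identical(e$t, 5:7)
  expect_error(expand_btop("2A", 1, 1), "malformed BTOP")
  expect_error(expand_btop("2--2", 1, 1), "gap on both sides")
})

test_that("pair count plus gap columns equals total column count", {
  set.seed(8)
  for (i in 1:100) {
    h <- random_hsp_line(n_cols = sample(10:60, 1))
    e <- expand_btop(h$btop, 1, 1)
    expect_identical(nrow(e), h$n_pairs)
    expect_identical(nrow(e) + attr(e, "n_gap_cols"), h$n_cols)
    expect_identical(attr(e, "q_span"), h$q_cols)
    expect_identical(attr(e, "s_span"), h$t_cols)
  }
})

test_that("tabular parsing accepts both dialects and skips comments", {
  set.seed(21)
  lines <- c("# BLASTP 2.x", vapply(1:5, function(i) random_hsp_line()$line,
                                    character(1)))
  f <- write_lines_tmp(lines)
  hs <- read_blast_hits(f)
  expect_identical(nrow(hs), 5L)
  expect_identical(hs$line, 2:6)
  # comment-only file
  f2 <- write_lines_tmp(c("# nothing", "# here"))
  expect_identical(nrow(read_blast_hits(f2)), 0L)
  # qseq/sseq dialect converts to the same mapping as btop
  line14 <- paste("q", "s", "80.00", 5, 1, 1, 1, 4, 10, 14, "1e-5", "20.0",
                  "AC-DE", "ACKDF", sep = "\t")
  f3 <- write_lines_tmp(line14)
  hs3 <- read_blast_hits(f3)
  expect_identical(nrow(hs3), 1L)
  e <- expand_btop(hs3$btop, 1, 10)
  expect_identical(e$q, c(1L, 2L, 3L, 4L))
  expect_identical(e$t, c(10L, 11L, 13L, 14L))
})

test_that("malformed and inconsistent lines are rejected with line numbers", {
  set.seed(22)
  good <- random_hsp_line()$line
  fields <- strsplit(good, "\t")[[1]]
  fields[8] <- as.character(as.integer(fields[8]) + 5L)  # qend off by 5
  bad_span <- paste(fields, collapse = "\t")
  f <- write_lines_tmp(c(good, bad_span, "too\tfew\tfields"))
  expect_warning(hs <- read_blast_hits(f), "rejected 2 malformed")
  expect_identical(nrow(hs), 1L)
  rej <- attr(hs, "rejected")
  expect_identical(rej$line, 2:3)
  expect_match(rej$reason[1], "coordinate inconsistency")
  # negative score rejected at parse time
  fields2 <- strsplit(good, "\t")[[1]]
  fields2[12] <- "-5.0"
  expect_warning(read_blast_hits(write_lines_tmp(paste(fields2, collapse = "\t"))),
                 "negative bit score")
  # a file in neither dialect errors outright
  expect_error(read_blast_hits(write_lines_tmp("a\tb\tc")),
               "unsupported BLAST tabular dialect")
})

test_that("HSP records distribute the bit score over aligned pairs only", {
  line <- paste("q", "s", "100.00", 50, 0, 0, 1, 50, 10, 59, "1e-30", "100.0",
                "50", sep = "\t")
  h <- read_blast_hits(write_lines_tmp(line))
  rec <- hsp_to_record(h)
  expect_identical(nrow(rec$mapping), 50L)
  expect_equal(unique(rec$mapping$w), 2)
  expect_equal(rec$total_score, 100)
  # gap columns excluded from n_pairs: 53 columns, 3 gaps -> 50 pairs
  line2 <- paste("q", "s", "90.00", 53, 0, 2, 1, 51, 10, 61, "1e-30", "100.0",
                 "20A-10-C-G20", sep = "\t")
  h2 <- read_blast_hits(write_lines_tmp(line2))
  rec2 <- hsp_to_record(h2)
  expect_identical(nrow(rec2$mapping), 50L)
  expect_equal(unique(rec2$mapping$w), 100 / 50)
})

test_that("reverse strands and negative frames are stored negated and monotonic", {
  # minus-strand subject: sstart > send
  line <- paste("q", "s", "100.00", 10, 0, 0, 1, 10, 50, 41, "1e-30", "30.0",
                "10", sep = "\t")
  rec <- hsp_to_record(read_blast_hits(write_lines_tmp(line)))
  expect_true(all(rec$mapping$t < 0))
  expect_true(validate_mapping(rec$mapping)$ok)
  expect_identical(abs(rec$mapping$t[1]), 50L)  # first column hits position 50
  # negative-frame translated query: qstart > qend, 3 nt per column
  line2 <- paste("q", "s", "100.00", 10, 0, 0, 30, 1, 5, 14, "1e-30", "30.0",
                 "10", sep = "\t")
  rec2 <- hsp_to_record(read_blast_hits(write_lines_tmp(line2)))
  expect_true(all(rec2$mapping$q < 0))
  expect_true(all(diff(rec2$mapping$q) == 3L))
  expect_true(validate_mapping(rec2$mapping)$ok)
  # score still reconstructs
  expect_equal(sum(rec2$mapping$w), 30, tolerance = 1e-6)
})

test_that("per-pair scores of parsed HSPs sum back to the bit score", {
  set.seed(31)
  lines <- vapply(1:50, function(i) random_hsp_line(n_cols = sample(10:80, 1))$line,
                  character(1))
  hs <- read_blast_hits(write_lines_tmp(lines))
  for (i in seq_len(nrow(hs))) {
    rec <- hsp_to_record(hs[i, , drop = FALSE], hsp_index = i)
    expect_equal(rec$total_score, hs$bitscore[i], tolerance = 1e-6)
    expect_equal(sum(rec$mapping$w), hs$bitscore[i], tolerance = 1e-6)
  }
})

test_that("the report format round-trips: write -> parse -> write is byte-identical", {
  set.seed(61)
  rows <- data.frame(
    query_id = sample(sprintf("q%02d", 1:5), 20, TRUE),
    target_id = sprintf("t%02d", sample(100, 20)),
    score = round(stats::runif(20, 1, 500), 1),
    n_pairs = sample.int(200L, 20), q_start = 1L, q_end = 10L,
    t_start = 5L, t_end = 14L, n_intermediates = sample.int(4L, 20, replace = TRUE),
    best_intermediate = sprintf("b%02d", sample(30, 20))
  )
  f1 <- tempfile(); f2 <- tempfile()
  write_report(rows, f1)
  back <- read_report(f1)
  write_report(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # scores descending within each query in the file
  for (qid in unique(back$query_id)) {
    expect_false(is.unsorted(rev(back$score[back$query_id == qid])))
  }
  # empty report: header only
  f3 <- tempfile()
  write_report(rows[0, ], f3)
  expect_identical(length(readLines(f3)), 1L)
  expect_match(readLines(f3), "^#query_id")
})

test_that("E-value threshold filters at parse time", {
  set.seed(71)
  mk <- function(ev) {
    fields <- strsplit(random_hsp_line()$line, "\t")[[1]]
    fields[11] <- ev
    paste(fields, collapse = "\t")
  }
  f <- write_lines_tmp(c(mk("1e-10"), mk("0.05"), mk("10")))
  expect_identical(nrow(read_blast_hits(f)), 3L)
  expect_identical(nrow(read_blast_hits(f, max_evalue = 0.1)), 2L)
  expect_identical(nrow(read_blast_hits(f, max_evalue = 1e-4)), 1L)
})
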