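test_that("pair pool keeps the maximal score per (q, t) cell", {
  a1 <- alignment_record("u", "t", position_mapping(c(3L, 4L), c(7L, 8L), c(1.5, 1)),
                         provenance = list(type = "transitive", intermediate = "b1"))
  a2 <- alignment_record("u", "t", position_mapping(3L, 7L, 2.0),
                         provenance = list(type = "transitive", intermediate = "b2"))
  pool <- build_pair_pool(list(a1, a2))
  cell <- pool[pool$q == 3 & pool$t == 7, ]
  expect_equal(cell$w, 2.0)
  expect_identical(cell$source, "b2")
  # a single alignment pools to exactly its pairs
  p1 <- build_pair_pool(list(a1))
  expect_equal(p1$q, a1$mapping$q)
  expect_equal(p1$w, a1$mapping$w)
  # disjoint alignments pool to their union
  a3 <- alignment_record("u", "t", position_mapping(10L, 20L, 1),
                         provenance = list(type = "transitive", intermediate = "b3"))
  expect_identical(nrow(build_pair_pool(list(a1, a2, a3))), 3L)
  expect_error(build_pair_pool(list(a1, alignment_record("x", "t", position_mapping(1L, 1L, 1)))),
               "share one")
})

test_that("dense consensus solves colinear and crossing toy pools", {
  pool <- random_pool_df(0, 1, 1)
  colinear <- pool[0, ]
  p <- data.frame(q = c(1L, 2L), t = c(1L, 2L), w = c(5, 5), source = "x")
  class(p) <- class(pool)
  expect_equal(consensus_dense(p)$score, 10)
  expect_identical(consensus_dense(p)$chosen, 1:2)
  cross <- data.frame(q = c(1L, 2L), t = c(2L, 1L), w = c(5, 5), source = "x")
  class(cross) <- class(pool)
  sol <- consensus_dense(cross)
  expect_equal(sol$score, 5)
  expect_identical(length(sol$chosen), 1L)
  expect_equal(consensus_dense(pool[0, ])$score, 0)
})

test_that("dense consensus matches the brute-force oracle on random pools", {
  set.seed(123)
  for (i in 1:150) {
    pool <- random_pool_df(sample(1:12, 1), 8L, 8L)
    expect_equal(consensus_dense(pool)$score, brute_force_consensus(pool),
                 tolerance = 1e-12)
  }
})

test_that("sparse chaining equals dense DP in optimum", {
  set.seed(321)
  for (i in 1:40) {
    n <- sample(c(1:5, 50, 200, 500), 1)
    pool <- random_pool_df(n, 40L, 40L)
    expect_equal(consensus_sparse(pool)$score, consensus_dense(pool)$score,
                 tolerance = 1e-9)
  }
  # staircase: all pairs chosen
  stair <- random_pool_df(1, 1, 1)
  k <- 10L
  p <- data.frame(q = 1:k, t = 1:k, w = 1, source = "x")
  class(p) <- class(stair)
  expect_equal(consensus_sparse(p)$score, k)
  expect_identical(consensus_sparse(p)$chosen, 1:k)
  single <- p[1, , drop = FALSE]
  expect_equal(consensus_sparse(single)$score, 1)
})

test_that("the chosen subsets from both solvers are valid and score-consistent", {
  set.seed(77)
  for (i in 1:30) {
    pool <- random_pool_df(sample(5:80, 1), 30L, 30L)
    for (solver in list(consensus_dense, consensus_sparse)) {
      sol <- solver(pool)
      sel <- pool[sol$chosen, ]
      expect_true(validate_mapping(sel)$ok)
      expect_equal(sum(sel$w), sol$score, tolerance = 1e-9)
    }
  }
})

test_that("adding a pair never decreases the optimum; any member is a lower bound", {
  set.seed(55)
  for (i in 1:25) {
    pool <- random_pool_df(sample(5:40, 1), 20L, 20L)
    base <- consensus_dense(pool)$score
    # grow: add one new random cell
    free <- setdiff(seq_len(400L), (pool$t - 1L) * 20L + pool$q)
    cell <- sample(free, 1)
    extra <- data.frame(q = ((cell - 1L) %% 20L) + 1L,
                        t = ((cell - 1L) %/% 20L) + 1L,
                        w = stats::runif(1, 0, 10), source = "x")
    grown <- rbind(as.data.frame(pool), extra)
    class(grown) <- class(pool)
    expect_gte(consensus_dense(grown)$score, base - 1e-12)
  }
})

test_that("consensus over a set dominates every contributing alignment", {
  set.seed(19)
  for (i in 1:25) {
    recs <- lapply(1:3, function(k) {
      alignment_record("u", "t", random_valid_mapping(sample(3:12, 1), 30L, 30L),
                       provenance = list(type = "transitive",
                                         intermediate = paste0("b", k)))
    })
    cr <- consensus_alignment(recs)
    for (r in recs) {
      expect_gte(cr$record$total_score, r$total_score - 1e-9)
    }
    expect_true(validate_mapping(cr$record$mapping)$ok)
  }
})

test_that("consensus over a singleton conserves the original score exactly", {
  set.seed(4)
  # scores that do not divide evenly across pairs still sum back
  rec <- alignment_record("u", "t",
    position_mapping(1:7, 11:17, distribute_score(37, 7)),
    provenance = list(type = "direct", hsp = 1L), total_score = 37)
  cr <- consensus_alignment(list(rec))
  expect_equal(cr$record$total_score, 37, tolerance = 1e-6)
  expect_equal(cr$record$mapping$q, rec$mapping$q)
  # empty set
  cr0 <- consensus_alignment(list())
  expect_equal(cr0$record$total_score, 0)
  expect_identical(nrow(cr0$record$mapping), 0L)
})

test_that("mixed-strand pools report the better-scoring strand only", {
  plus <- alignment_record("u", "t", position_mapping(1:3, 1:3, 2),
                           provenance = list(type = "transitive", intermediate = "bp"))
  minus <- alignment_record("u", "t", position_mapping(1:5, -(9:5)[order(-(9:5))], 3),
                            provenance = list(type = "transitive", intermediate = "bm"))
  cr <- consensus_alignment(list(plus, minus))
  expect_true(all(cr$record$mapping$t < 0))
  expect_equal(cr$record$total_score, 15)
  expect_identical(cr$intermediates$intermediate, "bm")
})

test_that("contributing intermediates are listed by descending score mass", {
  a1 <- alignment_record("u", "t", position_mapping(1:2, 1:2, 1),
                         provenance = list(type = "transitive", intermediate = "small"))
  a2 <- alignment_record("u", "t", position_mapping(3:6, 3:6, 5),
                         provenance = list(type = "transitive", intermediate = "big"))
  cr <- consensus_alignment(list(a1, a2))
  expect_identical(cr$intermediates$intermediate, c("big", "small"))
  expect_equal(cr$intermediates$score_mass, c(20, 2))
  expect_equal(cr$record$total_score, 22)
})
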