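test_that("component length score has the closed form and rejects odd input", {
  expect_equal(f_score(2, L = 8), 1)
  expect_equal(f_score(8, L = 8), 0)
  expect_equal(f_score(14, L = 8), -1)
  expect_equal(f_score(4, L = 8), 2 / 3)
  expect_error(f_score(3, L = 8), "even")
  expect_error(f_score(0, L = 8), "even|>= 2")
  expect_error(f_score(2, L = 7), "even")
})

test_that("balanced content takes per-family minima", {
  expect_equal(balanced_content(c(1, 2, 2, 3), c(2, 3, 3, 4)),
               c("2" = 1L, "3" = 1L))
  expect_equal(balanced_content(c(1, 2), c(1, 2)), c("1" = 1L, "2" = 1L))
  expect_equal(length(balanced_content(c(1, 2), c(3, 4))), 0L)
})

test_that("local DCJ similarity reproduces the worked examples", {
  expect_equal(local_dcj_similarity(c(1, 2, 3), c(1, 2, 3))$score, 3)
  expect_equal(local_dcj_similarity(c(1, 2, 3), c(1, -2, 3))$score, 5 / 3)
  r <- local_dcj_similarity(c(1, 4, 2, 3), c(1, 2, 3))
  expect_equal(r$score, 2.75)
  expect_equal(r$d, 1L)
})

test_that("self-similarity of a non-duplicated sequence of length n equals n", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(1:7, 1)
    v <- sample(n) * sample(c(-1, 1), n, replace = TRUE)
    expect_equal(local_dcj_similarity(v, v)$score, n)
  }
})

test_that("deletions cost exactly p each and score is monotone in p", {
  s <- c(1, 2, 3, 4)
  base <- local_dcj_similarity(s, s, p = 0.25)$score
  # one unmatched marker on one side
  expect_equal(local_dcj_similarity(c(1, 2, 9, 3, 4), s, p = 0.25)$score,
               base - 0.25)
  expect_equal(local_dcj_similarity(c(1, 2, 9, 3, 4), s, p = 2)$score,
               base - 2)
  set.seed(22)
  for (rep in 1:10) {
    a <- rand_dup_seq(6); b <- rand_dup_seq(6)
    lo <- local_dcj_similarity(a, b, p = 0.1)$score
    hi <- local_dcj_similarity(a, b, p = 0.9)$score
    expect_gte(lo, hi)
  }
})

test_that("disjoint contents score the full deletion penalty with no matches", {
  r <- local_dcj_similarity(c(1, 2), c(3, 4, 5), p = 0.25)
  expect_equal(r$score, -(2 + 3) * 0.25)
  expect_equal(nrow(r$matched), 0L)
})

test_that("reported d is consistent with the matched pairs", {
  set.seed(23)
  for (rep in 1:15) {
    a <- rand_dup_seq(sample(3:7, 1)); b <- rand_dup_seq(sample(3:7, 1))
    r <- local_dcj_similarity(a, b)
    expect_equal(r$d, length(a) + length(b) - 2L * nrow(r$matched))
    expect_true(all(table(r$matched$ref_pos) == 1))
    expect_true(all(table(r$matched$tgt_pos) == 1))
  }
})

test_that("optimizer equals the exhaustive oracle on random duplicated pairs", {
  set.seed(24)
  for (rep in 1:20) {
    a <- rand_dup_seq(sample(3:7, 1)); b <- rand_dup_seq(sample(3:7, 1))
    r <- local_dcj_similarity(a, b)
    expect_true(r$exact)
    expect_equal(r$score, oracle_local_dcj(a, b), tolerance = 1e-10)
  }
})

test_that("block scoring pairs the reference with every other occurrence", {
  m <- dplyr::bind_rows(marker_genome(list(c(1, 2, 3, 4)), "A"),
                        marker_genome(list(c(1, 2, 3, 4)), "B"),
                        marker_genome(list(c(1, 2, -3, 4)), "C"))
  b <- discover_blocks(m, "A", delta_table("default"), quorum = 2,
                       min_ref_size = 4)
  sc <- score_block_set(b, m)
  expect_equal(sort(unique(sc$genome)), c("B", "C"))
  full <- sc[sc$block_id == sc$block_id[which.max(sc$end - sc$start)], ]
  identical_occ <- full[full$genome == "B" & full$end - full$start == 3, ]
  expect_equal(identical_occ$score[1], 4)   # identity scores its length
})
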