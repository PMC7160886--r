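test_that("single constraints and full-set constraints are always accepted", {
  t <- pq_tree(letters[1:4])
  r <- pq_insert(t, c("a", "b"))
  expect_true(r$accepted)
  fr <- pq_frontier(r$tree)
  expect_equal(abs(diff(match(c("a", "b"), fr))), 1L)
  expect_true(pq_insert(r$tree, letters[1:4])$accepted)
})

test_that("an infeasible constraint is rejected and leaves the tree unchanged", {
  t <- pq_tree(letters[1:4])
  t <- pq_insert(t, c("a", "b"))$tree
  t <- pq_insert(t, c("b", "c"))$tree
  before <- t
  r <- pq_insert(t, c("a", "c"))
  expect_false(r$accepted)
  expect_identical(r$tree, before)
})

test_that("accepted constraints are consecutive in some frontier", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    leaves <- letters[seq_len(n)]
    t <- pq_tree(leaves)
    accepted <- list()
    for (k in 1:5) {
      s <- sample(leaves, sample(2:(n - 1), 1))
      r <- pq_insert(t, s)
      if (r$accepted) { t <- r$tree; accepted <- c(accepted, list(s)) }
    }
    frs <- all_frontiers(t)
    for (s in accepted) {
      ok <- any(vapply(frs, function(f) {
        w <- match(s, f); max(w) - min(w) + 1L == length(s)
      }, logical(1)))
      expect_true(ok)
    }
    # and every frontier satisfies every accepted constraint
    for (f in frs) {
      for (s in accepted) {
        w <- match(s, f)
        expect_equal(max(w) - min(w) + 1L, length(s))
      }
    }
  }
})

test_that("acceptance agrees with brute-force consecutive-ones feasibility", {
  set.seed(62)
  for (rep in 1:60) {
    n <- sample(4:6, 1)
    leaves <- letters[seq_len(n)]
    t <- pq_tree(leaves)
    kept <- list()
    for (k in 1:5) {
      s <- sample(leaves, sample(2:(n - 1), 1))
      r <- pq_insert(t, s)
      feasible <- oracle_c1p_feasible(c(kept, list(s)), leaves)
      expect_equal(r$accepted, feasible)
      if (r$accepted) { t <- r$tree; kept <- c(kept, list(s)) }
    }
  }
})

test_that("greedy construction is deterministic and weight-ordered", {
  cands <- tibble::tibble(
    content = list(c("a", "b"), c("b", "c"), c("a", "c")),
    weight = c(5, 3, 1))
  leaves <- c("a", "b", "c", "d")
  r1 <- build_pq_tree(cands, leaves)
  r2 <- build_pq_tree(cands, leaves)
  expect_identical(r1$log, r2$log)
  expect_equal(r1$log$accepted, c(TRUE, TRUE, FALSE))  # heavier first wins
  expect_equal(r1$log$weight, c(5, 3, 1))
})

test_that("CAR extraction flags order and reports the fixation metric", {
  # conflict-free chain: all constraints accepted, one fully ordered CAR
  cands <- tibble::tibble(content = list(c("a", "b"), c("b", "c")),
                          weight = c(2, 1))
  r <- build_pq_tree(cands, c("a", "b", "c", "d", "e"))
  cars <- extract_cars(r$tree)
  expect_equal(cars$metrics$car_count, 3L)     # [abc], d, e
  expect_equal(cars$metrics$marker_count, 5L)
  expect_equal(cars$metrics$q_node_mean_children, 3)
  big <- cars$cars[cars$cars$car_id ==
                     cars$cars$car_id[cars$cars$family == "b"], ]
  expect_true(all(big$ordered))
  # no accepted constraints: all-singleton CARs under a P root, no Q nodes
  r0 <- build_pq_tree(tibble::tibble(content = list(), weight = numeric()),
                      c("x", "y", "z"))
  c0 <- extract_cars(r0$tree)
  expect_equal(c0$metrics$car_count, 3L)
  expect_true(is.na(c0$metrics$q_node_mean_children))
  txt <- format_cars(c0)
  expect_equal(length(txt), 3L)
})
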