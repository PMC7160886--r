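test_that("content, multiplicity and balance follow their definitions", {
  s <- marker_genome(list(c(1, -2, 2)))
  expect_equal(content(s), c("1", "2"))
  expect_equal(content(marker_genome(list())), character(0))
  expect_equal(content(marker_genome(list(c(-3, -3)))), "3")

  expect_equal(multiplicity(s, 2), 2L)
  expect_equal(multiplicity(s, 5), 0L)
  g <- marker_genome(list(c(1, 2), -2))
  expect_equal(multiplicity(g, 2), 2L)

  expect_true(is_balanced(marker_genome(list(c(1, 2, 3))),
                          marker_genome(list(c(3, -1, 2)))))
  expect_false(is_balanced(marker_genome(list(c(1, 2, 2))),
                           marker_genome(list(c(1, 2)))))
  expect_true(is_balanced(marker_genome(list()), marker_genome(list())))
})

test_that("adjacency sets list telomeric and internal adjacencies", {
  a <- adjacency_set(marker_genome(list(c(1, 2))))
  expect_setequal(paste(a$ext1, a$ext2),
                  c("1:t NA", "1:h 2:t", "2:h NA"))
  b <- adjacency_set(marker_genome(list(-1)))
  expect_setequal(b$ext1, c("1:h", "1:t"))
  expect_true(all(is.na(b$ext2)))
  two <- adjacency_set(marker_genome(list(c(1, 2), 3)))
  expect_equal(nrow(two), 5L)              # 1 internal + 4 telomeric
  expect_equal(sum(is.na(two$ext2)), 4L)
  expect_error(adjacency_set(marker_genome(list(c(1, 1)))), "non-duplicated")
})

test_that("adjacency graph components match hand-derived cases", {
  g <- marker_genome(list(c(1, 2, 3)))
  ag <- adjacency_graph(g, g)
  expect_equal(sort(table(paste(ag$components$kind, ag$components$edges))),
               sort(table(c("cycle 2", "cycle 2", "odd_path 1", "odd_path 1"))))
  ag2 <- adjacency_graph(g, marker_genome(list(c(1, -2, 3))))
  tab <- ag2$components
  expect_equal(sum(tab$kind == "cycle" & tab$edges == 4), 1L)
  expect_equal(sum(tab$kind == "odd_path" & tab$edges == 1), 2L)
  ag3 <- adjacency_graph(marker_genome(list(1)), marker_genome(list(1)))
  expect_equal(ag3$c, 0L)
  expect_equal(ag3$o, 2L)
  expect_error(adjacency_graph(g, marker_genome(list(c(1, 2)))),
               "not balanced")
})

test_that("dcj distance equals n - c - o/2 on worked cases", {
  g <- marker_genome(list(c(1, 2, 3)))
  expect_equal(dcj_distance(g, g), 0)
  expect_equal(dcj_distance(g, marker_genome(list(c(1, -2, 3)))), 1)
  expect_equal(dcj_distance(marker_genome(list(c(1, 2), 3)), g), 1)
})

test_that("dcj distance is symmetric, zero on identity, and consistent with component accounting", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:5, 1)
    g <- rand_genome(n, genome = "G")
    h <- rand_genome(n, genome = "H")
    expect_equal(dcj_distance(g, g), 0)
    expect_equal(dcj_distance(g, h), dcj_distance(h, g))
    ag <- adjacency_graph(g, h)
    # every extremity is shared once: 2n edges in total
    expect_equal(sum(ag$components$edges), 2L * n)
    # path endpoints are the telomeric adjacencies of both genomes
    n_telo <- sum(is.na(adjacency_set(g)$ext2)) +
      sum(is.na(adjacency_set(h)$ext2))
    paths <- ag$components[ag$components$kind != "cycle", ]
    expect_equal(2L * nrow(paths), n_telo)
  }
})

test_that("closed-form distance agrees with exhaustive BFS on random pairs", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(2:4, 1)
    g <- rand_genome(n, genome = "G")
    h <- rand_genome(n, genome = "H")
    expect_equal(dcj_distance(g, h), dcj_distance_search(g, h))
  }
})

test_that("marker TSV round-trips exactly", {
  set.seed(5)
  m <- dplyr::bind_rows(rand_genome(6, genome = "A"),
                        rand_genome(4, genome = "B"))
  f <- tempfile(fileext = ".tsv")
  write_markers(m, f)
  m2 <- read_markers(f)
  expect_equal(as.data.frame(m2), as.data.frame(m))
  write_markers(m2, paste0(f, "2"))
  expect_identical(readLines(f), readLines(paste0(f, "2")))
})
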