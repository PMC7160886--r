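test_that("delta tables validate their invariants", {
  d <- delta_table("default", max_size = 12)
  expect_true(all(d$delta_add <= d$delta_sum))
  expect_true(all(diff(d$delta_sum) >= 0))
  r <- delta_table("relaxed", max_size = 12)
  expect_true(all(r$delta_sum >= d$delta_sum))
  custom <- tibble::tibble(size = c(2, 5), delta_add = c(0, 1),
                           delta_loss = c(0, 1), delta_sum = c(0, 2))
  ct <- delta_table(custom)
  expect_equal(attr(ct, "profile"), "custom")
  bad <- tibble::tibble(size = 2, delta_add = 3, delta_loss = 0, delta_sum = 1)
  expect_error(delta_table(bad), "exceed")
  f <- tempfile(); utils::write.table(as.data.frame(custom), f, sep = "\t",
                                      row.names = FALSE, quote = FALSE)
  expect_equal(delta_table(f)$delta_sum, c(0L, 2L))
})

test_that("interval deviation counts inserted and missing families", {
  expect_equal(interval_deviation(c("1", "2", "3"), c(1, 2, 3)),
               c(inserted = 0L, missing = 0L))
  expect_equal(interval_deviation(c("1", "2", "3"), c(1, 4, 3)),
               c(inserted = 1L, missing = 1L))
  expect_equal(interval_deviation(c("1", "2", "3"), character(0)),
               c(inserted = 0L, missing = 3L))
})

zero_delta <- function() {
  delta_table(tibble::tibble(size = 2, delta_add = 0, delta_loss = 0,
                             delta_sum = 0))
}

test_that("identical genomes yield one exact block per maximal interval", {
  m <- dplyr::bind_rows(marker_genome(list(c(1, 2, 3, 4)), "A"),
                        marker_genome(list(c(1, 2, 3, 4)), "B"))
  b <- discover_blocks(m, "A", zero_delta(), quorum = 2, min_ref_size = 2)
  # unique markers: every interval of size >= 2 is maximal -> 6 blocks
  expect_equal(length(b$content), 6L)
  occ <- b$occurrences
  expect_true(all(occ$inserted == 0L & occ$missing == 0L))
  cnt <- table(occ$block_id, occ$genome)
  expect_true(all(cnt == 1L))
})

test_that("the delta budget controls acceptance of deviating occurrences", {
  m <- dplyr::bind_rows(marker_genome(list(c(1, 2, 3)), "A"),
                        marker_genome(list(c(1, 5, 3)), "B"))
  tight <- delta_table(tibble::tibble(size = 3, delta_add = 1,
                                      delta_loss = 1, delta_sum = 1))
  loose <- delta_table(tibble::tibble(size = 3, delta_add = 1,
                                      delta_loss = 1, delta_sum = 2))
  expect_equal(length(discover_blocks(m, "A", tight, quorum = 2,
                                      min_ref_size = 3)$content), 0L)
  b <- discover_blocks(m, "A", loose, quorum = 2, min_ref_size = 3)
  expect_equal(length(b$content), 1L)
  occ <- b$occurrences[!b$occurrences$is_reference, ]
  expect_equal(occ$inserted, 1L)
  expect_equal(occ$missing, 1L)
})

test_that("quorum drops blocks conserved in too few genomes", {
  m <- dplyr::bind_rows(marker_genome(list(c(1, 2, 3)), "A"),
                        marker_genome(list(c(1, 2, 3)), "B"),
                        marker_genome(list(c(7, 8, 9)), "C"))
  b2 <- discover_blocks(m, "A", zero_delta(), quorum = 2, min_ref_size = 3)
  expect_equal(length(b2$content), 1L)
  b3 <- discover_blocks(m, "A", zero_delta(), quorum = 3, min_ref_size = 3)
  expect_equal(length(b3$content), 0L)
})

test_that("every reported occurrence satisfies its delta row", {
  set.seed(31)
  for (rep in 1:8) {
    m <- rand_genome_set(3, 9, n_fams = 6)
    for (prof in c("default", "relaxed")) {
      b <- discover_blocks(m, "G1", delta_table(prof), quorum = 2)
      occ <- b$occurrences
      if (nrow(occ) == 0) next
      d <- delta_table(prof)
      for (i in seq_len(nrow(occ))) {
        gset <- b$content[[occ$block_id[i]]]
        row <- ancar:::delta_row(d, length(gset))
        expect_lte(occ$inserted[i], row$add)
        expect_lte(occ$missing[i], row$loss)
        expect_lte(occ$inserted[i] + occ$missing[i], row$sum)
      }
    }
  }
})

test_that("raising delta thresholds never loses a discovered block content", {
  set.seed(32)
  for (rep in 1:6) {
    m <- rand_genome_set(3, 8, n_fams = 5)
    lo <- discover_blocks(m, "G1", delta_table("default"), quorum = 2)
    hi <- discover_blocks(m, "G1", delta_table("relaxed"), quorum = 2)
    ref_int <- function(b) {
      occ <- b$occurrences[b$occurrences$is_reference, ]
      sort(paste(occ$chrom, occ$start, occ$end))
    }
    expect_true(all(ref_int(lo) %in% ref_int(hi)))
  }
})

test_that("discovery agrees with the brute-force enumeration oracle", {
  set.seed(33)
  for (rep in 1:6) {
    m <- rand_genome_set(3, 8, n_fams = 5)
    for (prof in c("default", "relaxed")) {
      d <- delta_table(prof)
      got <- blocks_to_keys(discover_blocks(m, "G1", d, quorum = 2))
      want <- oracle_blocks(m, "G1", d, quorum = 2)
      expect_equal(got, want)
    }
  }
})

test_that("the overlap cap keeps the highest-weight blocks per component", {
  m <- dplyr::bind_rows(marker_genome(list(1:6), "A"),
                        marker_genome(list(1:6), "B"))
  b <- discover_blocks(m, "A", zero_delta(), quorum = 2)
  n0 <- length(b$content)
  expect_gt(n0, 3L)
  capped <- cap_overlapping_blocks(b, cap = 3L)
  expect_equal(length(capped$content), 3L)
  # default weight is reference length: the longest blocks survive
  ref <- capped$occurrences[capped$occurrences$is_reference, ]
  expect_true(all(ref$end - ref$start + 1 >= 4))
})
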