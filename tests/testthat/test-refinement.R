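# hand-built block/score scaffolding for refinement tests
mk_blocks <- function(occ_rows, content) {
  structure(list(occurrences = dplyr::bind_rows(occ_rows), content = content),
            class = "synteny_blocks")
}
occ_row <- function(bid, genome, chrom, start, end, ref = FALSE) {
  tibble::tibble(block_id = bid, genome = genome, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 inserted = 0L, missing = 0L, is_reference = ref)
}

test_that("overlap components join block sets sharing marker occurrences", {
  b <- mk_blocks(list(
    occ_row("B1", "A", "c1", 1, 3, TRUE), occ_row("B1", "B", "c1", 1, 3),
    occ_row("B2", "A", "c1", 3, 5, TRUE), occ_row("B2", "B", "c1", 3, 5),
    occ_row("B3", "A", "c2", 1, 2, TRUE), occ_row("B3", "B", "c2", 1, 2)),
    list(B1 = c("1", "2", "3"), B2 = c("3", "4", "5"), B3 = c("8", "9")))
  comp <- overlap_components(b)
  mem <- comp$membership
  expect_equal(mem$component[mem$block_id == "B1"],
               mem$component[mem$block_id == "B2"])   # share A:c1:3
  expect_false(mem$component[mem$block_id == "B3"] ==
                 mem$component[mem$block_id == "B1"])
  empty <- overlap_components(ancar:::empty_blocks())
  expect_equal(nrow(empty$membership), 0L)
})

test_that("rule (i) splits families along overlap components, proper subsets only", {
  m <- dplyr::bind_rows(marker_genome(list(c(1, 2, 1)), "A"),
                        marker_genome(list(c(1, 2)), "B"))
  b <- mk_blocks(list(occ_row("B1", "A", "chr1", 1, 2, TRUE),
                      occ_row("B1", "B", "chr1", 1, 2)),
                 list(B1 = c("1", "2")))
  comp <- overlap_components(b)
  r <- refine_rule_i(m, comp)
  fam_a <- r$markers$family[r$markers$genome == "A"]
  # the third occurrence of family 1 (outside the block) keeps the parent id
  expect_equal(fam_a[3], "1")
  expect_match(fam_a[1], "^1@O")
  # family 2 lies entirely inside the component: untouched
  expect_equal(fam_a[2], "2")
  # applying the rule twice changes nothing
  r2 <- refine_rule_i(r$markers, comp)
  expect_equal(r2$markers$family, r$markers$family)
})

test_that("rule (ii) creates families from consistent assignments only", {
  # three genomes; reference A; an extra copy of f in B keeps the candidate
  # a proper subset of its family
  m <- dplyr::bind_rows(marker_genome(list(c("f", "g")), "A"),
                        marker_genome(list(c("f", "g", "f")), "B"),
                        marker_genome(list(c("f", "g")), "C"))
  matched <- function(rp, tp) tibble::tibble(
    family = "f", ref_pos = rp, ref_sign = 1L, tgt_pos = tp, tgt_sign = 1L)
  scores <- tibble::tibble(
    block_id = c("B1", "B1", "B2"),
    genome = c("B", "C", "B"), chrom = "chr1",
    start = 1L, end = 2L,
    occurrence_id = c("B:chr1:1-2", "C:chr1:1-2", "B:chr1:1-2"),
    score = 1, d = 0L, exact = TRUE,
    matched = list(matched(1L, 1L), matched(1L, 1L), matched(1L, 1L)),
    ref_chrom = "chr1")
  r <- refine_rule_ii(m, scores, reference = "A")
  fam <- stats::setNames(r$markers$family, ancar:::occ_id_of(r$markers))
  expect_equal(fam[["A:chr1:1"]], fam[["B:chr1:1"]])
  expect_equal(fam[["A:chr1:1"]], fam[["C:chr1:1"]])
  expect_match(fam[["A:chr1:1"]], "#1$")
  # occurrences not in the new family keep their previous id
  expect_equal(fam[["B:chr1:2"]], "g")

  # conflicting assignment in genome B disqualifies the anchor
  scores2 <- scores
  scores2$matched[[3]] <- matched(1L, 2L)   # same anchor, different partner
  r2 <- refine_rule_ii(m, scores2, reference = "A")
  expect_equal(sort(unique(r2$markers$family)), c("f", "g"))
})

test_that("rule (ii) families span at most one occurrence per genome and anchor on the reference", {
  set.seed(51)
  ds <- simulate_dataset(30, 2, eudicot_phylogeny(2, 3, 0.6), seed = 51)
  m <- ds$genomes
  blocks <- discover_blocks(m, "rosid", delta_table("default"), quorum = 2,
                            max_ref_size = 6)
  scores <- score_block_set(blocks, m)
  rf <- refine_families(m, blocks, scores, "rosid")
  prov2 <- rf$provenance[rf$provenance$rule == "ii", ]
  if (nrow(prov2) > 0) {
    for (nf in prov2$new_family) {
      rows <- rf$markers[rf$markers$family == nf, ]
      expect_true(all(table(rows$genome) == 1L))
      expect_equal(sum(rows$genome == "rosid"), 1L)
    }
  }
  # the refined partition refines the input: members of a new family share
  # the original family
  orig <- stats::setNames(m$family, ancar:::occ_id_of(m))
  for (nf in unique(rf$markers$family)) {
    rows <- rf$markers[rf$markers$family == nf, ]
    expect_equal(length(unique(orig[ancar:::occ_id_of(rows)])), 1L)
  }
  # idempotence of the full refinement
  rf2 <- refine_families(rf$markers, blocks, scores, "rosid")
  expect_equal(rf2$markers$family, rf$markers$family)
})
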