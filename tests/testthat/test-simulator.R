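test_that("ancestor simulation is deterministic and validates its inputs", {
  set.seed(71); a1 <- simulate_ancestor(10, 2)
  set.seed(71); a2 <- simulate_ancestor(10, 2)
  expect_identical(a1, a2)
  expect_equal(nrow(a1), 10L)
  expect_equal(length(unique(a1$chrom)), 2L)
  expect_equal(length(unique(a1$family)), 10L)
  expect_equal(nrow(simulate_ancestor(0, 0)), 0L)
  expect_error(simulate_ancestor(3, 5), "exceed")
})

test_that("DCJ operations move the genome by bounded distance", {
  set.seed(72)
  anc <- simulate_ancestor(8, 2)
  expect_identical(apply_dcj_ops(anc, 0)[, 1:5], anc[, 1:5])
  one <- apply_dcj_ops(anc, 1)
  expect_equal(dcj_distance(anc[, 1:5], one[, 1:5]), 1)
  for (k in c(2, 5)) {
    g <- apply_dcj_ops(anc, k)
    expect_lte(dcj_distance(anc[, 1:5], g[, 1:5]), k)
    expect_true(is_balanced(anc, g))   # content preserved
  }
})

test_that("polyploidy copies chromosomes and fractionation spares pre-event copies", {
  set.seed(73)
  anc <- simulate_ancestor(20, 2)
  dup0 <- apply_polyploidy(anc, "wgd", loss_rate = 0)
  expect_true(all(table(dup0$family) == 2L))
  tri_all_lost <- apply_polyploidy(anc, "wgt", loss_rate = 1)
  expect_true(all(table(tri_all_lost$family) == 1L))   # back to pre-event
  set.seed(74)
  big <- apply_polyploidy(simulate_ancestor(1000, 4), "wgd", loss_rate = 0.5)
  expect_equal(mean(table(big$family)), 1.5, tolerance = 0.05)
})

test_that("a eudicot-like history orders the mean multiplicities of the leaves", {
  # two WGTs (stem + nested) and one terminal WGD, as in the classic scenario
  tr <- sim_branch("root", children = list(
    sim_branch("rosid", dcj_ops = 5),
    sim_branch("ast", dcj_ops = 5, wg_events = "wgt", children = list(
      sim_branch("asterid1", dcj_ops = 5),
      sim_branch("astII", dcj_ops = 5, wg_events = "wgt", children = list(
        sim_branch("asterid2", dcj_ops = 5),
        sim_branch("wgd_leaf", dcj_ops = 5, wg_events = "wgd")))))))
  ds <- simulate_dataset(120, 3, tr, seed = 75)
  mult <- tapply(ds$genomes$family, ds$genomes$genome,
                 function(x) mean(table(x)))
  expect_lt(mult[["rosid"]], mult[["asterid1"]])
  expect_lt(mult[["asterid1"]], mult[["asterid2"]])
  expect_lt(mult[["asterid2"]], mult[["wgd_leaf"]])
})

test_that("every ancestral marker survives in every leaf and datasets replay byte-identically", {
  ds <- simulate_dataset(40, 2, eudicot_phylogeny(3, 5, 0.6), seed = 76)
  fams <- unique(ds$ancestor$family)
  for (g in unique(ds$genomes$genome)) {
    expect_true(all(fams %in% ds$genomes$family[ds$genomes$genome == g]))
  }
  d1 <- tempfile(); d2 <- tempfile()
  emit_dataset(ds, d1)
  emit_dataset(simulate_dataset(40, 2, eudicot_phylogeny(3, 5, 0.6),
                                seed = 76), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # single leaf without events reproduces the ancestor's marker order
  plain <- simulate_dataset(15, 2, sim_branch("root", children = list(
    sim_branch("leaf"))), seed = 77)
  leaf <- plain$genomes
  anc <- plain$ancestor
  expect_equal(leaf$family, anc$family)
  expect_equal(leaf$sign, anc$sign)
})
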