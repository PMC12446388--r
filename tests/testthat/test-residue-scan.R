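res_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_residue_fixture(3, model = JTT)
    fx
  }
})

test_that("calls at the planted position match truth for every taxon", {
  fx <- res_fixture()
  calls <- call_reference_residue(fx$alignment, "human_TRPA1",
                                  fx$truth$position)
  expect_equal(nrow(calls), n_taxa(fx$alignment))
  planted <- fx$truth$planted_residues[calls$taxon_id]
  expect_identical(calls$residue, unname(planted))
  expect_identical(calls$call_class, unname(planted))  # all V or G here
  # the reference row itself carries V
  expect_equal(calls$call_class[calls$taxon_id == "human_TRPA1"], "V")
})

test_that("call classes collapse non-V/G residues and gaps", {
  aln <- aln_from_rows(ref = "MVKG", a = "MGKA", b = "M-KV")
  calls <- call_reference_residue(aln, "ref", 2L)
  expect_equal(setNames(calls$call_class, calls$taxon_id),
               c(ref = "V", a = "G", b = "gap"))
  calls4 <- call_reference_residue(aln, "ref", 4L)
  expect_equal(setNames(calls4$call_class, calls4$taxon_id),
               c(ref = "G", a = "other", b = "V"))
  expect_error(call_reference_residue(aln, "ref", 5L), "outside")
  expect_error(call_reference_residue(aln, "ref", 0L), "outside")
})

test_that("calls are stable under removing non-reference taxa", {
  fx <- res_fixture()
  full <- call_reference_residue(fx$alignment, "human_TRPA1",
                                 fx$truth$position)
  sub <- fx$alignment
  keep <- setdiff(taxa(sub), c("myomorpha_1", "lagomorpha_2"))
  sub$mat <- sub$mat[keep, , drop = FALSE]
  subcalls <- call_reference_residue(sub, "human_TRPA1", fx$truth$position)
  m <- match(subcalls$taxon_id, full$taxon_id)
  expect_identical(subcalls$call_class, full$call_class[m])
  expect_identical(subcalls$alignment_column, full$alignment_column[m])
})

test_that("a gap column left of the mapped column shifts it by one", {
  fx <- res_fixture()
  before <- call_reference_residue(fx$alignment, "human_TRPA1",
                                   fx$truth$position)
  shifted <- fx$alignment
  ins <- 5L   # insert a reference-gap column at position 5
  newcol <- rep("A", n_taxa(shifted))
  newcol[match("human_TRPA1", taxa(shifted))] <- "-"
  shifted$mat <- cbind(shifted$mat[, 1:(ins - 1)], newcol,
                       shifted$mat[, ins:n_cols(shifted)])
  colnames(shifted$mat) <- NULL
  after <- call_reference_residue(shifted, "human_TRPA1", fx$truth$position)
  expect_equal(after$alignment_column, before$alignment_column + 1L)
  expect_identical(after$call_class, before$call_class)
})

test_that("tabulation counts per group and attaches thermal labels", {
  fx <- res_fixture()
  calls <- call_reference_residue(fx$alignment, "human_TRPA1",
                                  fx$truth$position)
  tab <- tabulate_by_clade(calls, fx$clade_groups, fx$thermal_labels)
  expect_equal(tab$group_id, c(23L, 24L, 25L, 26L))
  expect_equal(tab$n_total,
               unname(table(fx$clade_groups$group_id)[as.character(tab$group_id)]),
               ignore_attr = TRUE)
  expect_true(all(rowSums(tab[, c("n_V", "n_G", "n_other", "n_gap")]) ==
                    tab$n_total))
  # concordance on the fixture: cold groups all G, insensitive all V
  cold <- tab[tab$thermal_label == "cold", ]
  expect_true(all(cold$n_G == cold$n_total))
  insv <- tab[tab$thermal_label == "insensitive", ]
  expect_true(all(insv$n_V == insv$n_total))
})

test_that("tabulation handles hand-built counts, empties and misses", {
  calls <- call_reference_residue(
    aln_from_rows(p1 = "AVC", p2 = "AVC", p3 = "AVC", r1 = "AGC", r2 = "AGC"),
    "p1", 2L)
  cg <- clade_group_table(c("p1", "p2", "p3", "r1", "r2"),
                          c(26, 26, 26, 25, 25),
                          c("Primates", "Primates", "Primates",
                            "Rodentia", "Rodentia"))
  tab <- tabulate_by_clade(calls, cg)
  expect_equal(tab$n_G[tab$group_id == 25], 2L)
  expect_equal(tab$n_V[tab$group_id == 26], 3L)
  expect_equal(unique(tab$thermal_label), "unknown")
  empty <- tabulate_by_clade(calls[0, ], cg)
  expect_equal(nrow(empty), 0L)
  expect_error(tabulate_by_clade(calls, cg[cg$taxon_id != "r1", ]), "r1")
})

test_that("extract_region_alignment slices the display region", {
  ds <- simulate_alignment(sim_config(seq_length = 900, seed = 12,
                                      n_taxa = 4), JTT)
  aln <- ds$alignment
  ref <- taxa(aln)[1]
  dm <- domain_map(ref, 900L, regions = list(S5 = c(870, 890)))
  s5 <- extract_region_alignment(aln, dm, "S5")
  expect_equal(n_cols(s5), 21L)
  expect_identical(s5$mat, aln$mat[, 870:890, drop = FALSE])
  expect_error(extract_region_alignment(aln, dm, "S6"), "not in domain map")
  # slicing a slice equals slicing the composed interval
  dm_outer <- domain_map(ref, 900L, regions = list(block = c(861, 900)))
  outer <- slice_region(aln, dm_outer, "block")
  dm_inner <- domain_map(ref, 40L, regions = list(inner = c(10, 30)))
  expect_identical(slice_region(outer, dm_inner, "inner")$mat,
                   aln$mat[, 870:890, drop = FALSE])
})
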