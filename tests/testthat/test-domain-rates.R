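test_that("reference column mapping follows the ungapped reference", {
  aln <- aln_from_rows(ref = "MKVR", other = "MKVR")
  expect_equal(map_reference_columns(aln, "ref"), 1:4)
  aln2 <- aln_from_rows(ref = "M-KV", other = "MAKV")
  expect_equal(unname(map_reference_columns(aln2, "ref")), c(1L, 3L, 4L))
  expect_error(map_reference_columns(aln, "absent"), "absent")
  # composing the map with the reference's gap structure is the identity
  cmap <- map_reference_columns(aln2, "ref")
  ungapped <- which(aln2$mat["ref", ] != "-")
  expect_identical(unname(cmap), ungapped)
})

test_that("slice_region concatenates mapped intervals", {
  aln <- aln_from_rows(ref = "MKVR", other = "MAVR")
  dm <- domain_map("ref", 4L, regions = list(mid = c(2, 3),
                                             split = rbind(c(1, 2), c(4, 4))))
  expect_identical(slice_region(aln, dm, "full_length")$mat, aln$mat)
  expect_identical(slice_region(aln, dm, "mid")$mat,
                   aln$mat[, 2:3, drop = FALSE])
  expect_identical(slice_region(aln, dm, "split")$mat,
                   aln$mat[, c(1, 2, 4), drop = FALSE])
  expect_error(slice_region(aln, dm, "nope"), "not in domain map")
  dm_far <- domain_map("ref", 9L, regions = list(far = c(5, 9)))
  expect_error(slice_region(aln, dm_far, "far"), "beyond")
})

test_that("all-gap columns are dropped with a count after slicing", {
  aln <- aln_from_rows(ref = "MK-R", a = "MK-R", b = "MKVR")
  aln$mat["b", 3] <- "-"   # make column 3 all-gap (bypass constructor)
  dm <- domain_map("ref", 3L, regions = list())
  sl <- slice_region(aln, dm, "full_length")
  # reference has 3 ungapped residues at columns 1,2,4
  expect_equal(n_cols(sl), 3L)
  expect_equal(attr(sl, "n_dropped_allgap"), 0L)
})

test_that("group summaries compute mean, sd and handle singletons", {
  tr <- ape::read.tree(text = "((s1:0.4,s2:0.4):0.1,(t1:0.2,lone:0.3):0.1);")
  cg <- clade_group_table(c("s1", "s2", "t1", "lone"),
                          c(14, 14, 15, 16),
                          c("Sirenia", "Sirenia", "Proboscidea", "Other"))
  s14 <- group_distance_summary(tr, cg, 14)
  expect_equal(s14$distances, c(s1 = 0.5, s2 = 0.5))
  expect_equal(s14$mean, 0.5)
  expect_equal(s14$sd, 0)
  s16 <- group_distance_summary(tr, cg, 16)
  expect_equal(s16$n, 1L)
  expect_true(is.na(s16$sd))
  expect_equal(s16$mean, 0.4)
  expect_error(group_distance_summary(tr, cg, 16,
                                      scheme = "mean_pairwise_within_group"),
               "singleton")
  expect_error(group_distance_summary(tr, cg, 22), "no members")
  # hand-enumerated within-group patristic means
  s14p <- group_distance_summary(tr, cg, 14,
                                 scheme = "mean_pairwise_within_group")
  expect_equal(s14p$distances, c(s1 = 0.8, s2 = 0.8))
})

test_that("scaling all branch lengths scales means and leaves ratios fixed", {
  tr <- ape::read.tree(text = "((s1:0.4,s2:0.6):0.1,(t1:0.2,t2:0.3):0.1);")
  cg <- clade_group_table(c("s1", "s2", "t1", "t2"), c(14, 14, 15, 15),
                          c("A", "A", "B", "B"))
  base <- group_distance_summary(tr, cg, 14)
  scaled_tr <- tr; scaled_tr$edge.length <- tr$edge.length * 2.5
  scaled <- group_distance_summary(scaled_tr, cg, 14)
  expect_equal(scaled$mean, 2.5 * base$mean)
  expect_equal(scaled$sd, 2.5 * base$sd)
  # a common scale cancels in any region/full-length ratio
  other <- group_distance_summary(tr, cg, 15)
  other_s <- group_distance_summary(scaled_tr, cg, 15)
  expect_equal(scaled$mean / other_s$mean, base$mean / other$mean)
})

small_fixture <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) {
      fx <<- make_marine_fixture(5, region_length = 120L,
                                 taxa_per_group = 3L, model = JTT)
    }
    fx
  }
})

test_that("rate_ratio_report has unit full-length ratios by construction", {
  fx <- small_fixture()
  rep <- rate_ratio_report(fx$alignment, fx$domain_map, fx$clade_groups, JTT,
                           rate_config(regions = c("sensor", "middle",
                                                   "pore")))
  expect_equal(nrow(rep), 16L)   # 4 groups x 4 regions
  fl <- rep$ratio[rep$region == "full_length"]
  expect_identical(fl, rep(1, 4))
  expect_true(all(rep$ratio >= 0))
  md <- attr(rep, "metadata")
  expect_equal(md$scheme, "root_to_tip")
  expect_equal(md$deletion, "complete")
})

test_that("the report is invariant to taxon order", {
  fx <- small_fixture()
  cfg <- rate_config(regions = "sensor")
  rep1 <- rate_ratio_report(fx$alignment, fx$domain_map, fx$clade_groups,
                            JTT, cfg)
  perm <- fx$alignment
  set.seed(8)
  ord <- sample(n_taxa(perm))
  perm$mat <- perm$mat[ord, , drop = FALSE]
  rep2 <- rate_ratio_report(perm, fx$domain_map, fx$clade_groups, JTT, cfg)
  # agreement up to optimizer tolerance: permuting rows changes the NJ
  # agglomeration order and the branch-optimization visit order
  expect_equal(rep1$ratio, rep2$ratio, tolerance = 1e-5)
  expect_equal(rep1$mean, rep2$mean, tolerance = 1e-5)
})

test_that("taxa absent from the clade table are reported", {
  fx <- small_fixture()
  cg <- fx$clade_groups[fx$clade_groups$taxon_id != "sirenia_1", ]
  expect_error(rate_ratio_report(fx$alignment, fx$domain_map, cg, JTT,
                                 rate_config(regions = "sensor")),
               "sirenia_1")
})

test_that("null simulation keeps mean ratios near 1", {
  # module contract: 20 replicates at 1000-site regions; 3 replicates at
  # 400 sites keep the run in budget (band unchanged)
  for (seed in 1:3) {
    fx <- make_marine_fixture(seed, sensor_multiplier = 1,
                              region_length = 400L, model = JTT)
    rep <- rate_ratio_report(fx$alignment, fx$domain_map, fx$clade_groups,
                             JTT, rate_config(regions = c("sensor", "middle",
                                                          "pore")))
    for (rg in c("sensor", "middle", "pore")) {
      mean_ratio <- mean(rep$ratio[rep$region == rg])
      expect_gt(mean_ratio, 0.9)
      expect_lt(mean_ratio, 1.1)
    }
  }
})

test_that("report writer emits metadata and parseable rows", {
  fx <- small_fixture()
  rep <- rate_ratio_report(fx$alignment, fx$domain_map, fx$clade_groups, JTT,
                           rate_config(regions = "sensor"))
  f <- withr::local_tempfile()
  write_rate_report(rep, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# scheme=root_to_tip", lines)))
  body <- read.delim(f, comment.char = "#")
  expect_equal(nrow(body), nrow(rep))
  expect_equal(body$ratio[body$region == "full_length"], rep(1, 4))
})
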