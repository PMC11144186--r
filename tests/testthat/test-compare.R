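ann_fixture <- function() {
  data.frame(
    protein_id = c("P1", "P1", "P2", "P3"),
    family_id = c("FA", "FB", "FA", "FC"),
    clan_id = c("CLX", "CLY", "CLX", "-"),
    start = c(10L, 100L, 5L, 1L), end = c(60L, 180L, 80L, 50L),
    stringsAsFactors = FALSE)
}

test_that("seed architecture: one-residue rule and ordering", {
  ann <- ann_fixture()
  # families ordered by start coordinate
  expect_identical(
    seed_architecture(regions("P1", 50, 200), ann), c("FA", "FB"))
  # no overlap at all
  expect_null(seed_architecture(regions("P1", 200, 300), ann))
  # a single overlapping residue is enough
  expect_identical(seed_architecture(regions("P1", 60, 99), ann), "FA")
  expect_identical(seed_architecture(regions("P1", 61, 100), ann), "FB")
  # clan level; FC has no clan -> pseudo-clan equal to the family
  expect_identical(seed_architecture(regions("P3", 1, 50), ann,
                                     level = "clan"), "FC")
  expect_identical(seed_architecture(regions("P1", 50, 200), ann,
                                     level = "clan"), c("CLX", "CLY"))
})

mc_with_seeds <- function(seed_df, id = "MC0001") {
  mc <- mk_mc(list(mk_pc("Q", "P1")), id = id)
  mc$seeds <- seed_df
  mc
}

test_that("dominant architecture: counting, UNK and the tie rule", {
  ann <- ann_fixture()
  # 6 seeds covering FA+FB on P1, 4 covering FA only on P2
  seeds <- regions(c(rep("P1", 6), rep("P2", 4)),
                   c(rep(10L, 6), rep(5L, 4)),
                   c(rep(180L, 6), rep(80L, 4)))
  mc <- mc_with_seeds(seeds)
  da <- dominant_architecture(mc, ann)
  expect_identical(da$architecture, c("FA", "FB"))
  expect_equal(da$percent, 60)

  # unannotated metacluster
  mc_unk <- mc_with_seeds(regions("Z1", 1, 50))
  expect_identical(dominant_architecture(mc_unk, ann)$architecture,
                   "UNK")
  expect_equal(dominant_architecture(mc_unk, ann)$percent, 0)

  # 5/5 tie between (FA;FB) and (FA): lexicographically smaller wins
  seeds2 <- regions(c(rep("P1", 5), rep("P2", 5)),
                    c(rep(10L, 5), rep(5L, 5)),
                    c(rep(180L, 5), rep(80L, 5)))
  da2 <- dominant_architecture(mc_with_seeds(seeds2), ann)
  expect_identical(da2$architecture, "FA")
  expect_equal(da2$percent, 50)
})

test_that("percent variants are monotone and follow the set semantics", {
  ann <- ann_fixture()
  # DA = (FA, FB); half the seeds exact, half the sub-architecture (FA)
  seeds <- regions(c(rep("P1", 5), rep("P2", 5)),
                   c(rep(10L, 5), rep(5L, 5)),
                   c(rep(180L, 5), rep(80L, 5)))
  pv <- percent_variants(mc_with_seeds(seeds), c("FA", "FB"), ann)
  expect_equal(unname(pv["Percent_DA"]), 50)
  expect_equal(unname(pv["Percent_DACF"]), 100)
  expect_true(all(diff(unname(pv)) >= 0))

  # all seeds exactly DA
  all_exact <- regions(rep("P1", 4), rep(10L, 4), rep(180L, 4))
  pv2 <- percent_variants(mc_with_seeds(all_exact), c("FA", "FB"), ann)
  expect_equal(unname(pv2), rep(100, 4))

  # a superset seed counts only in Percent_DACFA
  ann3 <- rbind(ann_fixture(), data.frame(
    protein_id = "P4", family_id = c("FA", "FB", "FC"),
    clan_id = c("CLX", "CLY", "-"),
    start = c(10L, 100L, 200L), end = c(60L, 180L, 260L)))
  seeds3 <- regions(c("P1", "P4"), c(10L, 10L), c(180L, 260L))
  pv3 <- percent_variants(mc_with_seeds(seeds3), c("FA", "FB"), ann3)
  expect_equal(unname(pv3["Percent_DA"]), 50)
  expect_equal(unname(pv3["Percent_DACF"]), 50)
  expect_equal(unname(pv3["Percent_DACFA"]), 100)

  # unannotated seeds count as the empty sub-architecture in DACF
  seeds4 <- regions(c("P1", "Z9"), c(10L, 1L), c(180L, 40L))
  pv4 <- percent_variants(mc_with_seeds(seeds4), c("FA", "FB"), ann)
  expect_equal(unname(pv4["Percent_DA"]), 50)
  expect_equal(unname(pv4["Percent_DACF"]), 100)
})

test_that("percent monotonicity holds on randomized annotation sets", {
  set.seed(53)
  for (k in 1:10) {
    nprot <- 12
    ann <- do.call(rbind, lapply(seq_len(nprot), function(p) {
      nf <- sample(0:3, 1)
      if (nf == 0) return(NULL)
      starts <- sort(sample(seq(1, 400, by = 10), nf))
      data.frame(protein_id = sprintf("P%d", p),
                 family_id = sample(c("FA", "FB", "FC", "FD"), nf,
                                    replace = TRUE),
                 clan_id = "-", start = starts, end = starts + 60L,
                 stringsAsFactors = FALSE)
    }))
    seeds <- regions(sprintf("P%d", seq_len(nprot)),
                     sample(100, nprot, replace = TRUE),
                     300L + sample(100, nprot, replace = TRUE))
    mc <- mc_with_seeds(seeds)
    da <- dominant_architecture(mc, ann)
    if (identical(da$architecture, "UNK")) next
    pv <- percent_variants(mc, da$architecture, ann)
    expect_true(all(diff(unname(pv)) >= -1e-12))
  }
})

test_that("overlap fractions match interval arithmetic", {
  ann <- data.frame(protein_id = "P1", family_id = "FA",
                    clan_id = "CLX", start = 1L, end = 100L,
                    stringsAsFactors = FALSE)
  exact <- mc_with_seeds(regions("P1", 1, 100))
  expect_equal(overlap_fractions(exact, "FA", ann),
               c(Fred = 0, Fext = 0))
  short <- mc_with_seeds(regions("P1", 1, 80))
  expect_equal(overlap_fractions(short, "FA", ann),
               c(Fred = 0.2, Fext = 0))
  shifted <- mc_with_seeds(regions("P1", 21, 120))
  expect_equal(overlap_fractions(shifted, "FA", ann),
               c(Fred = 0.2, Fext = 0.2))
  expect_error(overlap_fractions(mc_with_seeds(regions("Z", 1, 10)),
                                 "FA", ann), "no seed matches")
})

test_that("overlap classifier: anchors and boundary inclusivity", {
  expect_identical(classify_overlap(0.1, 0.1), "equivalent")
  expect_identical(classify_overlap(0.5, 0.5), "shifted")
  expect_identical(classify_overlap(0.3, 0.05), "reduced")
  expect_identical(classify_overlap(0.05, 0.3), "extended")
  expect_identical(classify_overlap(0.2, 0.2), "equivalent")
  expect_error(classify_overlap(1.2, 0))
})

test_that("composition labels apply the published thresholds", {
  proteins <- c(P1 = strrep("A", 100))
  mk_tracks <- function(lc_n = 0, dis_n = 0, tm = 0L) {
    famdpc:::tracks_from_intervals(data.frame(
      protein_id = c(if (lc_n > 0) "P1", if (dis_n > 0) "P1",
                     rep("P1", tm)),
      feature = c(if (lc_n > 0) "low_complexity",
                  if (dis_n > 0) "disordered",
                  rep("transmembrane", tm)),
      start = c(if (lc_n > 0) 1L, if (dis_n > 0) 1L, rep(0L, tm)),
      end = c(if (lc_n > 0) as.integer(lc_n),
              if (dis_n > 0) as.integer(dis_n), rep(0L, tm)),
      stringsAsFactors = FALSE), proteins)
  }
  mc <- mc_with_seeds(regions("P1", 1, 100))
  # 11% low complexity -> labeled; exactly 10% -> not (strict)
  expect_match(composition_labels(mc, mk_tracks(lc_n = 11))$labels,
               "LowComplexity")
  expect_identical(composition_labels(mc, mk_tracks(lc_n = 10))$labels,
                   "")
  # disordered: strict 50%
  expect_identical(composition_labels(mc, mk_tracks(dis_n = 50))$labels,
                   "")
  expect_match(composition_labels(mc, mk_tracks(dis_n = 51))$labels,
               "Disordered")
  # transmembrane: mean >= 2 inclusive
  expect_match(composition_labels(mc, mk_tracks(tm = 2L))$labels,
               "Transmembrane")
  expect_identical(composition_labels(mc, mk_tracks(tm = 1L))$labels,
                   "")
  # missing tracks treated as all-false
  mc2 <- mc_with_seeds(regions(c("P1", "ZZ"), c(1, 1), c(100, 100)))
  expect_identical(composition_labels(mc2, mk_tracks())$labels, "")
})

test_that("coverage statistics count overlapping residues once", {
  proteins <- c(P1 = strrep("A", 100))
  regs <- regions(c("P1", "P1"), c(1, 41), c(50, 60))
  expect_equal(coverage_stats(regs, proteins),
               c(residue_coverage = 60, sequence_coverage = 100))
  expect_equal(coverage_stats(regions(character(), integer(), integer()),
                              proteins),
               c(residue_coverage = 0, sequence_coverage = 0))
  two <- c(P1 = strrep("A", 50), P2 = strrep("A", 150))
  full <- regions(c("P1", "P2"), c(1, 1), c(50, 150))
  expect_equal(coverage_stats(full, two),
               c(residue_coverage = 100, sequence_coverage = 100))
  # invariant: splitting a region into adjacent halves changes nothing
  split_regs <- regions(c("P1", "P1", "P1"), c(1, 26, 41), c(25, 50, 60))
  expect_equal(coverage_stats(split_regs, proteins),
               coverage_stats(regs, proteins))
})

test_that("tail fit recovers a planted exponent and rejects degenerate input", {
  set.seed(59)
  x <- 1 * runif(10000)^(-1 / 1.25)  # pure Pareto, alpha = 1.25
  res <- size_ccdf_and_tail_fit(x)
  expect_lt(abs(res$fit$exponent - 1.25), 0.05)
  expect_equal(res$fit$stderr, res$fit$exponent / sqrt(10000))
  # CCDF is a proper survival table
  expect_equal(res$ccdf$ccdf[1], 1)
  expect_true(all(diff(res$ccdf$ccdf) <= 0))
  expect_error(size_ccdf_and_tail_fit(rep(5, 100)), "degenerate")
  # duplicating every observation leaves the exponent unchanged
  res2 <- size_ccdf_and_tail_fit(c(x, x))
  expect_equal(res2$fit$exponent, res$fit$exponent)
})

test_that("compare_metaclusters assembles coherent records", {
  ann <- ann_fixture()
  good <- mc_with_seeds(regions(rep("P1", 4), rep(10L, 4), rep(180L, 4)),
                        id = "MC0001")
  unk <- mc_with_seeds(regions("Z1", 1, 50), id = "MC0002")
  rec <- compare_metaclusters(list(good, unk), ann)
  expect_identical(rec$DA, c("FA;FB", "UNK"))
  expect_identical(rec$Label, c("equivalent", "UNK"))
  expect_equal(rec$Pfam_sequences, c(4, 0))
  expect_true(all(is.na(rec[2, c("Fred", "Fext")])))
})
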