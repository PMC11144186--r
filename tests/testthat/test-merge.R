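test_that("metacluster distance is the mean over all member pairs", {
  a <- mk_mc(list(mk_pc("Q1", c("P1", "P2"))), id = "MCa")
  expect_equal(metacluster_distance(a, a), 0)
  b <- mk_mc(list(mk_pc("Q2", c("Z1", "Z2"))), id = "MCb")
  expect_equal(metacluster_distance(a, b), 1)
  # 2x2 primary clusters with distances (0.8, 0.9, 0.8, 0.9) -> 0.85
  p1 <- mk_pc("Qa1", sprintf("S%02d", 1:10))
  p2 <- mk_pc("Qa2", c(sprintf("S%02d", 1:2), sprintf("T%d", 1:8)))
  A <- mk_mc(list(p1, p2), id = "A")
  q1 <- mk_pc("Qb1", c(sprintf("S%02d", 1:2), sprintf("U%d", 1:8)))
  # shares 2 with p1 (0.8) and 1 with p2 via S01? construct explicitly:
  expect_equal(primary_cluster_distance(p1, q1), 0.8)
  q2 <- mk_pc("Qb2", c("S01", sprintf("V%d", 1:9)))
  B <- mk_mc(list(q1, q2), id = "B")
  d11 <- primary_cluster_distance(p1, q1)
  d12 <- primary_cluster_distance(p1, q2)
  d21 <- primary_cluster_distance(p2, q1)
  d22 <- primary_cluster_distance(p2, q2)
  expect_equal(metacluster_distance(A, B), mean(c(d11, d12, d21, d22)))
})

test_that("merge rule: 0.85 merges, 0.95 does not, chains close transitively", {
  a <- mk_mc_sharing(3L, "MCa", "A")   # d(a,b) = 1 - 3/20 = 0.85
  b <- mk_mc_sharing(3L, "MCb", "B")
  res <- merge_metaclusters(list(a, b))
  expect_length(res$metaclusters, 1)
  expect_equal(res$decisions$avg_distance, 0.85)
  expect_true(res$decisions$merged)

  a1 <- mk_mc_sharing(1L, "MCa", "A")  # d = 1 - 1/20 = 0.95
  b1 <- mk_mc_sharing(1L, "MCb", "B")
  res2 <- merge_metaclusters(list(a1, b1))
  expect_length(res2$metaclusters, 2)
  expect_false(res2$decisions$merged)

  # chain: A-B close, B-C close, A-C far -> one component of 3
  pa <- mk_pc("Qa", c(sprintf("AB%02d", 1:4), sprintf("A%d", 1:6)))
  pb <- mk_pc("Qb", c(sprintf("AB%02d", 1:4), sprintf("BC%02d", 1:4),
                      "B1", "B2"))
  pc_ <- mk_pc("Qc", c(sprintf("BC%02d", 1:4), sprintf("C%d", 1:6)))
  A <- mk_mc(list(pa), "MCA"); B <- mk_mc(list(pb), "MCB")
  C <- mk_mc(list(pc_), "MCC")
  expect_lt(metacluster_distance(A, B), 0.9)
  expect_lt(metacluster_distance(B, C), 0.9)
  expect_gte(metacluster_distance(A, C), 0.9)
  res3 <- merge_metaclusters(list(A, B, C))
  expect_length(res3$metaclusters, 1)
})

test_that("merging is idempotent and order-invariant", {
  set.seed(31)
  mcs <- lapply(1:8, function(i) {
    mk_mc(list(mk_pc(sprintf("Q%d", i),
                     sample(sprintf("P%02d", 1:30), 12))),
          id = sprintf("MC%04d", i))
  })
  res <- merge_metaclusters(mcs)
  again <- merge_metaclusters(res$metaclusters)
  expect_length(again$metaclusters, length(res$metaclusters))
  expect_true(all(!again$decisions$merged))
  base <- seed_partition(res$metaclusters)
  for (k in 1:20) {
    perm <- sample(length(mcs))
    resp <- merge_metaclusters(mcs[perm])
    expect_identical(seed_partition(resp$metaclusters), base)
  }
})

test_that("optional shared-support mode drops single-source seeds", {
  a <- mk_mc_sharing(3L, "MCa", "A")
  b <- mk_mc_sharing(3L, "MCb", "B")
  strict <- merge_metaclusters(list(a, b), keep_shared_only = TRUE)
  expect_length(strict$metaclusters, 1)
  expect_identical(nrow(strict$metaclusters[[1]]$seeds), 3L)
  loose <- merge_metaclusters(list(a, b))
  expect_identical(nrow(loose$metaclusters[[1]]$seeds), 37L)
})

test_that("seed dedup keeps the longest of near-duplicates", {
  mc <- mk_mc(list(mk_pc("Q", "P1")), id = "MC0001")
  mc$seeds <- regions(c("P1", "P1", "P1", "P2"),
                      c(1L, 2L, 200L, 1L), c(100L, 100L, 300L, 100L))
  out <- deduplicate_seeds(mc)
  expect_identical(nrow(out$seeds), 3L)
  expect_true(any(out$seeds$start == 1L & out$seeds$end == 100L &
                    out$seeds$protein_id == "P1"))
  expect_false(any(out$seeds$start == 2L))
  # identical duplicates collapse
  mc$seeds <- regions(c("P1", "P1"), c(5L, 5L), c(50L, 50L))
  expect_identical(nrow(deduplicate_seeds(mc)$seeds), 1L)
})

test_that("size/length filter is strict on both bounds", {
  keep <- mk_mc_seeds(rep(60L, 51))          # 51 seeds, mean 60
  drop_n <- mk_mc_seeds(rep(60L, 50))        # 50 seeds
  drop_len <- mk_mc_seeds(rep(50L, 51))      # mean exactly 50
  keep_len <- mk_mc_seeds(c(rep(50L, 50), 56L))  # 51 seeds, mean 50.12
  out <- filter_metaclusters(list(keep, drop_n, drop_len, keep_len))
  expect_length(out, 2)
})

test_that("mc statistics use the population standard deviation", {
  expect_equal(mc_statistics(mk_mc_seeds(100L)),
               c(seed_count = 1, mean_length = 100, sd_length = 0))
  expect_equal(mc_statistics(mk_mc_seeds(c(40L, 60L))),
               c(seed_count = 2, mean_length = 50, sd_length = 10))
  expect_equal(mc_statistics(mk_mc_seeds(c(50L, 50L, 50L)))[["sd_length"]],
               0)
})

test_that("seed FASTA extraction uses protein/start-end headers", {
  proteins <- c(P1 = paste(rep(c("M", "K", "V", "W"), 25), collapse = ""))
  mc <- mk_mc(list(mk_pc("Q", "P1", len = 8L, starts = 3L)), id = "MC1")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_seed_fasta(mc, proteins, f)
  fa <- read_fasta(f)
  expect_identical(names(fa), "P1/3-10")
  expect_identical(unname(fa), substr(proteins[["P1"]], 3, 10))
})
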