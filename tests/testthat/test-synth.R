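test_that("proteome generation is deterministic and bookkeeps regions", {
  d <- planted_design(n_families = 2, n_proteins = 20, seed = 7)
  pr <- generate_proteome(d)
  expect_length(pr$proteins, 20)
  expect_identical(nrow(pr$truth), 20L)
  expect_true(all(pr$truth$end <= nchar(pr$proteins[pr$truth$protein_id])))
  # every planted region reads back as a mutated family copy
  expect_true(all(pr$truth$family_id %in% c("F1", "F2")))
  pr2 <- generate_proteome(d)
  expect_identical(pr2$proteins, pr$proteins)
  expect_identical(pr2$truth, pr$truth)
  # different seed, different sequences
  pr3 <- generate_proteome(planted_design(n_families = 2,
                                          n_proteins = 20, seed = 8))
  expect_false(identical(pr3$proteins, pr$proteins))
})

test_that("zero substitution rate reproduces ancestors exactly", {
  d <- planted_design(n_families = 2, n_proteins = 6, seed = 3,
                      substitution_rate = 0)
  pr <- generate_proteome(d)
  same_fam <- split(seq_len(6), unlist(d$architectures))
  for (idx in same_fam) {
    doms <- vapply(idx, function(p) {
      tr <- pr$truth[pr$truth$protein_id == names(pr$proteins)[p], ]
      substr(pr$proteins[[p]], tr$start, tr$end)
    }, character(1))
    expect_length(unique(doms), 1)
  }
})

test_that("design validation rejects out-of-range parameters", {
  expect_error(planted_design(substitution_rate = 0.6), "substitution")
  expect_error(planted_design(family_length_range = c(10, 50)), ">= 30")
  expect_error(planted_design(n_proteins = 3,
                              architectures = list("F1")), "per protein")
})

test_that("smith_waterman: identical sequences and disjoint alphabets", {
  sc <- default_scoring()
  a <- strrep("MKVLWAYDER", 5)
  r <- smith_waterman(a, a, sc)
  expect_equal(unname(r$a_region), c(1, 50))
  expect_equal(unname(r$b_region), c(1, 50))
  expect_identical(r$matches, 50L)
  # the self-alignment score equals the sum of diagonal matrix entries
  idx <- match(strsplit(a, "")[[1]], rownames(sc$matrix))
  expect_identical(r$score, sum(diag(sc$matrix)[idx]))

  # no positive-scoring pair -> empty alignment
  mat <- matrix(-1L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  diag(mat) <- 2L
  sc2 <- list(matrix = mat, alphabet = "AB", gap_open = 2L,
              gap_extend = 1L)
  r2 <- smith_waterman("AAAA", "BBBB", sc2)
  expect_identical(r2$score, 0L)
  expect_null(r2$a_region)
})

test_that("smith_waterman equals the exhaustive DP oracle on short pairs", {
  mat <- matrix(-1L, 4, 4,
                dimnames = list(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")))
  diag(mat) <- 2L
  sc <- list(matrix = mat, alphabet = "ACGT", gap_open = 2L,
             gap_extend = 1L)
  score_fun <- function(x, y) if (x == y) 2 else -1
  set.seed(61)
  for (k in 1:150) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:12, 1),
                      replace = TRUE), collapse = "")
    got <- smith_waterman(a, b, sc)$score
    want <- oracle_sw_score(a, b, score_fun, 2, 1)
    expect_identical(got, as.integer(want))
  }
})

test_that("all_vs_all recovers planted domains and respects bounds", {
  d <- planted_design(n_families = 1, n_proteins = 3, seed = 11)
  pr <- generate_proteome(d)
  hits <- all_vs_all(pr$proteins, max_hsps = 5L)
  expect_lte(nrow(hits), 3 * 2 * 5)
  # each ordered pair of same-family proteins shares the planted domain
  for (q in names(pr$proteins)) {
    qh <- hits[hits$query_id == q, ]
    expect_gte(nrow(qh), 1)
    tr <- pr$truth[pr$truth$protein_id == q, ]
    jac <- famdpc:::interval_jaccard(qh$qstart, qh$qend, tr$start, tr$end)
    expect_gte(max(jac), 0.7)
  }
  # an unreachable score threshold empties the output
  none <- all_vs_all(pr$proteins, score_min = 100000L)
  expect_identical(nrow(none), 0L)
})

test_that("recovery scoring: perfect, lumped and shuffled partitions", {
  d <- planted_design(n_families = 2, n_proteins = 8, seed = 13,
                      substitution_rate = 0)
  pr <- generate_proteome(d)
  perfect <- lapply(c("F1", "F2"), function(f) {
    tr <- pr$truth[pr$truth$family_id == f, ]
    mc <- mk_mc(list(mk_pc("Q", tr$protein_id)), id = paste0("MC", f))
    mc$seeds <- regions(tr$protein_id, tr$start, tr$end)
    mc
  })
  res <- planted_recovery_score(perfect, pr$truth)
  expect_equal(res$ari, 1)
  expect_equal(res$family_recall, 1)

  lumped <- mk_mc(list(mk_pc("Q", pr$truth$protein_id)), id = "MC1")
  lumped$seeds <- regions(pr$truth$protein_id, pr$truth$start,
                          pr$truth$end)
  res2 <- planted_recovery_score(list(lumped), pr$truth)
  expect_equal(res2$ari, 0)
  expect_equal(res2$family_recall, 0.5)
})

test_that("adjusted Rand index behaves at its anchors", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  set.seed(67)
  x <- sample(1:5, 400, replace = TRUE)
  y <- sample(x)  # random permutation: chance-level agreement
  expect_lt(abs(adjusted_rand_index(x, y)), 0.1)
})
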