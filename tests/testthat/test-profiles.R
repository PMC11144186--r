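test_that("greedy pruning joins mutants to their ancestor, keeps strangers", {
  set.seed(41)
  a <- random_aa(80)
  av <- strsplit(a, "")[[1]]
  idx <- sample(80, 8)  # 10% point mutations
  av[idx] <- vapply(av[idx], function(x) {
    sample(setdiff(famdpc:::AA20, x), 1)
  }, character(1))
  a_mut <- paste(av, collapse = "")
  b <- random_aa(70)
  pruned <- greedy_identity_prune(c(anc = a, mut = a_mut, other = b))
  expect_setequal(names(pruned$representatives), c("anc", "other"))
  expect_identical(unname(pruned$assignment["mut"]), "anc")

  # identical sequences collapse to one representative
  p2 <- greedy_identity_prune(c(x = a, y = a))
  expect_length(p2$representatives, 1)
  expect_error(greedy_identity_prune(character(0)))
})

test_that("representative count is monotone in the identity threshold", {
  set.seed(43)
  base <- random_aa(60)
  seqs <- c(base, vapply(1:6, function(i) {
    v <- strsplit(base, "")[[1]]
    k <- sample(60, 6 * i)
    v[k] <- sample(famdpc:::AA20, length(k), replace = TRUE)
    paste(v, collapse = "")
  }, character(1)), random_aa(60))
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  counts <- vapply(c(1.0, 0.8, 0.6, 0.4, 0.2), function(thr) {
    length(greedy_identity_prune(seqs, thr)$representatives)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("null backend emits a padded stacked pseudo-MSA", {
  pruned <- greedy_identity_prune(
    c(a = "MKVLW", b = "MKV", c = "MKVLWYA", d = "AAAA", e = "Q"),
    threshold = 1.0)
  out <- build_family_artifacts(pruned, withr::local_tempfile(),
                                backend = null_backend())
  expect_false(out$aligned)
  msa <- read_fasta(out$msa)
  expect_length(msa, length(pruned$representatives))
  expect_length(unique(nchar(msa)), 1)
  expect_error(build_family_artifacts(
    list(representatives = character(0)), tempfile()), "empty")
})

test_that("real backend produces MSA and profile files", {
  set.seed(47)
  base <- random_aa(60)
  seqs <- vapply(1:5, function(i) {
    v <- strsplit(base, "")[[1]]
    k <- sample(60, 5)
    v[k] <- sample(famdpc:::AA20, 5, replace = TRUE)
    paste(v, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%d", 1:5)
  pruned <- greedy_identity_prune(seqs, threshold = 1.0)
  out <- build_family_artifacts(pruned, withr::local_tempfile(),
                                backend = external_backend())
  expect_true(out$aligned)
  expect_gt(file.size(out$msa), 0)
  expect_gt(file.size(out$hmm), 0)

  # profile search against proteins embedding the family
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(hit1 = paste0(random_aa(20), base, random_aa(20)),
                miss = random_aa(150)), fa)
  hits <- hmmsearch_handoff(out$hmm, fa)
  expect_true("hit1" %in% hits$protein_id)
  expect_false("miss" %in% hits$protein_id)
})

test_that("domain-table parsing and E-value thresholding", {
  tbl <- withr::local_tempfile(fileext = ".domtblout")
  hdr <- "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  row <- function(id, pe, de, a1, a2) {
    paste(id, "-", 200, "fam", "-", 80, pe, 55, 0.1, 1, 1, de, de, 50,
          0.1, 1, 80, a1, a2, a1, a2, 0.9, "-")
  }
  writeLines(c(hdr, row("P1", 0.001, 0.01, 10, 90),
               row("P2", 0.001, 0.05, 5, 85)), tbl)
  dom <- parse_domtblout(tbl)
  expect_identical(nrow(dom), 2L)
  kept <- filter_hmm_hits(dom)
  expect_identical(kept$protein_id, "P1")
  expect_identical(kept$start, 10L)

  # empty table
  writeLines(hdr, tbl)
  expect_identical(nrow(parse_domtblout(tbl)), 0L)

  # malformed row carries its line number
  writeLines(c(hdr, "P1 only four fields x"), tbl)
  expect_error(parse_domtblout(tbl), "line 2")
})

test_that("missing search backend raises an explicit error", {
  expect_error(
    hmmsearch_handoff("x.hmm", "y.fasta",
                      backend = external_backend(
                        hmmsearch = "no-such-tool-xyz")),
    "backend unavailable")
})
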