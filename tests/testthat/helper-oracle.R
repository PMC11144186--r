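# Independent brute-force implementations used as oracles. These are
# deliberately written with different control flow from the package
# code: plain loops, no vectorisation, no shared helpers.

# --- density-peak clustering, Rodriguez-Laio style -------------------

oracle_dpc <- function(d, dc, rho_min = 1, delta_min = 0.5) {
  n <- nrow(d)
  rho <- rep(0, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && d[i, j] < dc) rho[i] <- rho[i] + 1
    }
  }
  # j is "denser" than i when rho[j] > rho[i], or equal rho and j < i
  denser_than <- function(i) {
    out <- integer(0)
    for (j in seq_len(n)) {
      if (j == i) next
      if (rho[j] > rho[i] || (rho[j] == rho[i] && j < i)) out <- c(out, j)
    }
    out
  }
  delta <- rep(0, n)
  nearest <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hs <- denser_than(i)
    if (length(hs) == 0) {
      delta[i] <- if (n > 1) max(d[i, setdiff(seq_len(n), i)]) else 0
    } else {
      best <- hs[1]
      for (j in hs) if (d[i, j] < d[i, best]) best <- j
      delta[i] <- d[i, best]
      nearest[i] <- best
    }
  }
  centers <- integer(0)
  for (i in seq_len(n)) {
    if (rho[i] >= rho_min && delta[i] >= delta_min) centers <- c(centers, i)
  }
  if (length(centers) == 0) {
    best <- 1
    for (i in seq_len(n)) if (rho[i] > rho[best]) best <- i
    centers <- best
  }
  lab <- rep(NA_integer_, n)
  for (k in seq_along(centers)) lab[centers[k]] <- k
  ord <- order(-rho, seq_len(n))
  for (i in ord) {
    if (is.na(lab[i])) lab[i] <- lab[nearest[i]]
  }
  list(rho = rho, delta = delta, centers = centers, assignment = lab)
}

# canonical form of a partition (labels renumbered by first appearance)
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# --- affine-gap local alignment score, three-matrix recurrence -------

oracle_sw_score <- function(a, b, score_fun, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             E[i + 1, j] - gap_extend)
      F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                             F[i, j + 1] - gap_extend)
      H[i + 1, j + 1] <- max(0,
                             H[i, j] + score_fun(av[i], bv[j]),
                             E[i + 1, j + 1], F[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# --- fixture builders ------------------------------------------------

# a primary cluster whose members sit on the given proteins, each region
# [1, len]; identical layouts make shared-member counting predictable
mk_pc <- function(query_id, subject_ids, len = 100L,
                  starts = rep(1L, length(subject_ids)),
                  footprint = c(1L, len)) {
  members <- data.frame(subject_id = subject_ids, sstart = starts,
                        send = starts + len - 1L,
                        qstart = rep(footprint[1], length(subject_ids)),
                        qend = rep(footprint[2], length(subject_ids)),
                        stringsAsFactors = FALSE)
  famdpc:::new_primary_cluster(query_id, members)
}

mk_mc <- function(pcs, id = "MC0001") {
  famdpc:::new_metacluster(pcs, id = id)
}

# a metacluster with n seeds of the given lengths, one per protein
mk_mc_seeds <- function(lengths, id = "MC0001", prefix = "P") {
  prots <- sprintf("%s%04d", prefix, seq_along(lengths))
  pcs <- list(mk_pc("Q1", prots, len = 1L))  # placeholder members
  mc <- famdpc:::new_metacluster(pcs, id = id)
  mc$seeds <- regions(prots, rep(1L, length(lengths)),
                      as.integer(lengths))
  mc
}

# metaclusters with a controlled pairwise distance: single primary
# clusters over n proteins sharing exactly k members
mk_mc_sharing <- function(k, id, tag_a = "A", n = 20L) {
  shared <- sprintf("SH%02d", seq_len(k))
  own <- sprintf("%s%02d", tag_a, seq_len(n - k))
  mk_mc(list(mk_pc(paste0("Q", tag_a), c(shared, own))), id = id)
}

random_aa <- function(n, alphabet = famdpc:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# partitions of seed keys, for order-invariance comparisons
seed_partition <- function(mcs) {
  sets <- lapply(mcs, function(mc) {
    sort(paste(mc$seeds$protein_id, mc$seeds$start, mc$seeds$end))
  })
  sets[order(vapply(sets, paste, character(1), collapse = "|"))]
}
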