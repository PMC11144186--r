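#' Distance between two metaclusters
#'
#' The mean primary-cluster distance over all cross pairs of their
#' member primary clusters. Two density peaks separated by a
#' high-density saddle produce metaclusters that still share many
#' sequences; this average detects them.
#'
#' @param A,B metaclusters with at least one primary cluster each.
#' @param overlap_threshold member-overlap threshold passed down to
#'   [primary_cluster_distance()].
#' @return numeric in `[0, 1]`.
#' @export
metacluster_distance <- function(A, B, overlap_threshold = 0.8) {
  if (length(A$primary_members) == 0L || length(B$primary_members) == 0L) {
    stop("metacluster_distance requires non-empty metaclusters")
  }
  vals <- vapply(A$primary_members, function(a) {
    vapply(B$primary_members, function(b) {
      primary_cluster_distance(a, b, overlap_threshold)
    }, numeric(1))
  }, numeric(length(B$primary_members)))
  mean(vals)
}

#' Merge metaclusters closer than a threshold
#'
#' Builds a graph with an edge between every metacluster pair whose
#' average distance is below `merge_threshold` and collapses each
#' connected component into one metacluster (seeds unioned, exact
#' duplicates removed). Component semantics make the result
#' transitive, idempotent and independent of input order.
#'
#' @param mcs list of metaclusters.
#' @param merge_threshold merge when distance is strictly smaller
#'   (default 0.9).
#' @param overlap_threshold member-overlap threshold for the underlying
#'   distance.
#' @param keep_shared_only optional stricter post-merge mode: inside a
#'   merged component, retain only seeds supported by at least two
#'   constituent metaclusters (default off; see the package vignette
#'   for why).
#' @return list with `metaclusters` (relabelled) and `decisions`
#'   (data.frame of pairwise `mc_a`, `mc_b`, `avg_distance`, `merged`).
#' @export
merge_metaclusters <- function(mcs, merge_threshold = 0.9,
                               overlap_threshold = 0.8,
                               keep_shared_only = FALSE) {
  stopifnot(merge_threshold > 0, merge_threshold <= 1)
  n <- length(mcs)
  if (n == 0L) {
    return(list(metaclusters = list(), decisions = empty_merge_log()))
  }
  ids <- vapply(mcs, function(mc) mc$id, character(1))
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  decisions <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        dij <- metacluster_distance(mcs[[i]], mcs[[j]], overlap_threshold)
        merged <- dij < merge_threshold
        decisions[[length(decisions) + 1L]] <- data.frame(
          mc_a = ids[i], mc_b = ids[j], avg_distance = dij,
          merged = merged, stringsAsFactors = FALSE)
        if (merged) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  merged_mcs <- lapply(comps, function(idx) {
    pcs <- do.call(c, lapply(mcs[idx], function(mc) mc$primary_members))
    out <- new_metacluster(pcs)
    if (keep_shared_only && length(idx) > 1L) {
      support <- seed_support(mcs[idx])
      keep <- support >= 2L
      out$seeds <- out$seeds[keep, , drop = FALSE]
      rownames(out$seeds) <- NULL
    }
    out
  })
  log <- if (length(decisions) > 0L) do.call(rbind, decisions) else
    empty_merge_log()
  list(metaclusters = relabel_metaclusters(merged_mcs), decisions = log)
}

# for each deduplicated seed of the merged component, in how many of the
# constituent metaclusters does it appear?
seed_support <- function(mcs) {
  keyed <- lapply(mcs, function(mc) {
    unique(paste(mc$seeds$protein_id, mc$seeds$start, mc$seeds$end))
  })
  counts <- table(unlist(keyed))
  pcs <- do.call(c, lapply(mcs, function(mc) mc$primary_members))
  merged <- new_metacluster(pcs)
  as.integer(counts[paste(merged$seeds$protein_id, merged$seeds$start,
                          merged$seeds$end)])
}

empty_merge_log <- function() {
  data.frame(mc_a = character(), mc_b = character(),
             avg_distance = numeric(), merged = logical(),
             stringsAsFactors = FALSE)
}

#' Remove near-duplicate seeds within a metacluster
#'
#' Among seeds on the same protein whose pairwise interval Jaccard
#' exceeds `overlap_threshold`, only the longest is retained (ties to
#' the smaller start coordinate).
#'
#' @param mc a metacluster.
#' @param overlap_threshold strict Jaccard threshold, default 0.8.
#' @return the metacluster with deduplicated seeds.
#' @export
deduplicate_seeds <- function(mc, overlap_threshold = 0.8) {
  s <- mc$seeds
  if (nrow(s) < 2L) return(mc)
  keep <- logical(nrow(s))
  # longest first, ties by smaller start
  ord <- order(-(s$end - s$start), s$start, s$protein_id)
  for (i in ord) {
    kept <- which(keep & s$protein_id == s$protein_id[i])
    if (length(kept) > 0L) {
      jac <- interval_jaccard(s$start[i], s$end[i], s$start[kept],
                              s$end[kept])
      if (any(jac > overlap_threshold)) next
    }
    keep[i] <- TRUE
  }
  mc$seeds <- s[keep, , drop = FALSE]
  mc$seeds <- mc$seeds[order(mc$seeds$protein_id, mc$seeds$start,
                             mc$seeds$end), , drop = FALSE]
  rownames(mc$seeds) <- NULL
  mc
}

#' Size and length filter
#'
#' Keeps metaclusters with strictly more than `min_seeds` seeds and a
#' mean seed length strictly above `min_mean_length` amino acids (both
#' inequalities strict, matching the release rule "more than 50 protein
#' seeds and an average sequence length of more than 50 amino acids").
#'
#' @param mcs list of metaclusters.
#' @param min_seeds,min_mean_length strict lower bounds, both 50 by
#'   default.
#' @return filtered list (ids preserved).
#' @export
filter_metaclusters <- function(mcs, min_seeds = 50, min_mean_length = 50) {
  stopifnot(min_seeds > 0, min_mean_length > 0)
  keep <- vapply(mcs, function(mc) {
    n <- nrow(mc$seeds)
    n > min_seeds && mean(region_length(mc$seeds)) > min_mean_length
  }, logical(1))
  mcs[keep]
}

#' Seed statistics of a metacluster
#'
#' @param mc non-empty metacluster.
#' @return `c(seed_count, mean_length, sd_length)`; the standard
#'   deviation uses the population (n) divisor.
#' @export
mc_statistics <- function(mc) {
  n <- nrow(mc$seeds)
  if (n == 0L) stop("metacluster has no seeds")
  len <- region_length(mc$seeds)
  m <- mean(len)
  c(seed_count = n, mean_length = m,
    sd_length = sqrt(mean((len - m)^2)))
}

#' Extract seed subsequences to FASTA
#'
#' Headers follow the `proteinid/start-end` convention.
#'
#' @param mc metacluster.
#' @param proteins named character vector of full-length sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_seed_fasta <- function(mc, proteins, path) {
  s <- mc$seeds
  miss <- setdiff(unique(s$protein_id), names(proteins))
  if (length(miss) > 0L) stop("seed protein absent from protein set: ",
                              miss[1])
  seqs <- substring(proteins[s$protein_id], s$start, s$end)
  names(seqs) <- sprintf("%s/%d-%d", s$protein_id, s$start, s$end)
  write_fasta(seqs, path)
}

#' Seed subsequences of a metacluster
#' @inheritParams write_seed_fasta
#' @return named character vector (`proteinid/start-end` names).
#' @export
seed_sequences <- function(mc, proteins) {
  s <- mc$seeds
  seqs <- substring(proteins[s$protein_id], s$start, s$end)
  names(seqs) <- sprintf("%s/%d-%d", s$protein_id, s$start, s$end)
  seqs
}
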