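#' Members shared by two primary clusters
#'
#' Counts member pairs — one region from each cluster, on the same
#' subject protein — whose interval Jaccard overlap exceeds
#' `overlap_threshold`. Matching is greedy one-to-one (best overlap
#' first, ties to the pair with the longer region) so no member is
#' counted twice; the count is therefore bounded by the smaller
#' cluster's size.
#'
#' @param a,b primary clusters.
#' @param overlap_threshold minimum (strict) Jaccard overlap, default
#'   0.8.
#' @return integer count.
#' @export
shared_member_count <- function(a, b, overlap_threshold = 0.8) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  ma <- a$members; mb <- b$members
  common <- intersect(unique(ma$subject_id), unique(mb$subject_id))
  if (length(common) == 0L) return(0L)
  ia <- which(ma$subject_id %in% common)
  ib <- which(mb$subject_id %in% common)
  # candidate pairs on the same protein
  g <- expand.grid(i = ia, j = ib)
  g <- g[ma$subject_id[g$i] == mb$subject_id[g$j], , drop = FALSE]
  if (nrow(g) == 0L) return(0L)
  jac <- interval_jaccard(ma$sstart[g$i], ma$send[g$i],
                          mb$sstart[g$j], mb$send[g$j])
  keep <- jac > overlap_threshold
  g <- g[keep, , drop = FALSE]
  jac <- jac[keep]
  if (nrow(g) == 0L) return(0L)
  pairlen <- pmax(ma$send[g$i] - ma$sstart[g$i],
                  mb$send[g$j] - mb$sstart[g$j])
  ord <- order(-jac, -pairlen, g$i, g$j)
  used_a <- logical(nrow(ma)); used_b <- logical(nrow(mb))
  count <- 0L
  for (k in ord) {
    i <- g$i[k]; j <- g$j[k]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    count <- count + 1L
  }
  count
}

#' Distance between two primary clusters
#'
#' One minus the shared-member count normalised by the size of the
#' smaller cluster, so clusters drawing on the same subject regions are
#' close (0 for identical member sets) and clusters sharing nothing are
#' at distance 1.
#'
#' @inheritParams shared_member_count
#' @return numeric in `[0, 1]`.
#' @export
primary_cluster_distance <- function(a, b, overlap_threshold = 0.8) {
  na <- nrow(a$members); nb <- nrow(b$members)
  stopifnot(na >= 1L, nb >= 1L)
  shared <- shared_member_count(a, b, overlap_threshold)
  1 - shared / min(na, nb)
}

# Dense distance matrix over primary clusters; pairs without a shared
# subject protein stay at distance 1 and are skipped (sparse contract).
primary_cluster_distance_matrix <- function(pcs, overlap_threshold = 0.8) {
  n <- length(pcs)
  d <- matrix(1, n, n)
  diag(d) <- 0
  prots <- lapply(pcs, function(pc) unique(pc$members$subject_id))
  # invert: protein -> clusters touching it
  idx <- split(rep(seq_len(n), lengths(prots)), unlist(prots))
  cand <- unique(do.call(rbind, lapply(idx, function(v) {
    if (length(v) < 2L) return(NULL)
    t(utils::combn(sort(v), 2L))
  })))
  if (!is.null(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (d[i, j] < 1) next
      dij <- primary_cluster_distance(pcs[[i]], pcs[[j]], overlap_threshold)
      d[i, j] <- dij; d[j, i] <- dij
    }
  }
  d
}

#' Group primary clusters into metaclusters
#'
#' Second density-peak stage: primary clusters from different queries
#' that keep recruiting the same subject regions are grouped together.
#' Each partition class is flattened into a metacluster whose seeds are
#' the union of its members' subject regions (exact duplicates
#' removed).
#'
#' @param primary_clusters non-empty list of primary clusters.
#' @param overlap_threshold member-overlap threshold for
#'   [shared_member_count()].
#' @param dpc_control list of arguments forwarded to [dpc()].
#' @return list of metaclusters, ids `MC0001, ...` assigned by
#'   decreasing seed count; each has `id`, `primary_members` (list of
#'   primary clusters) and `seeds` (region data.frame).
#' @export
metacluster <- function(primary_clusters, overlap_threshold = 0.8,
                        dpc_control = list()) {
  stopifnot(length(primary_clusters) >= 1L)
  d <- primary_cluster_distance_matrix(primary_clusters, overlap_threshold)
  fit <- do.call(dpc, c(list(d = d), dpc_control))
  groups <- split(seq_along(primary_clusters), fit$assignment)
  mcs <- lapply(groups, function(idx) {
    new_metacluster(primary_clusters[idx])
  })
  relabel_metaclusters(mcs)
}

new_metacluster <- function(pcs, id = NA_character_) {
  seeds <- do.call(rbind, lapply(pcs, function(pc) {
    data.frame(protein_id = pc$members$subject_id,
               start = pc$members$sstart, end = pc$members$send,
               stringsAsFactors = FALSE)
  }))
  seeds <- unique(seeds)
  seeds <- seeds[order(seeds$protein_id, seeds$start, seeds$end), ,
                 drop = FALSE]
  rownames(seeds) <- NULL
  class(seeds) <- c("fam_regions", "data.frame")
  structure(list(id = id, primary_members = pcs, seeds = seeds),
            class = "metacluster")
}

# Stable ids: decreasing seed count, ties by smallest query id of the
# first primary member, so output ordering is diffable.
relabel_metaclusters <- function(mcs) {
  sizes <- vapply(mcs, function(mc) nrow(mc$seeds), integer(1))
  anchor <- vapply(mcs, function(mc) {
    min(vapply(mc$primary_members, function(pc) pc$query_id, character(1)))
  }, character(1))
  ord <- order(-sizes, anchor)
  mcs <- mcs[ord]
  for (i in seq_along(mcs)) mcs[[i]]$id <- sprintf("MC%04d", i)
  unname(mcs)
}

#' @export
print.metacluster <- function(x, ...) {
  cat(sprintf("<metacluster %s> %d primary clusters, %d seeds\n",
              x$id, length(x$primary_members), nrow(x$seeds)))
  invisible(x)
}

#' Dump metaclusters as TSV
#' @param mcs list of metaclusters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metacluster_table <- function(mcs, path) {
  rows <- lapply(mcs, function(mc) {
    data.frame(mc_id = mc$id,
               primary_cluster_count = length(mc$primary_members),
               seed_count = nrow(mc$seeds), stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(mc_id = character(), primary_cluster_count = integer(),
               seed_count = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
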