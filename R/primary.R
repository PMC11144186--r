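#' Cluster the aligned regions of one query sequence
#'
#' Groups the hits of a single query by the overlap of their query
#' footprints (the footprint Jaccard distance), using density-peak
#' clustering. Each resulting primary cluster is a high-density region
#' along the query — a domain-like segment — and carries, for every
#' member hit, the subject region (the future seed material) together
#' with its query footprint. Clusters with fewer than `min_members`
#' hits are discarded: singleton density peaks are unreliable.
#'
#' @param hits data.frame of alignment rows sharing one `query_id`
#'   (columns as in [read_alignment_table()]).
#' @param min_members minimum member count for a cluster to be kept.
#' @param dpc_control list of arguments forwarded to [dpc()]
#'   (`dc`, `kernel`, `rho_min`, `delta_min`).
#' @return list of primary clusters; each is a list with `query_id`,
#'   `footprint` (`c(start, end)`, the coordinate-wise median of member
#'   footprints), and `members` (data.frame `subject_id`, `sstart`,
#'   `send`, `qstart`, `qend`).
#' @export
cluster_query <- function(hits, min_members = 2L, dpc_control = list()) {
  stopifnot(nrow(hits) >= 1L)
  qid <- unique(hits$query_id)
  if (length(qid) != 1L) stop("cluster_query expects hits of a single query")
  d <- footprint_distance_matrix(hits$qstart, hits$qend)
  fit <- do.call(dpc, c(list(d = d), dpc_control))
  out <- list()
  for (lab in sort(unique(fit$assignment))) {
    idx <- which(fit$assignment == lab)
    if (length(idx) < min_members) next
    members <- data.frame(
      subject_id = hits$subject_id[idx],
      sstart = hits$sstart[idx], send = hits$send[idx],
      qstart = hits$qstart[idx], qend = hits$qend[idx],
      stringsAsFactors = FALSE
    )
    out[[length(out) + 1L]] <- new_primary_cluster(qid, members)
  }
  out
}

new_primary_cluster <- function(query_id, members) {
  footprint <- c(
    start = as.integer(round(stats::median(members$qstart))),
    end = as.integer(round(stats::median(members$qend)))
  )
  structure(
    list(query_id = query_id, footprint = footprint, members = members),
    class = "primary_cluster"
  )
}

#' @export
print.primary_cluster <- function(x, ...) {
  cat(sprintf("<primary cluster> query %s [%d, %d], %d members\n",
              x$query_id, x$footprint[["start"]], x$footprint[["end"]],
              nrow(x$members)))
  invisible(x)
}

#' Primary clustering across all queries
#'
#' Applies [cluster_query()] to every query independently; queries are
#' processed in sorted id order so the result is reproducible and, the
#' per-query problems being independent, identical under any input row
#' order.
#'
#' @param hits full hit table.
#' @inheritParams cluster_query
#' @return flat list of primary clusters.
#' @export
cluster_all_queries <- function(hits, min_members = 2L,
                                dpc_control = list()) {
  if (nrow(hits) == 0L) return(list())
  out <- list()
  for (qid in sort(unique(hits$query_id))) {
    qhits <- hits[hits$query_id == qid, , drop = FALSE]
    qhits <- qhits[order(qhits$qstart, qhits$qend, qhits$subject_id,
                         qhits$sstart, qhits$send), , drop = FALSE]
    out <- c(out, cluster_query(qhits, min_members, dpc_control))
  }
  out
}

#' Dump primary clusters as TSV
#' @param pcs list of primary clusters.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_primary_clusters <- function(pcs, path) {
  rows <- lapply(seq_along(pcs), function(i) {
    pc <- pcs[[i]]
    data.frame(query_id = pc$query_id, cluster_index = i,
               footprint_start = pc$footprint[["start"]],
               footprint_end = pc$footprint[["end"]],
               member_count = nrow(pc$members), stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(query_id = character(), cluster_index = integer(),
               footprint_start = integer(), footprint_end = integer(),
               member_count = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
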