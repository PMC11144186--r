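#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline. The defaults are the
#' published operating point: member-overlap 0.8, merge threshold 0.9,
#' release filter at more than 50 seeds and more than 50 aa mean seed
#' length, seed pruning at 60\% identity, and profile-search reporting
#' thresholds of 0.03 (domain) and 0.01 (protein) E-value. The
#' density-peak thresholds of the two clustering stages are this
#' package's own defaults (the original parameterisation is not
#' published) and are fully exposed here.
#'
#' @param member_overlap strict Jaccard threshold for counting shared
#'   members (0.8).
#' @param merge_threshold merge metaclusters at average distance below
#'   this (0.9).
#' @param min_seeds,min_mean_length strict release-filter bounds (50,
#'   50).
#' @param prune_identity seed-pruning identity (0.60).
#' @param domain_evalue,protein_evalue profile-search thresholds
#'   (0.03, 0.01).
#' @param min_members minimum members of a primary cluster (2).
#' @param dpc_primary,dpc_meta lists of [dpc()] arguments for the two
#'   stages (`dc = NULL` means the percentile heuristic).
#' @param score_min,max_hsps all-versus-all alignment controls.
#' @param keep_shared_only stricter post-merge seed retention mode,
#'   default off.
#' @param seed integer RNG seed recorded with every run.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(member_overlap = 0.8, merge_threshold = 0.9,
                            min_seeds = 50, min_mean_length = 50,
                            prune_identity = 0.60, domain_evalue = 0.03,
                            protein_evalue = 0.01, min_members = 2L,
                            dpc_primary = list(rho_min = 1, delta_min = 0.5),
                            dpc_meta = list(rho_min = 1, delta_min = 0.5),
                            score_min = 100L, max_hsps = 5L,
                            keep_shared_only = FALSE, seed = 1L) {
  structure(list(
    member_overlap = member_overlap, merge_threshold = merge_threshold,
    min_seeds = min_seeds, min_mean_length = min_mean_length,
    prune_identity = prune_identity, domain_evalue = domain_evalue,
    protein_evalue = protein_evalue, min_members = as.integer(min_members),
    dpc_primary = dpc_primary, dpc_meta = dpc_meta,
    score_min = as.integer(score_min), max_hsps = as.integer(max_hsps),
    keep_shared_only = keep_shared_only, seed = as.integer(seed)
  ), class = "pipeline_config")
}

# flat key=value serialisation (lists flattened with dotted keys)
config_lines <- function(config) {
  flat <- unlist(config)
  paste0(names(flat), "=", vapply(flat, format, character(1)))
}

#' Parse a flat key=value config file
#' @param path file with one `key=value` per line.
#' @return `pipeline_config` with the listed keys overridden.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  config <- pipeline_config()
  for (pair in kv) {
    key <- trimws(pair[1]); val <- trimws(pair[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num else if (val %in% c("TRUE", "FALSE"))
      as.logical(val) else val
    if (length(parts) == 1L) config[[parts]] <- parsed
    else config[[parts[1]]][[parts[2]]] <- parsed
  }
  config
}

#' Run the full family-discovery pipeline
#'
#' Executes all stages — all-versus-all alignment (when hits are not
#' supplied), per-query primary clustering, metaclustering, merging,
#' seed de-duplication, the release size/length filter, seed pruning —
#' plus, when reference annotations and residue tracks are available,
#' the comparison and composition analytics, and writes every artifact
#' into `out_dir`. A failing stage aborts with the stage name and
#' leaves a `FAILED` marker next to the partial outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param proteins named character vector of sequences, or a FASTA
#'   path.
#' @param hits hit data.frame or alignment-table path; `NULL` computes
#'   the built-in all-versus-all alignment.
#' @param annotations annotation data.frame or TSV path, optional.
#' @param tracks `fam_tracks` object or TSV path, optional.
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(out_dir, proteins, hits = NULL,
                         annotations = NULL, tracks = NULL,
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  cfg_path <- file.path(out_dir, "config.txt")
  writeLines(config_lines(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  logf("config_hash=%s", cfg_hash)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name,
                         conditionMessage(e)), failed_marker)
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins)) {
    proteins <- stage("read_fasta", read_fasta(proteins))
  }
  if (is.character(annotations)) {
    annotations <- stage("read_annotations", read_annotations(annotations))
  }
  if (is.character(tracks)) {
    tracks <- stage("read_tracks", read_tracks(tracks, proteins))
  }
  set.seed(config$seed)
  if (is.null(hits)) {
    hits <- stage("all_vs_all", all_vs_all(
      proteins, score_min = config$score_min, max_hsps = config$max_hsps))
    write_alignment_table(hits, file.path(out_dir, "alignments.tsv"))
  } else if (is.character(hits)) {
    hits <- stage("read_alignment_table", read_alignment_table(hits))
  }
  logf("hits=%d queries=%d", nrow(hits), length(unique(hits$query_id)))

  pcs <- stage("primary_clustering", cluster_all_queries(
    hits, min_members = config$min_members,
    dpc_control = config$dpc_primary))
  write_primary_clusters(pcs, file.path(out_dir, "primary_clusters.tsv"))
  write_primary_members(pcs, file.path(out_dir, "primary_members.tsv"))
  logf("primary_clusters=%d", length(pcs))
  if (length(pcs) == 0L) stop("stage primary_clustering produced no clusters")

  mcs_pre <- stage("metaclustering", metacluster(
    pcs, overlap_threshold = config$member_overlap,
    dpc_control = config$dpc_meta))
  write_metacluster_table(mcs_pre,
                          file.path(out_dir, "metaclusters_pre_merge.tsv"))
  logf("metaclusters_pre_merge=%d", length(mcs_pre))

  merged <- stage("merging", merge_metaclusters(
    mcs_pre, merge_threshold = config$merge_threshold,
    overlap_threshold = config$member_overlap,
    keep_shared_only = config$keep_shared_only))
  utils::write.table(merged$decisions,
                     file.path(out_dir, "merge_log.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mcs <- stage("seed_dedup", lapply(merged$metaclusters,
                                    deduplicate_seeds,
                                    overlap_threshold = config$member_overlap))
  logf("metaclusters_post_merge=%d", length(mcs))

  filtered <- stage("filtering", filter_metaclusters(
    mcs, min_seeds = config$min_seeds,
    min_mean_length = config$min_mean_length))
  write_metacluster_table(mcs, file.path(out_dir, "metaclusters.tsv"))
  write_metacluster_table(filtered,
                          file.path(out_dir, "metaclusters_filtered.tsv"))
  write_seed_table(mcs, file.path(out_dir, "seeds.tsv"))
  logf("metaclusters_filtered=%d", length(filtered))

  seeds_dir <- file.path(out_dir, "seeds")
  dir.create(seeds_dir, showWarnings = FALSE)
  pruned_dir <- file.path(out_dir, "pruned_seeds")
  dir.create(pruned_dir, showWarnings = FALSE)
  stage("pruning", for (mc in mcs) {
    write_seed_fasta(mc, proteins,
                     file.path(seeds_dir, paste0(mc$id, ".fasta")))
    pruned <- greedy_identity_prune(seed_sequences(mc, proteins),
                                    threshold = config$prune_identity)
    write_fasta(pruned$representatives,
                file.path(pruned_dir, paste0(mc$id, ".fasta")))
  })

  comparisons <- NULL
  properties <- NULL
  if (!is.null(annotations)) {
    comparisons <- stage("comparison", compare_metaclusters(mcs, annotations))
    utils::write.table(comparisons,
                       file.path(out_dir, "comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(tracks)) {
    properties <- stage("labeling", do.call(rbind, lapply(
      mcs, composition_labels, tracks = tracks)))
    utils::write.table(properties,
                       file.path(out_dir, "properties.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  stage("xml", write_metacluster_xml(
    mcs, comparisons, properties,
    file.path(out_dir, "metaclusters.xml")))

  cov <- coverage_stats(mcs, proteins)
  logf("residue_coverage=%.2f sequence_coverage=%.2f",
       cov[["residue_coverage"]], cov[["sequence_coverage"]])
  tailfit <- tryCatch({
    sizes <- vapply(mcs, function(mc) nrow(mc$seeds), integer(1))
    fit <- size_ccdf_and_tail_fit(sizes)
    utils::write.table(fit$ccdf, file.path(out_dir, "size_ccdf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("tail_exponent=%.4f stderr=%.4f", fit$fit$exponent,
         fit$fit$stderr)
    fit
  }, error = function(e) {
    logf("tail_fit_skipped=%s", conditionMessage(e))
    NULL
  })
  manifest <- data.frame(file = list.files(out_dir, recursive = TRUE),
                         config_hash = cfg_hash)
  utils::write.table(manifest, file.path(out_dir, "MANIFEST.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(
    hits = hits, primary_clusters = pcs, metaclusters_pre = mcs_pre,
    merge_log = merged$decisions, metaclusters = mcs,
    filtered = filtered, comparisons = comparisons,
    properties = properties, coverage = cov, tail_fit = tailfit,
    config_hash = cfg_hash
  ))
}

#' Serialize primary-cluster members
#' @param pcs list of primary clusters.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_primary_members <- function(pcs, path) {
  rows <- lapply(seq_along(pcs), function(i) {
    m <- pcs[[i]]$members
    data.frame(cluster_index = i, query_id = pcs[[i]]$query_id,
               subject_id = m$subject_id, sstart = m$sstart,
               send = m$send, qstart = m$qstart, qend = m$qend,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(cluster_index = integer(), query_id = character(),
               subject_id = character(), sstart = integer(),
               send = integer(), qstart = integer(), qend = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rehydrate primary clusters from a member table
#' @param path TSV from [write_primary_members()].
#' @return list of primary clusters.
#' @export
read_primary_members <- function(path) {
  if (!file.exists(path)) stop("primary member table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(query_id = "character",
                                          subject_id = "character"))
  lapply(split(tab, tab$cluster_index), function(m) {
    new_primary_cluster(m$query_id[1], data.frame(
      subject_id = m$subject_id, sstart = m$sstart, send = m$send,
      qstart = m$qstart, qend = m$qend, stringsAsFactors = FALSE))
  })
}

#' Serialize metacluster seeds
#' @param mcs list of metaclusters.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_seed_table <- function(mcs, path) {
  rows <- lapply(mcs, function(mc) {
    if (nrow(mc$seeds) == 0L) return(NULL)
    data.frame(mc_id = mc$id, protein_id = mc$seeds$protein_id,
               start = mc$seeds$start, end = mc$seeds$end,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(mc_id = character(), protein_id = character(),
               start = integer(), end = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
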