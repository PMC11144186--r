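#' Read a protein FASTA file
#'
#' The identifier of each record is the header token before the first
#' whitespace; sequences are uppercased. The returned object is a named
#' character vector (a "protein set"), the in-memory sequence container
#' used throughout the package.
#'
#' @param path path to a FASTA file.
#' @return named character vector of amino-acid strings.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate protein id in FASTA: ", dup[1])
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence in FASTA: ", ids[which(nchar(seqs) == 0L)[1]])
  }
  names(seqs) <- ids
  seqs
}

#' Write a protein set to FASTA
#'
#' @param proteins named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  ss <- Biostrings::BStringSet(proteins)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read an all-versus-all local-alignment table
#'
#' Parses the standard 12-column tab-separated alignment dialect
#' (query id, subject id, percent identity, alignment length,
#' mismatches, gap opens, q.start, q.end, s.start, s.end, e-value, bit
#' score). Full self-hits (query equals subject over identical regions)
#' are excluded: a query trivially aligns to itself over its full
#' length, which would bias the density estimate of the clustering.
#'
#' @param path path to the tab-separated table (no header).
#' @param drop_self_hits drop rows where query and subject ids and both
#'   regions coincide (default `TRUE`).
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_alignment_table <- function(path, drop_self_hits = TRUE) {
  if (!file.exists(path)) stop("alignment table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop("malformed alignment row at line ", bad[1],
         ": expected 12 tab-separated columns, found ", nf[bad[1]])
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  num_bad <- which(!stats::complete.cases(
    hits[, c("pident", "qstart", "qend", "sstart", "send", "evalue")]))
  if (length(num_bad) > 0L) {
    stop("malformed alignment row at line ", num_bad[1],
         ": non-numeric field")
  }
  rev_q <- which(hits$qstart > hits$qend)
  if (length(rev_q) > 0L) {
    stop("malformed alignment row at line ", rev_q[1],
         ": q.start > q.end (protein alignments are forward-only)")
  }
  rev_s <- which(hits$sstart > hits$send)
  if (length(rev_s) > 0L) {
    stop("malformed alignment row at line ", rev_s[1],
         ": s.start > s.end (protein alignments are forward-only)")
  }
  if (drop_self_hits) {
    self <- hits$query_id == hits$subject_id &
      hits$qstart == hits$sstart & hits$qend == hits$send
    hits <- hits[!self, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

empty_hits <- function() {
  data.frame(
    query_id = character(), subject_id = character(),
    pident = numeric(), length = integer(), mismatch = integer(),
    gapopen = integer(), qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(), evalue = numeric(),
    bitscore = numeric(), stringsAsFactors = FALSE
  )
}

#' Write hits in the 12-column alignment dialect
#'
#' @param hits data.frame as returned by [read_alignment_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(hits, path) {
  utils::write.table(
    hits[, c("query_id", "subject_id", "pident", "length", "mismatch",
             "gapopen", "qstart", "qend", "sstart", "send", "evalue",
             "bitscore")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read reference domain annotations
#'
#' Tab-separated with header columns `protein_id`, `family_id`,
#' `clan_id`, `start`, `end`; `clan_id` may be `-` (no clan), in which
#' case the family acts as its own singleton pseudo-clan downstream.
#'
#' @param path TSV path.
#' @return annotation data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character",
                                          family_id = "character",
                                          clan_id = "character"))
  need <- c("protein_id", "family_id", "clan_id", "start", "end")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) stop("annotation file misses columns: ",
                              paste(miss, collapse = ", "))
  if (any(ann$start > ann$end)) stop("annotation with start > end")
  ann
}

#' Write reference domain annotations
#' @param ann annotation data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read per-residue property tracks
#'
#' Tab-separated with header `protein_id`, `feature`, `start`, `end`.
#' Features `low_complexity`, `coiled_coil` and `disordered` mark
#' residue intervals where the corresponding predictor fired; each
#' `transmembrane` row stands for one predicted transmembrane segment
#' (its interval may be a placeholder), so a protein's transmembrane
#' count is its number of `transmembrane` rows.
#'
#' @param path TSV path.
#' @param proteins named character vector of sequences (defines mask
#'   lengths; proteins absent from the file get all-false masks).
#' @return a "residue tracks" object: named list per protein with
#'   logical masks `low_complexity`, `coiled_coil`, `disordered` and
#'   integer `tm_count`.
#' @export
read_tracks <- function(path, proteins) {
  if (!file.exists(path)) stop("tracks file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(protein_id = "character",
                                          feature = "character"))
  need <- c("protein_id", "feature", "start", "end")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop("tracks file misses columns: ",
                              paste(miss, collapse = ", "))
  tracks_from_intervals(tab, proteins)
}

# Build mask-based tracks from an interval table (also used by synth).
tracks_from_intervals <- function(tab, proteins) {
  tracks <- lapply(nchar(proteins), function(L) {
    list(low_complexity = rep(FALSE, L), coiled_coil = rep(FALSE, L),
         disordered = rep(FALSE, L), tm_count = 0L)
  })
  names(tracks) <- names(proteins)
  mask_features <- c("low_complexity", "coiled_coil", "disordered")
  for (k in seq_len(nrow(tab))) {
    pid <- tab$protein_id[k]
    if (!pid %in% names(tracks)) next
    feat <- tab$feature[k]
    if (feat %in% mask_features) {
      L <- length(tracks[[pid]][[feat]])
      s <- max(1L, tab$start[k]); e <- min(L, tab$end[k])
      if (s <= e) tracks[[pid]][[feat]][s:e] <- TRUE
    } else if (feat == "transmembrane") {
      tracks[[pid]]$tm_count <- tracks[[pid]]$tm_count + 1L
    } else {
      stop("unknown track feature: ", feat)
    }
  }
  structure(tracks, class = "fam_tracks")
}

#' Write residue tracks to the interval TSV dialect
#' @param tracks a `fam_tracks` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- list()
  for (pid in names(tracks)) {
    tr <- tracks[[pid]]
    for (feat in c("low_complexity", "coiled_coil", "disordered")) {
      runs <- mask_runs(tr[[feat]])
      if (nrow(runs) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, feature = feat,
          start = runs$start, end = runs$end, stringsAsFactors = FALSE)
      }
    }
    if (tr$tm_count > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, feature = "transmembrane",
        start = rep(0L, tr$tm_count), end = rep(0L, tr$tm_count),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(protein_id = character(), feature = character(),
               start = integer(), end = integer())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# TRUE runs of a logical mask as start/end intervals
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
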