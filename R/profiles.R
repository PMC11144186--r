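#' Greedy identity pruning of seed sequences
#'
#' Desk-scale re-implementation of greedy incremental identity
#' clustering: sequences are visited in order of decreasing length and
#' each either joins the first existing representative with which it
#' shares at least `threshold` identity, or founds a new
#' representative. Identity is the best ungapped sliding-window match
#' count divided by the length of the shorter sequence (the
#' representative-picker convention of the tools this mimics). Word
#' heuristics of those tools are not reproduced; this is an exact
#' all-offsets comparison.
#'
#' @param seed_sequences named character vector of seed subsequences.
#' @param threshold identity threshold in `(0, 1]`, default 0.60.
#' @return list with `representatives` (named character vector, a
#'   subset of the input), `assignment` (representative name for every
#'   input sequence) and `identity_threshold`.
#' @export
greedy_identity_prune <- function(seed_sequences, threshold = 0.60) {
  if (length(seed_sequences) == 0L) stop("no seed sequences to prune")
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(names(seed_sequences))) {
    names(seed_sequences) <- sprintf("seed%04d", seq_along(seed_sequences))
  }
  ord <- order(-nchar(seed_sequences), names(seed_sequences))
  reps <- integer(0)
  assignment <- character(length(seed_sequences))
  names(assignment) <- names(seed_sequences)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      idy <- sliding_identity_cpp(seed_sequences[[r]], seed_sequences[[i]])
      if (idy >= threshold) {
        assignment[i] <- names(seed_sequences)[r]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assignment[i] <- names(seed_sequences)[i]
    }
  }
  list(representatives = seed_sequences[sort(reps)],
       assignment = assignment, identity_threshold = threshold)
}

#' External-tool backend descriptors
#'
#' A backend bundles the commands used to turn pruned seeds into family
#' artifacts: a multiple aligner and a profile-HMM builder/search pair.
#' `null_backend()` performs no alignment at all — it stacks the
#' sequences right-padded to equal length, which is only good for
#' format plumbing and is flagged as such in the result.
#'
#' @param align,hmmbuild,hmmsearch command names or paths.
#' @return backend object.
#' @export
external_backend <- function(align = "mafft", hmmbuild = "hmmbuild",
                             hmmsearch = "hmmsearch") {
  structure(list(align = align, hmmbuild = hmmbuild,
                 hmmsearch = hmmsearch), class = "fam_backend")
}

#' @rdname external_backend
#' @export
null_backend <- function() {
  structure(list(align = NULL, hmmbuild = NULL, hmmsearch = NULL),
            class = "fam_backend")
}

backend_available <- function(cmd) {
  !is.null(cmd) && nzchar(Sys.which(cmd))
}

#' Build MSA and profile-HMM files for a pruned seed set
#'
#' With a real backend, runs the configured aligner on the
#' representatives and builds a profile from the alignment. With the
#' null backend, writes a trivially stacked, right-padded pseudo-MSA
#' (`aligned = FALSE` in the return value) and no profile, so the
#' pipeline and its tests run with zero external installs.
#'
#' @param pruned result of [greedy_identity_prune()].
#' @param out_prefix path prefix; writes `<prefix>.msa.fasta` and,
#'   with a real backend, `<prefix>.hmm`.
#' @param backend a backend object.
#' @return list with `msa` path, `hmm` path or `NULL`, and `aligned`
#'   flag.
#' @export
build_family_artifacts <- function(pruned, out_prefix,
                                   backend = null_backend()) {
  reps <- pruned$representatives
  if (length(reps) == 0L) stop("empty pruned seed set")
  msa_path <- paste0(out_prefix, ".msa.fasta")
  if (is.null(backend$align)) {
    width <- max(nchar(reps))
    padded <- vapply(reps, function(s) {
      paste0(s, strrep("-", width - nchar(s)))
    }, character(1))
    write_fasta(padded, msa_path)
    return(list(msa = msa_path, hmm = NULL, aligned = FALSE))
  }
  if (!backend_available(backend$align)) {
    stop("backend unavailable: aligner '", backend$align, "' not found")
  }
  in_fa <- tempfile(fileext = ".fasta")
  errf <- tempfile(fileext = ".log")
  on.exit(unlink(c(in_fa, errf)), add = TRUE)
  write_fasta(reps, in_fa)
  system2(backend$align, c("--auto", in_fa), stdout = msa_path,
          stderr = errf)
  if (!file.exists(msa_path) || file.size(msa_path) == 0L) {
    stop("aligner failed: ",
         paste(readLines(errf, warn = FALSE), collapse = "\n"))
  }
  hmm_path <- paste0(out_prefix, ".hmm")
  if (!backend_available(backend$hmmbuild)) {
    stop("backend unavailable: '", backend$hmmbuild, "' not found")
  }
  out <- system2(backend$hmmbuild, c(hmm_path, msa_path),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(hmm_path)) {
    stop("hmmbuild failed: ", paste(out, collapse = "\n"))
  }
  list(msa = msa_path, hmm = hmm_path, aligned = TRUE)
}

#' Parse a profile-HMM domain-table file
#'
#' Reads the whitespace-separated per-domain table emitted by profile
#' search tools (`--domtblout` dialect): one row per domain hit with
#' the full-sequence and per-domain E-values and the alignment
#' coordinates on the target.
#'
#' @param path table path.
#' @return data.frame with `protein_id`, `protein_evalue`,
#'   `domain_evalue`, `ali_start`, `ali_end`.
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(data.frame(protein_id = character(),
                      protein_evalue = numeric(),
                      domain_evalue = numeric(), ali_start = integer(),
                      ali_end = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(keep, function(ln) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 21L) {
      stop("malformed domain-table row at line ", ln,
           ": expected >= 21 whitespace-separated fields, found ",
           length(f))
    }
    vals <- suppressWarnings(list(
      protein_evalue = as.numeric(f[7]),
      domain_evalue = as.numeric(f[13]),  # independent E-value column
      ali_start = as.integer(f[18]), ali_end = as.integer(f[19])))
    if (any(vapply(vals, is.na, logical(1)))) {
      stop("malformed domain-table row at line ", ln,
           ": non-numeric E-value or coordinate field")
    }
    data.frame(protein_id = f[1], protein_evalue = vals$protein_evalue,
               domain_evalue = vals$domain_evalue,
               ali_start = vals$ali_start, ali_end = vals$ali_end,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter domain-table hits by the release E-value thresholds
#'
#' Retains rows with domain E-value `<= domain_evalue` and
#' full-protein E-value `<= protein_evalue` (defaults 0.03 and 0.01,
#' the reporting thresholds of the published search step) and returns
#' them as member regions.
#'
#' @param dom data.frame from [parse_domtblout()].
#' @param domain_evalue,protein_evalue inclusive thresholds.
#' @return data.frame `protein_id`, `start`, `end`, `domain_evalue`,
#'   `protein_evalue`.
#' @export
filter_hmm_hits <- function(dom, domain_evalue = 0.03,
                            protein_evalue = 0.01) {
  keep <- dom$domain_evalue <= domain_evalue &
    dom$protein_evalue <= protein_evalue
  out <- dom[keep, , drop = FALSE]
  data.frame(protein_id = out$protein_id, start = out$ali_start,
             end = out$ali_end, domain_evalue = out$domain_evalue,
             protein_evalue = out$protein_evalue,
             stringsAsFactors = FALSE)
}

#' Search a profile-HMM against a protein FASTA
#'
#' Runs the configured search tool with a domain-table output and
#' applies [filter_hmm_hits()]. Members found this way extend a
#' metacluster but never mutate its seeds; seed and searched members
#' are kept distinct downstream.
#'
#' @param hmm path to a profile-HMM file.
#' @param fasta path to the protein FASTA to search.
#' @param backend backend object with a search command.
#' @param domain_evalue,protein_evalue inclusive E-value thresholds
#'   (defaults 0.03 / 0.01).
#' @return data.frame as [filter_hmm_hits()].
#' @export
hmmsearch_handoff <- function(hmm, fasta, backend = external_backend(),
                              domain_evalue = 0.03,
                              protein_evalue = 0.01) {
  if (!backend_available(backend$hmmsearch)) {
    stop("backend unavailable: '", backend$hmmsearch,
         "' not found; metacluster extension skipped")
  }
  tbl <- tempfile(fileext = ".domtblout")
  on.exit(unlink(tbl), add = TRUE)
  out <- system2(backend$hmmsearch,
                 c("--domtblout", tbl, "-E", format(protein_evalue),
                   "--domE", format(domain_evalue), hmm, fasta),
                 stdout = TRUE, stderr = TRUE)
  if (!file.exists(tbl)) {
    stop("hmmsearch failed: ", paste(out, collapse = "\n"))
  }
  filter_hmm_hits(parse_domtblout(tbl), domain_evalue, protein_evalue)
}
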