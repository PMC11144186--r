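AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
# Linkers draw from a skewed, polar/disorder-like composition over the
# full alphabet (P/G/S/T/N/Q/E/K three-fold enriched). The distribution
# must keep its support on all 20 letters: restricting linkers to the
# enriched subset alone makes any two linkers mutually similar under
# BLOSUM62 (expected pairwise score +0.23 per residue), and alignments
# then extend straight through linkers; the enriched-but-full
# composition has expected score -0.76, so linker-linker and
# linker-domain extensions die out.
LINKER_W <- stats::setNames(rep(1, 20), AA20)
LINKER_W[c("P", "G", "S", "T", "N", "Q", "E", "K")] <- 3

#' Describe a synthetic proteome with planted domain families
#'
#' The design is the fully stated world the generator realises: family
#' count and lengths, number of proteins, the per-protein domain
#' architecture, the substitution rate applied independently to every
#' residue of every domain copy, and the RNG seed. Defaults are the
#' desk-scale benchmark used throughout the package tests: 5 unrelated
#' families of 80--150 residues, 200 single-domain proteins (families
#' assigned round-robin), 10\% substitutions, seed 1.
#'
#' @param n_families number of ancestral families.
#' @param n_proteins number of proteins.
#' @param family_length_range inclusive residue-length range from which
#'   each family's ancestral length is drawn.
#' @param substitution_rate per-residue substitution probability for
#'   every domain copy, in `[0, 0.5]`.
#' @param seed integer RNG seed; all randomness flows through it.
#' @param architectures optional list (length `n_proteins`) of family-id
#'   vectors, e.g. `c("F1", "F2")` for a two-domain protein; default is
#'   single-domain round-robin.
#' @param linker_length_range inclusive length range of the random
#'   linkers placed before, between and after domains.
#' @param disordered_linker_rate probability that a linker is marked
#'   disordered in the emitted residue tracks.
#' @return a `planted_design` list.
#' @export
planted_design <- function(n_families = 5L, n_proteins = 200L,
                           family_length_range = c(80L, 150L),
                           substitution_rate = 0.10, seed = 1L,
                           architectures = NULL,
                           linker_length_range = c(15L, 35L),
                           disordered_linker_rate = 0.5) {
  if (substitution_rate < 0 || substitution_rate > 0.5) {
    stop("substitution_rate must be in [0, 0.5]")
  }
  if (min(family_length_range) < 30L) {
    stop("family lengths must be >= 30 residues")
  }
  if (n_families < 1L || n_proteins < 1L) stop("invalid design size")
  fam_ids <- sprintf("F%d", seq_len(n_families))
  if (is.null(architectures)) {
    architectures <- as.list(fam_ids[((seq_len(n_proteins) - 1L) %%
                                        n_families) + 1L])
  }
  if (length(architectures) != n_proteins) {
    stop("architectures must have one entry per protein")
  }
  bad <- setdiff(unlist(architectures), fam_ids)
  if (length(bad) > 0L) stop("unknown family in architecture plan: ", bad[1])
  structure(list(
    n_families = n_families, family_ids = fam_ids,
    n_proteins = n_proteins,
    family_length_range = as.integer(family_length_range),
    substitution_rate = substitution_rate, seed = as.integer(seed),
    architectures = architectures,
    linker_length_range = as.integer(linker_length_range),
    disordered_linker_rate = disordered_linker_rate
  ), class = "planted_design")
}

#' A mixed single/two-domain design
#'
#' Two families appearing alone and in combination, the standard test
#' bed for multi-domain segmentation: `n_single` proteins of `F1`,
#' `n_single` of `F2` and `n_double` with architecture `(F1, F2)`.
#'
#' @param n_single proteins per single-domain family.
#' @param n_double two-domain proteins.
#' @param ... forwarded to [planted_design()].
#' @return a `planted_design`.
#' @export
multidomain_design <- function(n_single = 40L, n_double = 40L, ...) {
  arch <- c(rep(list("F1"), n_single), rep(list("F2"), n_single),
            rep(list(c("F1", "F2")), n_double))
  planted_design(n_families = 2L, n_proteins = length(arch),
                 architectures = arch, ...)
}

#' Generate a synthetic proteome from a design
#'
#' Every family gets a random ancestral sequence; every protein
#' concatenates mutated family copies (i.i.d. substitutions at the
#' design rate) separated by random linkers of a distinct residue
#' composition. Ground-truth regions, reference annotations (families
#' `F1, F2, ...` mapped pairwise onto clans `CL1, CL2, ...`) and
#' simple residue tracks (linkers marked disordered at the design rate)
#' are emitted alongside. Byte-identical output for equal seeds.
#'
#' @param design a [planted_design()].
#' @return list with `proteins` (named character vector), `truth`
#'   (data.frame `protein_id`, `family_id`, `start`, `end`),
#'   `annotations` (same plus `clan_id`), `tracks` (a `fam_tracks`
#'   object) and the `design`.
#' @export
generate_proteome <- function(design) {
  if (!inherits(design, "planted_design")) stop("invalid design")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(design$seed)
  flr <- design$family_length_range
  fam_len <- sample(seq(flr[1], flr[2]), design$n_families, replace = TRUE)
  ancestors <- lapply(fam_len, function(L) {
    sample(AA20, L, replace = TRUE)
  })
  names(ancestors) <- design$family_ids
  llr <- design$linker_length_range
  proteins <- character(design$n_proteins)
  ids <- sprintf("SP%04d", seq_len(design$n_proteins))
  truth <- list()
  dis <- list()
  for (p in seq_len(design$n_proteins)) {
    arch <- design$architectures[[p]]
    nlink <- length(arch) + 1L
    link_len <- sample(seq(llr[1], llr[2]), nlink, replace = TRUE)
    pieces <- character(0)
    pos <- 0L
    dis_iv <- list()
    for (k in seq_along(arch)) {
      linker <- sample(AA20, link_len[k], replace = TRUE, prob = LINKER_W)
      if (stats::runif(1) < design$disordered_linker_rate &&
          link_len[k] > 0L) {
        dis_iv[[length(dis_iv) + 1L]] <-
          c(pos + 1L, pos + link_len[k])
      }
      pieces <- c(pieces, paste(linker, collapse = ""))
      pos <- pos + link_len[k]
      dom <- mutate_copy(ancestors[[arch[k]]], design$substitution_rate)
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = ids[p], family_id = arch[k],
        start = pos + 1L, end = pos + length(dom),
        stringsAsFactors = FALSE)
      pieces <- c(pieces, paste(dom, collapse = ""))
      pos <- pos + length(dom)
    }
    linker <- sample(AA20, link_len[nlink], replace = TRUE, prob = LINKER_W)
    if (stats::runif(1) < design$disordered_linker_rate &&
        link_len[nlink] > 0L) {
      dis_iv[[length(dis_iv) + 1L]] <- c(pos + 1L, pos + link_len[nlink])
    }
    pieces <- c(pieces, paste(linker, collapse = ""))
    proteins[p] <- paste(pieces, collapse = "")
    dis[[p]] <- dis_iv
  }
  names(proteins) <- ids
  truth <- do.call(rbind, truth)
  clan_of <- sprintf("CL%d", (seq_len(design$n_families) + 1L) %/% 2L)
  names(clan_of) <- design$family_ids
  annotations <- data.frame(
    protein_id = truth$protein_id, family_id = truth$family_id,
    clan_id = unname(clan_of[truth$family_id]),
    start = truth$start, end = truth$end, stringsAsFactors = FALSE)
  track_rows <- list()
  for (p in seq_len(design$n_proteins)) {
    for (iv in dis[[p]]) {
      track_rows[[length(track_rows) + 1L]] <- data.frame(
        protein_id = ids[p], feature = "disordered",
        start = iv[1], end = iv[2], stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(track_rows) > 0L) do.call(rbind, track_rows) else
    data.frame(protein_id = character(), feature = character(),
               start = integer(), end = integer())
  tracks <- tracks_from_intervals(tab, proteins)
  list(proteins = proteins, truth = truth, annotations = annotations,
       tracks = tracks, design = design)
}

mutate_copy <- function(ancestor, rate) {
  if (rate <= 0) return(ancestor)
  hit <- stats::runif(length(ancestor)) < rate
  if (any(hit)) {
    ancestor[hit] <- vapply(ancestor[hit], function(aa) {
      sample(setdiff(AA20, aa), 1L)
    }, character(1))
  }
  ancestor
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default alignment scoring
#'
#' BLOSUM62 with affine gaps (open 11, extend 1), mirroring standard
#' protein-search defaults.
#'
#' @param gap_open,gap_extend affine gap parameters; a gap of length k
#'   costs `gap_open + k * gap_extend`.
#' @return scoring list with `matrix`, `alphabet`, `gap_open`,
#'   `gap_extend`.
#' @export
default_scoring <- function(gap_open = 11L, gap_extend = 1L) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  storage.mode(m) <- "integer"
  list(matrix = m, alphabet = paste(rownames(m), collapse = ""),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment of two amino-acid strings under a
#' substitution matrix and affine gap penalties. Intended as the
#' desk-scale stand-in for an external all-versus-all search tool.
#'
#' @param a,b non-empty amino-acid strings.
#' @param scoring scoring list from [default_scoring()].
#' @return list with `score`, `a_region` and `b_region`
#'   (`c(start, end)`, `NULL` when the score is 0), `matches`,
#'   `aln_length`, `mismatches`, `gapopens`.
#' @export
smith_waterman <- function(a, b, scoring = default_scoring()) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  r <- sw_align_cpp(toupper(a), toupper(b), scoring$matrix,
                    scoring$alphabet, scoring$gap_open,
                    scoring$gap_extend)
  list(
    score = r$score,
    a_region = if (r$score > 0) c(start = r$a_start, end = r$a_end),
    b_region = if (r$score > 0) c(start = r$b_start, end = r$b_end),
    matches = r$matches, aln_length = r$aln_length,
    mismatches = r$mismatches, gapopens = r$gapopens
  )
}

# Karlin-Altschul-flavoured E-value surrogate; calibration is out of
# scope, the number is only carried through the hit table.
surrogate_evalue <- function(score, n, m, lambda = 0.267, K = 0.041) {
  K * n * m * exp(-lambda * score)
}

#' All-versus-all local alignment of a protein set
#'
#' Computes up to `max_hsps` high-scoring local alignments per ordered
#' protein pair (secondary alignments obtained by masking the residues
#' of previously reported ones and re-scanning) and reports them in the
#' 12-column alignment dialect consumed by [read_alignment_table()].
#' The alignment of a pair is computed once and emitted in both
#' directions.
#'
#' @param proteins named character vector, length >= 2.
#' @param scoring scoring list from [default_scoring()].
#' @param score_min minimum raw score for an alignment to be reported.
#' @param max_hsps maximum alignments per pair.
#' @return hit data.frame in the layout of [read_alignment_table()].
#' @export
all_vs_all <- function(proteins, scoring = default_scoring(),
                       score_min = 100L, max_hsps = 5L) {
  if (length(proteins) < 2L) stop("all_vs_all needs at least 2 proteins")
  ids <- names(proteins)
  acc <- list()
  for (i in seq_len(length(proteins) - 1L)) {
    for (j in seq((i + 1L), length(proteins))) {
      hsps <- sw_hsps_cpp(proteins[[i]], proteins[[j]], scoring$matrix,
                          scoring$alphabet, scoring$gap_open,
                          scoring$gap_extend, as.integer(score_min),
                          as.integer(max_hsps))
      for (r in hsps) {
        ev <- surrogate_evalue(r$score, nchar(proteins[[i]]),
                               nchar(proteins[[j]]))
        pid <- 100 * r$matches / max(1L, r$aln_length)
        bs <- r$score / 2
        acc[[length(acc) + 1L]] <- list(
          ids[i], ids[j], pid, r$aln_length, r$mismatches, r$gapopens,
          r$a_start, r$a_end, r$b_start, r$b_end, ev, bs)
        acc[[length(acc) + 1L]] <- list(
          ids[j], ids[i], pid, r$aln_length, r$mismatches, r$gapopens,
          r$b_start, r$b_end, r$a_start, r$a_end, ev, bs)
      }
    }
  }
  if (length(acc) == 0L) return(empty_hits())
  col <- function(k, cast) cast(vapply(acc, function(x) x[[k]], numeric(1)))
  chrcol <- function(k) vapply(acc, function(x) x[[k]], character(1))
  hits <- data.frame(
    query_id = chrcol(1), subject_id = chrcol(2),
    pident = col(3, as.numeric), length = col(4, as.integer),
    mismatch = col(5, as.integer), gapopen = col(6, as.integer),
    qstart = col(7, as.integer), qend = col(8, as.integer),
    sstart = col(9, as.integer), send = col(10, as.integer),
    evalue = col(11, as.numeric), bitscore = col(12, as.numeric),
    stringsAsFactors = FALSE
  )
  hits <- hits[order(hits$query_id, hits$subject_id, hits$qstart,
                     hits$qend), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Score recovery of planted families
#'
#' Maps every metacluster seed to the planted family whose ground-truth
#' region overlaps it by the most residues (`NOISE` when none overlaps)
#' and compares the metacluster partition of the seeds against the
#' planted one.
#'
#' @param metaclusters list of metaclusters.
#' @param truth ground-truth data.frame from [generate_proteome()].
#' @return list with `ari` (adjusted Rand index), `family_recall`
#'   (fraction of planted families that are the majority family of
#'   some metacluster) and the per-seed `labels` data.frame.
#' @export
planted_recovery_score <- function(metaclusters, truth) {
  rows <- list()
  for (mc in metaclusters) {
    s <- mc$seeds
    if (nrow(s) == 0L) next
    fam <- vapply(seq_len(nrow(s)), function(k) {
      tr <- truth[truth$protein_id == s$protein_id[k], , drop = FALSE]
      if (nrow(tr) == 0L) return("NOISE")
      ov <- intersect_len(s$start[k], s$end[k], tr$start, tr$end)
      if (max(ov) == 0L) "NOISE" else tr$family_id[which.max(ov)]
    }, character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      mc_id = mc$id, protein_id = s$protein_id, start = s$start,
      end = s$end, family_id = fam, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(list(ari = NA_real_, family_recall = 0,
                labels = data.frame()))
  }
  labels <- do.call(rbind, rows)
  ari <- adjusted_rand_index(labels$mc_id, labels$family_id)
  majority <- vapply(split(labels$family_id, labels$mc_id), function(f) {
    tt <- sort(table(f), decreasing = TRUE)
    names(tt)[1]
  }, character(1))
  fams <- unique(truth$family_id)
  recall <- mean(fams %in% majority)
  list(ari = ari, family_recall = recall, labels = labels)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement between two partitions of
#' the same items.
#'
#' @param x,y label vectors of equal length.
#' @return numeric scalar (1 for identical partitions, ~0 at chance).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Write ground truth to TSV
#' @param truth data.frame from [generate_proteome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
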