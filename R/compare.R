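#' Reference architecture of one seed region
#'
#' All reference domain annotations overlapping the seed by at least
#' one residue, ordered by ascending start coordinate on the protein
#' (annotating a single amino acid is enough to associate a seed with a
#' family). `NULL` when nothing overlaps.
#'
#' @param seed single-row region data.frame.
#' @param annotations annotation data.frame (see
#'   [read_annotations()]).
#' @param level `"family"` or `"clan"`; at clan level a family without
#'   a clan (`-` or `NA`) acts as its own singleton pseudo-clan.
#' @return character vector of ids, or `NULL`.
#' @export
seed_architecture <- function(seed, annotations, level = c("family", "clan")) {
  level <- match.arg(level)
  ann <- annotations[annotations$protein_id == seed$protein_id[1], ,
                     drop = FALSE]
  if (nrow(ann) == 0L) return(NULL)
  ov <- intersect_len(seed$start[1], seed$end[1], ann$start, ann$end)
  ann <- ann[ov >= 1L, , drop = FALSE]
  if (nrow(ann) == 0L) return(NULL)
  ann <- ann[order(ann$start, ann$end, ann$family_id), , drop = FALSE]
  if (level == "family") ann$family_id else clan_or_self(ann)
}

clan_or_self <- function(ann) {
  ifelse(is.na(ann$clan_id) | ann$clan_id %in% c("", "-"),
         ann$family_id, ann$clan_id)
}

arch_key <- function(arch) {
  if (is.null(arch) || length(arch) == 0L) NA_character_
  else paste(arch, collapse = ";")
}

# per-seed architecture keys for a whole metacluster
seed_arch_keys <- function(mc, annotations, level = "family") {
  s <- mc$seeds
  vapply(seq_len(nrow(s)), function(k) {
    arch_key(seed_architecture(s[k, , drop = FALSE], annotations, level))
  }, character(1))
}

#' Dominant architecture of a metacluster
#'
#' The reference architecture shared by the largest number of seeds;
#' the percentage is computed over all seeds (annotated or not). Ties
#' go to the lexicographically smaller architecture for determinism.
#' `UNK` with percent 0 when no seed is annotated.
#'
#' @param mc a metacluster with seeds.
#' @param annotations annotation data.frame.
#' @param level `"family"` or `"clan"`.
#' @return list with `architecture` (character vector or `"UNK"`) and
#'   `percent` in `[0, 100]`.
#' @export
dominant_architecture <- function(mc, annotations,
                                  level = c("family", "clan")) {
  level <- match.arg(level)
  stopifnot(nrow(mc$seeds) >= 1L)
  keys <- seed_arch_keys(mc, annotations, level)
  ann_keys <- keys[!is.na(keys)]
  if (length(ann_keys) == 0L) {
    return(list(architecture = "UNK", percent = 0))
  }
  counts <- table(ann_keys)
  winners <- names(counts)[counts == max(counts)]
  da <- sort(winners)[1]
  list(architecture = strsplit(da, ";", fixed = TRUE)[[1]],
       percent = 100 * max(counts) / length(keys))
}

is_contig_subseq <- function(sub, full) {
  ns <- length(sub); nf <- length(full)
  if (ns == 0L) return(TRUE)
  if (ns > nf) return(FALSE)
  for (off in 0:(nf - ns)) {
    if (all(sub == full[off + seq_len(ns)])) return(TRUE)
  }
  FALSE
}

#' Architecture-match percentages of a metacluster
#'
#' Four nested match notions against the dominant architecture `DA`
#' (family-id vector): exact family-level match (`Percent_DA`), exact
#' clan-level match (`Percent_DAC`), clan-level match or contiguous
#' sub-architecture — unannotated seeds count as the empty
#' sub-architecture (`Percent_DACF`) — and additionally contiguous
#' super-architectures (`Percent_DACFA`). The chain is monotone
#' non-decreasing by construction.
#'
#' @param mc metacluster.
#' @param DA family-id character vector (the dominant architecture).
#' @param annotations annotation data.frame.
#' @return named numeric vector of the four percentages.
#' @export
percent_variants <- function(mc, DA, annotations) {
  stopifnot(length(DA) >= 1L, !identical(DA, "UNK"))
  fam_keys <- seed_arch_keys(mc, annotations, "family")
  clan_keys <- seed_arch_keys(mc, annotations, "clan")
  clan_map <- family_clan_map(annotations)
  DA_clan <- unname(ifelse(DA %in% names(clan_map), clan_map[DA], DA))
  da_key <- arch_key(DA)
  dac_key <- arch_key(DA_clan)
  n <- length(fam_keys)
  p_da <- 100 * sum(fam_keys == da_key, na.rm = TRUE) / n
  match_dac <- !is.na(clan_keys) & clan_keys == dac_key
  p_dac <- 100 * sum(match_dac) / n
  clan_archs <- lapply(clan_keys, function(k) {
    if (is.na(k)) character(0) else strsplit(k, ";", fixed = TRUE)[[1]]
  })
  is_sub <- vapply(clan_archs, is_contig_subseq, logical(1),
                   full = DA_clan)
  p_dacf <- 100 * sum(match_dac | is_sub) / n
  is_super <- vapply(clan_archs, function(a) {
    is_contig_subseq(DA_clan, a)
  }, logical(1))
  p_dacfa <- 100 * sum(match_dac | is_sub | is_super) / n
  c(Percent_DA = p_da, Percent_DAC = p_dac, Percent_DACF = p_dacf,
    Percent_DACFA = p_dacfa)
}

family_clan_map <- function(annotations) {
  u <- unique(annotations[, c("family_id", "clan_id")])
  clans <- clan_or_self(u)
  stats::setNames(clans, u$family_id)
}

#' Mean boundary-overlap fractions of a metacluster
#'
#' For every seed matching the dominant architecture exactly (family
#' level), the reference span is the interval spanned by the
#' annotations composing the architecture on that protein. `Fred` is
#' the mean fraction of that span not covered by the seed (the family
#' under-covered by the metacluster); `Fext` the mean fraction of the
#' seed outside the span (the metacluster extending beyond the
#' family). Means are over all matching seed/reference pairs.
#'
#' @param mc metacluster.
#' @param DA family-id vector.
#' @param annotations annotation data.frame.
#' @return `c(Fred = , Fext = )`, both in `[0, 1]`.
#' @export
overlap_fractions <- function(mc, DA, annotations) {
  stopifnot(length(DA) >= 1L, !identical(DA, "UNK"))
  s <- mc$seeds
  fam_keys <- seed_arch_keys(mc, annotations, "family")
  idx <- which(!is.na(fam_keys) & fam_keys == arch_key(DA))
  if (length(idx) == 0L) {
    stop("no seed matches the dominant architecture")
  }
  fred <- numeric(length(idx))
  fext <- numeric(length(idx))
  for (k in seq_along(idx)) {
    seed <- s[idx[k], , drop = FALSE]
    ann <- annotations[annotations$protein_id == seed$protein_id, ,
                       drop = FALSE]
    ov <- intersect_len(seed$start, seed$end, ann$start, ann$end)
    ann <- ann[ov >= 1L, , drop = FALSE]
    span <- c(min(ann$start), max(ann$end))
    span_len <- span[2] - span[1] + 1L
    seed_len <- seed$end - seed$start + 1L
    inter <- intersect_len(seed$start, seed$end, span[1], span[2])
    fred[k] <- (span_len - inter) / span_len
    fext[k] <- (seed_len - inter) / seed_len
  }
  c(Fred = mean(fred), Fext = mean(fext))
}

#' Classify metacluster/reference overlap
#'
#' Four-way rule on the mean uncovered fractions: both within 0.2
#' (inclusive) is `equivalent`; both strictly above 0.2 is `shifted`;
#' only `Fred` above means the metacluster covers less than the family
#' (`reduced`); only `Fext` above means it extends beyond it
#' (`extended`).
#'
#' @param Fred,Fext fractions in `[0, 1]`.
#' @param threshold boundary, default 0.2.
#' @return one of `"equivalent"`, `"reduced"`, `"extended"`,
#'   `"shifted"`.
#' @export
classify_overlap <- function(Fred, Fext, threshold = 0.2) {
  if (is.na(Fred) || is.na(Fext) || Fred < 0 || Fred > 1 || Fext < 0 ||
      Fext > 1) {
    stop("Fred and Fext must be fractions in [0, 1]")
  }
  red <- Fred > threshold
  ext <- Fext > threshold
  if (red && ext) "shifted"
  else if (red) "reduced"
  else if (ext) "extended"
  else "equivalent"
}

#' Full reference comparison for a set of metaclusters
#'
#' One record per metacluster: dominant architectures at family and
#' clan level, the four match percentages, the overlap fractions and
#' the qualitative label. The label is only assigned when the dominant
#' architecture is shared by at least half of the seeds (`DA >= 50\%`);
#' otherwise it is `UNK`. `Pfam_sequences` counts the annotated seeds
#' used for the comparison.
#'
#' @param mcs list of metaclusters.
#' @param annotations annotation data.frame.
#' @return data.frame keyed by `mc_id`.
#' @export
compare_metaclusters <- function(mcs, annotations) {
  rows <- lapply(mcs, function(mc) {
    keys <- seed_arch_keys(mc, annotations, "family")
    n_ann <- sum(!is.na(keys))
    da <- dominant_architecture(mc, annotations, "family")
    dac <- dominant_architecture(mc, annotations, "clan")
    if (identical(da$architecture, "UNK")) {
      return(data.frame(
        mc_id = mc$id, DA = "UNK", DAC = "UNK", Percent_DA = NA_real_,
        Percent_DAC = NA_real_, Percent_DACF = NA_real_,
        Percent_DACFA = NA_real_, Label = "UNK", Fred = NA_real_,
        Fext = NA_real_, Pfam_sequences = n_ann,
        stringsAsFactors = FALSE))
    }
    pv <- percent_variants(mc, da$architecture, annotations)
    fr <- overlap_fractions(mc, da$architecture, annotations)
    label <- if (da$percent >= 50) {
      classify_overlap(fr[["Fred"]], fr[["Fext"]])
    } else "UNK"
    data.frame(
      mc_id = mc$id, DA = arch_key(da$architecture),
      DAC = arch_key(dac$architecture),
      Percent_DA = pv[["Percent_DA"]], Percent_DAC = pv[["Percent_DAC"]],
      Percent_DACF = pv[["Percent_DACF"]],
      Percent_DACFA = pv[["Percent_DACFA"]], Label = label,
      Fred = fr[["Fred"]], Fext = fr[["Fext"]], Pfam_sequences = n_ann,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composition-based property labels
#'
#' Pools the residues of all seed regions and computes the fraction
#' falling in low-complexity, coiled-coil and disordered tracks, plus
#' the mean transmembrane-segment count per seed. Labels follow the
#' published thresholds: strictly more than 10\% for `LowComplexity`
#' and `CoiledCoil`, strictly more than 50\% for `Disordered`, and a
#' mean of at least two segments (inclusive) for `Transmembrane`.
#' Proteins missing from the tracks are treated as all-false.
#'
#' @param mc metacluster.
#' @param tracks a `fam_tracks` object.
#' @return data.frame row with `mc_id`, the three fractions, `mean_tm`
#'   and a comma-separated `labels` string.
#' @export
composition_labels <- function(mc, tracks) {
  s <- mc$seeds
  tot <- 0L
  lc <- 0L; cc <- 0L; dis <- 0L
  tm <- numeric(nrow(s))
  for (k in seq_len(nrow(s))) {
    tr <- tracks[[s$protein_id[k]]]
    len <- s$end[k] - s$start[k] + 1L
    tot <- tot + len
    if (is.null(tr)) next
    L <- length(tr$low_complexity)
    lo <- min(s$start[k], L + 1L); hi <- min(s$end[k], L)
    if (lo <= hi) {
      idx <- lo:hi
      lc <- lc + sum(tr$low_complexity[idx])
      cc <- cc + sum(tr$coiled_coil[idx])
      dis <- dis + sum(tr$disordered[idx])
    }
    tm[k] <- tr$tm_count
  }
  frac_lc <- lc / tot; frac_cc <- cc / tot; frac_dis <- dis / tot
  mean_tm <- mean(tm)
  labels <- c(
    if (frac_lc > 0.10) "LowComplexity",
    if (frac_cc > 0.10) "CoiledCoil",
    if (frac_dis > 0.50) "Disordered",
    if (mean_tm >= 2) "Transmembrane"
  )
  data.frame(mc_id = mc$id, frac_low_complexity = frac_lc,
             frac_coiled_coil = frac_cc, frac_disordered = frac_dis,
             mean_tm = mean_tm,
             labels = paste(labels, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Residue and sequence coverage of a protein set
#'
#' Fraction of all residues covered by at least one member region
#' (overlaps counted once) and fraction of proteins carrying at least
#' one member, both as percentages.
#'
#' @param members either a list of metaclusters or a region data.frame.
#' @param proteins named character vector of sequences.
#' @return `c(residue_coverage = , sequence_coverage = )` in percent.
#' @export
coverage_stats <- function(members, proteins) {
  if (is.list(members) && !is.data.frame(members)) {
    regs <- do.call(rbind, lapply(members, function(mc) {
      as.data.frame(mc$seeds)[, c("protein_id", "start", "end")]
    }))
  } else {
    regs <- as.data.frame(members)[, c("protein_id", "start", "end")]
  }
  total_res <- sum(nchar(proteins))
  if (is.null(regs) || nrow(regs) == 0L) {
    return(c(residue_coverage = 0, sequence_coverage = 0))
  }
  covered <- 0L
  by_prot <- split(regs, regs$protein_id)
  for (pid in names(by_prot)) {
    if (!pid %in% names(proteins)) next
    L <- nchar(proteins[[pid]])
    r <- by_prot[[pid]]
    # union of clamped intervals by sweep
    s <- pmax(1L, r$start); e <- pmin(L, r$end)
    ok <- s <= e
    if (!any(ok)) next
    iv <- cbind(s[ok], e[ok])
    iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
    cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
    for (k in seq_len(nrow(iv))[-1]) {
      if (iv[k, 1] <= cur_e + 1L) {
        cur_e <- max(cur_e, iv[k, 2])
      } else {
        covered <- covered + (cur_e - cur_s + 1L)
        cur_s <- iv[k, 1]; cur_e <- iv[k, 2]
      }
    }
    covered <- covered + (cur_e - cur_s + 1L)
  }
  with_member <- sum(names(proteins) %in% regs$protein_id)
  c(residue_coverage = 100 * covered / total_res,
    sequence_coverage = 100 * with_member / length(proteins))
}

#' Empirical CCDF and Pareto tail fit of family sizes
#'
#' Computes the complementary cumulative distribution function
#' `P(X >= x)` of the size distribution and fits the tail above
#' `threshold` with a Pareto law by maximum likelihood (the Hill
#' estimator, i.e. the generalized-Pareto shape reparameterised to the
#' CCDF exponent `alpha`, `P(X >= x) ~ (x / threshold)^(-alpha)`).
#' The standard error is the asymptotic `alpha / sqrt(n)`.
#'
#' @param sizes positive numeric vector of family sizes.
#' @param threshold minimum size entering the fit; default the smallest
#'   observed size.
#' @param min_tail minimum number of tail observations required.
#' @return list with `ccdf` (data.frame `size`, `ccdf`) and `fit`
#'   (list `exponent`, `scale`, `threshold`, `stderr`, `n_tail`).
#' @export
size_ccdf_and_tail_fit <- function(sizes, threshold = NULL,
                                   min_tail = 30L) {
  stopifnot(length(sizes) > 0L, all(sizes > 0))
  if (length(unique(sizes)) == 1L) {
    stop("degenerate size distribution: all sizes equal")
  }
  if (is.null(threshold)) threshold <- min(sizes)
  xs <- sort(unique(sizes))
  ccdf <- vapply(xs, function(x) mean(sizes >= x), numeric(1))
  tail_sizes <- sizes[sizes >= threshold]
  n <- length(tail_sizes)
  if (n < min_tail) {
    stop("too few sizes above the fit threshold (", n, " < ", min_tail,
         ")")
  }
  alpha <- n / sum(log(tail_sizes / threshold))
  list(
    ccdf = data.frame(size = xs, ccdf = ccdf),
    fit = list(exponent = alpha, scale = threshold,
               threshold = threshold, stderr = alpha / sqrt(n),
               n_tail = n)
  )
}
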