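#' Construct a table of protein regions
#'
#' A region is a 1-based, inclusive residue interval on a named protein
#' sequence. Regions are the atoms of clustering: alignment footprints,
#' metacluster seeds and reference domain annotations are all regions.
#'
#' @param protein_id character vector of protein identifiers.
#' @param start,end integer vectors of 1-based inclusive residue
#'   coordinates, recycled against `protein_id`.
#' @return A `data.frame` with columns `protein_id`, `start`, `end` and
#'   class `fam_regions`.
#' @examples
#' regions("P1", 1, 100)
#' @export
regions <- function(protein_id, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("region coordinates must be integer and non-missing")
  }
  if (any(start < 1L)) stop("region start must be >= 1 (1-based coordinates)")
  if (any(end < start)) stop("region end must be >= start (inclusive intervals)")
  df <- data.frame(
    protein_id = as.character(protein_id),
    start = start,
    end = end,
    stringsAsFactors = FALSE
  )
  class(df) <- c("fam_regions", "data.frame")
  df
}

#' Region lengths in residues
#'
#' @param r a `fam_regions` table (or any data.frame with `start`/`end`).
#' @return integer vector, `end - start + 1`.
#' @export
region_length <- function(r) {
  r$end - r$start + 1L
}

#' Intersection and union sizes of two residue intervals
#'
#' Both counts are in residues under the 1-based inclusive convention.
#' The union of disjoint intervals counts only residues actually covered
#' (no gap residues), so `union == len(a) + len(b) - intersection` always
#' holds and both quantities are amino-acid counts.
#'
#' @param a,b single-row region tables (or lists with `protein_id`,
#'   `start`, `end`) on the same protein.
#' @return `c(intersection = , union = )`, both integers.
#' @examples
#' interval_intersection_union(regions("P", 1, 100), regions("P", 51, 150))
#' @export
interval_intersection_union <- function(a, b) {
  if (a$protein_id[1] != b$protein_id[1]) {
    stop("regions lie on different proteins: ",
         a$protein_id[1], " vs ", b$protein_id[1])
  }
  inter <- intersect_len(a$start[1], a$end[1], b$start[1], b$end[1])
  la <- a$end[1] - a$start[1] + 1L
  lb <- b$end[1] - b$start[1] + 1L
  c(intersection = inter, union = la + lb - inter)
}

# vectorised intersection length of [s1,e1] and [s2,e2]; 0 when disjoint
intersect_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# vectorised Jaccard overlap of intervals on the same protein
interval_jaccard <- function(s1, e1, s2, e2) {
  i <- intersect_len(s1, e1, s2, e2)
  u <- (e1 - s1 + 1L) + (e2 - s2 + 1L) - i
  i / u
}

#' Query-footprint overlap distance
#'
#' The clustering distance between two aligned regions of the same query
#' sequence: one minus the Jaccard overlap of their query footprints,
#' with both intersection and union expressed in amino acids. Identical
#' footprints are at distance 0, disjoint footprints at distance 1. The
#' distance is a semimetric (symmetric, zero iff equal); the triangle
#' inequality is not guaranteed and is never relied upon.
#'
#' @param qi,qj single-row region tables on the same query protein.
#' @return numeric scalar in `[0, 1]`.
#' @examples
#' query_overlap_distance(regions("Q", 1, 100), regions("Q", 51, 150))
#' @export
query_overlap_distance <- function(qi, qj) {
  iu <- interval_intersection_union(qi, qj)
  1 - iu[["intersection"]] / iu[["union"]]
}

# Full pairwise Eq.-style distance matrix for footprints on one query.
footprint_distance_matrix <- function(start, end) {
  n <- length(start)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  d <- 1 - interval_jaccard(start[i], end[i], start[j], end[j])
  matrix(d, n, n)
}
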