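#' Density Peak Clustering over a precomputed distance matrix
#'
#' The two-step density-peak procedure used by both clustering stages
#' of the pipeline: estimate a local density `rho` for every item, find
#' each item's distance `delta` to the nearest item of higher density,
#' declare items with simultaneously high `rho` and `delta` cluster
#' centers, and let every other item inherit the label of its nearest
#' higher-density neighbour in decreasing-density order.
#'
#' Determinism: ties in density are resolved by ascending item index
#' ("higher density" means larger `rho`, or equal `rho` with smaller
#' index), so the partition is a pure function of the matrix.
#'
#' @param d symmetric distance matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @param dc density cutoff; `NULL` picks the 2nd percentile of the
#'   off-diagonal distances clamped to `[0.2, 0.5]` (see
#'   [default_dc()] for why the floor sits at 0.2).
#' @param kernel `"cutoff"` (integer densities, default) or
#'   `"gaussian"`.
#' @param rho_min,delta_min center-selection thresholds; a center must
#'   satisfy both. If no item qualifies the global density maximum is
#'   forced as the single center.
#' @param halo if `TRUE`, items with `rho == 0` are relabelled `NA`
#'   (noise) after assignment.
#' @return list with `rho`, `delta`, `nearest_higher` (index or `NA`
#'   for the density maximum), `centers` (item indices), `assignment`
#'   (integer labels `1..k` in center order), and `dc`.
#' @export
dpc <- function(d, dc = NULL, kernel = c("cutoff", "gaussian"),
                rho_min = 1, delta_min = 0.5, halo = FALSE) {
  kernel <- match.arg(kernel)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n == 0L) stop("empty distance matrix")
  if (is.null(dc)) dc <- default_dc(d)
  rho <- compute_density(d, dc, kernel)
  dl <- compute_delta(d, rho)
  centers <- select_centers(rho, dl$delta, rho_min, delta_min)
  assignment <- assign_clusters(d, rho, dl$nearest_higher, centers)
  if (halo) assignment[rho == 0] <- NA_integer_
  list(rho = rho, delta = dl$delta, nearest_higher = dl$nearest_higher,
       centers = centers, assignment = assignment, dc = dc)
}

#' Default density cutoff for a distance matrix
#'
#' 2nd percentile of the off-diagonal distances, clamped to
#' `[0.2, 0.5]`. Both overlap distances used by the pipeline are
#' quantized (Jaccard of integer intervals; shared-member counts over
#' the smaller cluster size), so a cutoff below the quantization step
#' would zero out all densities; 0.2 sits above that step for any
#' cluster with at least five members while staying well below the
#' "unrelated" distance of 1.
#' @param d distance matrix.
#' @return numeric scalar.
#' @export
default_dc <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0.2)
  off <- d[upper.tri(d)]
  min(max(stats::quantile(off, 0.02, names = FALSE), 0.2), 0.5)
}

#' Per-item density
#'
#' Cutoff kernel: number of other items strictly closer than `dc`.
#' Gaussian kernel: `sum_j exp(-(d_ij/dc)^2)` over `j != i`.
#'
#' @param d distance matrix.
#' @param dc cutoff, in `(0, 1]`.
#' @param kernel `"cutoff"` or `"gaussian"`.
#' @return numeric vector of densities.
#' @export
compute_density <- function(d, dc, kernel = c("cutoff", "gaussian")) {
  kernel <- match.arg(kernel)
  n <- nrow(d)
  if (n == 0L) stop("empty distance matrix")
  if (!(dc > 0 && dc <= 1)) stop("dc must be in (0, 1]")
  if (kernel == "cutoff") {
    rho <- rowSums(d < dc) - 1  # subtract the zero diagonal
  } else {
    rho <- rowSums(exp(-(d / dc)^2)) - 1
  }
  as.numeric(rho)
}

#' Distance to the nearest higher-density item
#'
#' Item `j` counts as denser than `i` when `rho[j] > rho[i]`, or when
#' densities tie and `j < i` (index tie-break). The unique top item
#' under this order has no denser neighbour; its `delta` is its largest
#' row distance and its `nearest_higher` is `NA`.
#'
#' @param d distance matrix.
#' @param rho densities from [compute_density()].
#' @return list with numeric `delta` and integer `nearest_higher`.
#' @export
compute_delta <- function(d, rho) {
  n <- length(rho)
  delta <- numeric(n)
  nearest <- rep(NA_integer_, n)
  # total order: by decreasing rho, ties by ascending index
  ord <- order(-rho, seq_len(n))
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    if (pos == 1L) {
      delta[i] <- if (n > 1L) max(d[i, -i]) else 0
      next
    }
    higher <- ord[seq_len(pos - 1L)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    nearest[i] <- j
  }
  list(delta = delta, nearest_higher = nearest)
}

#' Select cluster centers on the decision graph
#'
#' Centers are items with `rho >= rho_min` and `delta >= delta_min`.
#' If no item passes both thresholds the global density maximum
#' (smallest index on ties) is forced, so there is always at least one
#' center.
#'
#' @param rho,delta vectors from the previous steps.
#' @param rho_min,delta_min thresholds.
#' @return integer vector of center indices, ascending.
#' @export
select_centers <- function(rho, delta, rho_min = 1, delta_min = 0.5) {
  centers <- which(rho >= rho_min & delta >= delta_min)
  if (length(centers) == 0L) {
    centers <- which(rho == max(rho))[1]
  }
  sort(centers)
}

#' Assign every item to a center
#'
#' Centers label their own clusters (numbered `1..k` in ascending
#' center-index order); every other item, visited in decreasing-density
#' order, inherits the label of its nearest higher-density neighbour.
#'
#' @param d distance matrix (only used for its dimension).
#' @param rho densities.
#' @param nearest_higher from [compute_delta()].
#' @param centers integer center indices, non-empty.
#' @return integer label vector.
#' @export
assign_clusters <- function(d, rho, nearest_higher, centers) {
  n <- length(rho)
  if (length(centers) == 0L) stop("no centers")
  labels <- rep(NA_integer_, n)
  labels[centers] <- seq_along(centers)
  ord <- order(-rho, seq_len(n))
  for (i in ord) {
    if (!is.na(labels[i])) next
    labels[i] <- labels[nearest_higher[i]]
  }
  labels
}

#' Dump the (rho, delta) decision graph as TSV
#' @param fit result of [dpc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decision_graph <- function(fit, path) {
  utils::write.table(
    data.frame(item = seq_along(fit$rho), rho = fit$rho,
               delta = fit$delta, center = seq_along(fit$rho) %in% fit$centers,
               cluster = fit$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
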