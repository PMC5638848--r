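# Greedy abundance-sorted centroid clustering of MCRA peptides at 97%
# identity, the 0.1% cluster floor, and the sample x cluster count
# matrix.

#' Pairwise peptide identity under global alignment
#'
#' Global alignment with match +1, mismatch 0 and affine gaps (open 10,
#' extend 1 on the same unit scale); identity is matches divided by
#' alignment columns, excluding terminal-gap columns (so a sequence is
#' 100% identical to its own prefix). Symmetric.
#'
#' @param a,b non-empty peptide sequences.
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  if (a == b) return(1)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  S <- 1 * outer(ca, cb, "==")
  al <- .gotoh_align(S, 10, 1)
  ncol_all <- length(al$ai)
  gap <- al$ai == 0 | al$bi == 0
  # terminal gap runs
  lead <- if (gap[1]) which.min(gap) - 1L else 0L
  trail <- if (gap[ncol_all]) ncol_all - which.min(rev(gap)) + 1L
  else ncol_all + 1L
  keep <- setdiff(seq_len(ncol_all), c(seq_len(lead),
                                       seq.int(trail, ncol_all + 1L)))
  keep <- keep[keep <= ncol_all]
  if (!length(keep)) return(0)
  matches <- sum(al$ai[keep] > 0 & al$bi[keep] > 0 &
                   ca[pmax(al$ai[keep], 1)] == cb[pmax(al$bi[keep], 1)])
  matches / length(keep)
}

#' Greedy centroid clustering of peptides
#'
#' Peptides are processed in decreasing total abundance (ties broken by
#' lexicographic sequence order) and assigned to the first existing
#' centroid with identity at or above the threshold; otherwise they found
#' a new cluster with themselves as centroid. Deterministic.
#'
#' @param peptides unique peptide sequences.
#' @param abundances total counts per peptide.
#' @param threshold identity threshold (default 0.97).
#' @return data frame with columns peptide, abundance, cluster (centroid
#'   index in processing order) and an attribute `centroids` (character
#'   vector of centroid peptides).
#' @export
greedy_cluster <- function(peptides, abundances, threshold = 0.97) {
  stopifnot(length(peptides) == length(abundances))
  ord <- order(-abundances, peptides)
  centroids <- character(0)
  assign <- integer(length(peptides))
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(centroids)) {
      if (pairwise_identity(peptides[i], centroids[ci]) >= threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, peptides[i])
      assign[i] <- length(centroids)
    }
  }
  out <- data.frame(peptide = peptides, abundance = abundances,
                    cluster = assign)
  attr(out, "centroids") <- centroids
  out
}

#' Apply the minimum-abundance cluster floor
#'
#' A cluster is retained iff it accounts for at least `min_fraction` of
#' the total peptide count (inclusive).
#'
#' @param totals named numeric vector of cluster totals.
#' @param min_fraction floor as a fraction of the grand total
#'   (default 0.001 = 0.1%).
#' @return list with `retained` (names), `discarded` (names) and
#'   `retained_fraction` (fraction of peptides kept).
#' @export
apply_min_fraction <- function(totals, min_fraction = 0.001) {
  grand <- sum(totals)
  if (grand == 0) stop("grand total of peptides is zero")
  keep <- totals / grand >= min_fraction
  list(retained = names(totals)[keep],
       discarded = names(totals)[!keep],
       retained_fraction = sum(totals[keep]) / grand)
}

#' Build the sample x cluster count matrix
#'
#' @param assignments data frame from [greedy_cluster()].
#' @param peptide_counts integer matrix, unique peptides x samples.
#' @param cluster_ids optional labels per cluster index; default
#'   `C1, C2, ...` in order of decreasing cluster total.
#' @return list with `counts` (samples x clusters integer matrix,
#'   columns ordered by decreasing total), `centroids` (named centroid
#'   peptides) and `relative` (percent relative abundances; rows sum to
#'   100, all-zero samples flagged by attribute `empty_samples`).
#' @export
build_count_matrix <- function(assignments, peptide_counts,
                               cluster_ids = NULL) {
  stopifnot(nrow(assignments) == nrow(peptide_counts))
  ncl <- max(assignments$cluster)
  agg <- matrix(0L, ncol(peptide_counts), ncl,
                dimnames = list(colnames(peptide_counts), NULL))
  for (i in seq_len(nrow(assignments)))
    agg[, assignments$cluster[i]] <- agg[, assignments$cluster[i]] +
      peptide_counts[i, ]
  totals <- colSums(agg)
  ord <- order(-totals)
  agg <- agg[, ord, drop = FALSE]
  cents <- attr(assignments, "centroids")[ord]
  if (is.null(cluster_ids)) cluster_ids <- paste0("C", seq_len(ncl))
  colnames(agg) <- cluster_ids
  names(cents) <- cluster_ids
  rel <- relative_abundance(agg)
  list(counts = agg, centroids = cents, relative = rel)
}

#' Percent relative abundance per sample
#'
#' @param counts samples x clusters matrix.
#' @return matrix of percentages; rows sum to 100. All-zero samples are
#'   left at zero and recorded in attribute `empty_samples`.
#' @export
relative_abundance <- function(counts) {
  rs <- rowSums(counts)
  empty <- rownames(counts)[rs == 0]
  rs[rs == 0] <- 1
  rel <- 100 * counts / rs
  attr(rel, "empty_samples") <- empty
  rel
}
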