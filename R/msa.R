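# Progressive multiple alignment of cluster centroids and reference
# peptides: pairwise Gotoh alignments under BLOSUM62 with affine gaps,
# guided by a UPGMA tree over k-mer distances, followed by site-coverage
# masking of gappy columns.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# 1 - Jaccard similarity of peptide 3-mer sets.
kmer_distance <- function(seqs, k = 3L) {
  sets <- lapply(seqs, kmer_set, k = k)
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    u <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- if (u == 0) 0 else
      1 - length(intersect(sets[[i]], sets[[j]])) / u
  }
  d
}

# Align two profiles (character matrices rows x columns). Column score =
# sum of BLOSUM62 over residue pairs / number of sequence pairs; gap
# residues contribute zero.
align_profiles <- function(A, B, gap_open = 10, gap_ext = 1) {
  bl <- blosum62()
  scorecol <- function(P) {
    # per column: residue counts over the alignment alphabet
    alpha <- rownames(bl)
    t(apply(P, 2, function(col) {
      col <- col[col != "-"]
      tabulate(match(col, alpha), nbins = length(alpha))
    }))
  }
  ca <- scorecol(A); cb <- scorecol(B)
  # S[i,j] = ca[i,] %*% bl %*% cb[j,] / (nA * nB)
  S <- (ca %*% bl %*% t(cb)) / (nrow(A) * nrow(B))
  al <- .gotoh_align(S, gap_open, gap_ext)
  ncols <- length(al$ai)
  out <- matrix("-", nrow(A) + nrow(B), ncols)
  ai <- al$ai; bi <- al$bi
  out[seq_len(nrow(A)), ai > 0] <- A[, ai[ai > 0], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), bi > 0] <- B[, bi[bi > 0], drop = FALSE]
  rownames(out) <- c(rownames(A), rownames(B))
  out
}

#' Progressive multiple alignment of peptides
#'
#' Pairwise Gotoh alignments (BLOSUM62, affine gap open 10 / extend 1)
#' merged progressively along a UPGMA guide tree built from 3-mer
#' Jaccard distances. Deterministic for a given input order.
#'
#' @param seqs named character vector of peptides (>= 3).
#' @return a `masked_alignment` object: list with `rows` (named aligned
#'   strings), `kept` (column indices, initially all) and `n_positions`.
#' @export
align_peptides <- function(seqs) {
  if (length(seqs) < 3) stop("need at least 3 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  d <- kmer_distance(seqs)
  hc <- hclust(as.dist(d), method = "average")
  profiles <- lapply(seq_along(seqs), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    get_prof <- function(idx) if (idx < 0) profiles[[-idx]]
    else merged[[idx]]
    merged[[k]] <- align_profiles(get_prof(hc$merge[k, 1]),
                                  get_prof(hc$merge[k, 2]))
  }
  final <- merged[[length(merged)]]
  final <- final[names(seqs), , drop = FALSE]
  rows <- apply(final, 1, paste, collapse = "")
  structure(list(rows = rows, kept = seq_len(ncol(final)),
                 n_positions = ncol(final)),
            class = "masked_alignment")
}

#' Align cluster centroids to a reference panel
#'
#' @param centroids named centroid peptides.
#' @param panel an `mcra_panel` supplying labelled reference peptides.
#' @return a `masked_alignment` over centroids and panel members.
#' @export
align_to_panel <- function(centroids, panel) {
  if (is.null(panel) || !length(panel$peptides))
    stop("reference panel is empty")
  align_peptides(c(centroids, panel$peptides))
}

#' Mask alignment columns by site coverage
#'
#' A column is kept iff its fraction of non-gap residues is at least
#' `site_coverage_min`.
#'
#' @param aln a `masked_alignment`.
#' @param site_coverage_min minimum non-gap fraction (default 0.85).
#' @return the alignment with `kept` and `n_positions` updated.
#' @export
mask_columns <- function(aln, site_coverage_min = 0.85) {
  m <- alignment_matrix(aln, masked = FALSE)
  cov <- colMeans(m != "-")
  keep <- which(cov >= site_coverage_min)
  if (!length(keep)) stop("no informative positions after masking")
  aln$kept <- keep
  aln$n_positions <- length(keep)
  aln
}

#' Alignment as a character matrix
#' @param aln a `masked_alignment`.
#' @param masked restrict to kept columns.
#' @return character matrix rows x columns.
#' @export
alignment_matrix <- function(aln, masked = TRUE) {
  m <- do.call(rbind, strsplit(aln$rows, ""))
  rownames(m) <- names(aln$rows)
  if (masked) m[, aln$kept, drop = FALSE] else m
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat("peptide alignment:", length(x$rows), "rows,",
      nchar(x$rows[[1]]), "columns,", x$n_positions, "kept positions\n")
  invisible(x)
}
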