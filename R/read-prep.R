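# Overlap merging of read pairs into full-length amplicons, followed by
# the amplicon size selection. The merge algorithm scans the 3' end of R1
# against the reverse complement of R2 and keeps the longest overlap
# whose mismatch rate is acceptable; at overlap mismatches the
# higher-quality base wins (R1 on quality ties).

#' Merge one read pair into an amplicon
#'
#' @param seq1,qual1 forward read and quality string.
#' @param seq2,qual2 reverse read and quality string.
#' @param min_overlap minimum acceptable overlap (nt).
#' @param max_mismatch_rate maximum fraction of mismatching positions in
#'   the overlap.
#' @return a list with `merged`, `qual`, `overlap`, `mismatches` on
#'   success, or `list(rejected = "no_overlap")`.
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, min_overlap = 20L,
                       max_mismatch_rate = 0.1) {
  if (!nchar(seq1) || !nchar(seq2)) stop("reads must be non-empty")
  rc2 <- revcomp(seq2)
  rq2 <- paste(rev(strsplit(qual2, "")[[1]]), collapse = "")
  l1 <- nchar(seq1); l2 <- nchar(rc2)
  c1 <- strsplit(seq1, "")[[1]]; c2 <- strsplit(rc2, "")[[1]]
  q1 <- utf8ToInt(qual1) - 33L; q2 <- utf8ToInt(rq2) - 33L
  for (o in seq.int(min(l1, l2), min_overlap)) {
    i1 <- (l1 - o + 1L):l1
    i2 <- 1L:o
    mism <- which(c1[i1] != c2[i2])
    if (length(mism) / o <= max_mismatch_rate) {
      cons <- c1[i1]
      consq <- pmax(q1[i1], q2[i2])
      if (length(mism)) {
        use2 <- q2[i2][mism] > q1[i1][mism]
        cons[mism[use2]] <- c2[i2][mism[use2]]
      }
      merged <- paste0(substr(seq1, 1L, l1 - o),
                       paste(cons, collapse = ""),
                       substr(rc2, o + 1L, l2))
      qual <- paste0(substr(qual1, 1L, l1 - o),
                     intToUtf8(consq + 33L),
                     substr(rq2, o + 1L, l2))
      return(list(merged = merged, qual = qual, overlap = o,
                  mismatches = length(mism)))
    }
  }
  list(rejected = "no_overlap")
}

# Merge a set of dereplicated pairs; returns merged table plus rejection
# counts by reason (weighted by pair multiplicity).
merge_pairs <- function(pairs, counts, min_overlap = 20L,
                        max_mismatch_rate = 0.1) {
  n <- nrow(pairs)
  merged <- character(n); qual <- character(n)
  overlap <- integer(n); mism <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    r <- merge_pair(pairs$seq1[i], pairs$qual1[i], pairs$seq2[i],
                    pairs$qual2[i], min_overlap, max_mismatch_rate)
    if (is.null(r$rejected)) {
      ok[i] <- TRUE
      merged[i] <- r$merged; qual[i] <- r$qual
      overlap[i] <- r$overlap; mism[i] <- r$mismatches
    }
  }
  list(merged = data.frame(seq = merged[ok], qual = qual[ok],
                           overlap = overlap[ok], mismatches = mism[ok]),
       merged_counts = counts[ok, , drop = FALSE],
       rejected = c(no_overlap = sum(counts[!ok, , drop = FALSE])))
}

#' Size-select amplicons around the expected fragment length
#'
#' @param lengths integer vector of amplicon lengths.
#' @param target_length expected amplicon size (default 472 nt).
#' @param tolerance allowed deviation (default 1 nt).
#' @return logical vector: TRUE for retained amplicons
#'   (`|length - target| <= tolerance`).
#' @export
length_filter <- function(lengths, target_length = 472L, tolerance = 1L) {
  abs(lengths - target_length) <= tolerance
}

#' Per-cycle quality summary
#'
#' Minimal replacement for an external read-quality report: per-cycle
#' minimum, mean and maximum Phred scores. Reporting only; no reads are
#' dropped on quality.
#'
#' @param quals character vector of quality strings (Phred+33).
#' @return data frame with cycle, min, mean, max.
#' @export
quality_summary <- function(quals) {
  if (!length(quals))
    return(data.frame(cycle = integer(0), min = numeric(0),
                      mean = numeric(0), max = numeric(0)))
  qs <- lapply(quals, function(q) utf8ToInt(q) - 33L)
  maxlen <- max(lengths(qs))
  m <- matrix(NA_real_, length(qs), maxlen)
  for (i in seq_along(qs)) m[i, seq_along(qs[[i]])] <- qs[[i]]
  data.frame(cycle = seq_len(maxlen),
             min = apply(m, 2, min, na.rm = TRUE),
             mean = colMeans(m, na.rm = TRUE),
             max = apply(m, 2, max, na.rm = TRUE))
}
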