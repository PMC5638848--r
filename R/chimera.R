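# Two-parent single-crossover chimera screen, applied both de novo
# (against more abundant co-occurring amplicons) and against a reference
# panel. A query is chimeric when the best two-parent crossover model
# explains it markedly better than the best single parent: b2 - b1 >=
# delta and b2 >= the minimum model identity.

kmer_set <- function(seq, k = 8L) {
  n <- nchar(seq) - k + 1L
  if (n < 1) return(character(0))
  unique(substring(seq, seq_len(n), seq_len(n) + k - 1L))
}

#' Rank candidate chimera parents for a query
#'
#' De novo mode considers only pool sequences whose abundance is at least
#' `abundance_skew` times the query abundance (a chimera cannot outnumber
#' its parents after PCR); reference mode considers the whole panel.
#' Candidates are ranked by shared 8-mer count with the query, ties
#' broken by abundance then id, and the top `k` kept.
#'
#' @param query query sequence.
#' @param query_abundance dereplicated count of the query.
#' @param pool data frame with columns id, seq, abundance.
#' @param mode "denovo" or "reference".
#' @param abundance_skew minimum parent/query abundance ratio (de novo).
#' @param k number of candidates retained.
#' @return data frame of candidates (possibly empty).
#' @export
candidate_parents <- function(query, query_abundance, pool,
                              mode = c("denovo", "reference"),
                              abundance_skew = 2.0, k = 4L) {
  mode <- match.arg(mode)
  if (!nrow(pool)) return(pool)
  elig <- if (mode == "denovo")
    pool[pool$abundance >= abundance_skew * query_abundance, ,
         drop = FALSE]
  else pool
  if (!nrow(elig)) return(elig)
  qk <- kmer_set(query)
  shared <- vapply(elig$seq, function(s)
    length(intersect(qk, kmer_set(s))), integer(1), USE.NAMES = FALSE)
  ord <- order(-shared, -elig$abundance, elig$id)
  elig[head(ord, k), , drop = FALSE]
}

# Query-anchored per-position match profile: for each query position,
# TRUE when the aligned parent residue matches. Parent gaps count as
# mismatches; query-gap columns are dropped.
match_profile <- function(query, parent) {
  qc <- strsplit(query, "")[[1]]
  pc <- strsplit(parent, "")[[1]]
  S <- 1 * outer(qc, pc, "==")
  al <- .gotoh_align(S, 10, 1)
  prof <- logical(nchar(query))
  qpos <- al$ai[al$ai > 0]
  ppos <- al$bi[al$ai > 0]
  hit <- ppos > 0
  prof[qpos[hit]] <- qc[qpos[hit]] == pc[ppos[hit]]
  prof
}

#' Score a query against a two-parent crossover model
#'
#' Aligns the query to each candidate parent, then for every crossover
#' position x computes the fraction of query positions explained by
#' parent A up to x and parent B beyond x (and the reverse orientation).
#' `b2` is the best crossover fraction, `b1` the best single-parent
#' identity.
#'
#' @param query query sequence.
#' @param parent_a,parent_b candidate parent sequences.
#' @param delta minimum improvement `b2 - b1` to call a chimera.
#' @param min_b2 minimum `b2` to call a chimera.
#' @return list with b1, b2, crossover, orientation and `is_chimera`.
#' @export
score_chimera <- function(query, parent_a, parent_b, delta = 0.02,
                          min_b2 = 0.99) {
  score_from_profiles(match_profile(query, parent_a),
                      match_profile(query, parent_b),
                      nchar(query), delta, min_b2)
}

score_from_profiles <- function(pa, pb, L, delta = 0.02, min_b2 = 0.99) {
  ca <- cumsum(pa); cb <- cumsum(pb)
  ta <- ca[L]; tb <- cb[L]
  # crossover after position x, x in 0..L
  fa <- c(0, ca) + tb - c(0, cb)   # A left, B right
  fb <- c(0, cb) + ta - c(0, ca)   # B left, A right
  b1 <- max(ta, tb) / L
  iab <- which.max(fa); iba <- which.max(fb)
  if (fa[iab] >= fb[iba]) {
    b2 <- fa[iab] / L; xover <- iab - 1L; orient <- "AB"
  } else {
    b2 <- fb[iba] / L; xover <- iba - 1L; orient <- "BA"
  }
  b2 <- max(b2, b1)  # the single-parent model is a degenerate crossover
  list(b1 = b1, b2 = b2, crossover = xover, orientation = orient,
       is_chimera = (b2 - b1 >= delta) && (b2 >= min_b2))
}

# Candidates per query segment: eligible pool sequences ranked by shared
# 8-mers with each quarter of the query separately, top k kept per
# segment (a chimera shares each flank with a different parent, and for
# any crossover position at least one quarter is pure parent sequence,
# so per-segment ranking keeps both true parents in play).
candidate_parents_sided <- function(query, query_abundance, pool, mode,
                                    abundance_skew = 2.0, k = 4L,
                                    n_segments = 4L) {
  elig <- if (mode == "denovo")
    pool[pool$abundance >= abundance_skew * query_abundance, ,
         drop = FALSE]
  else pool
  if (!nrow(elig)) return(elig)
  ekmers <- lapply(elig$seq, kmer_set)
  L <- nchar(query)
  cuts <- unique(round(seq(0, L, length.out = n_segments + 1L)))
  idx <- integer(0)
  for (s in seq_len(length(cuts) - 1L)) {
    part <- substr(query, cuts[s] + 1L, cuts[s + 1L])
    qk <- kmer_set(part)
    shared <- vapply(ekmers, function(ks)
      length(intersect(qk, ks)), integer(1))
    idx <- union(idx, head(order(-shared, -elig$abundance, elig$id), k))
  }
  elig[sort(idx), , drop = FALSE]
}

#' Flag and remove chimeric amplicons
#'
#' Dereplicated amplicons are screened de novo (parents drawn from more
#' abundant amplicons in the run) and against the reference panel; a
#' sequence flagged by either mode is removed. Queries are processed in
#' decreasing abundance and only sequences already accepted as
#' non-chimeric serve as de novo parents, so chimeras cannot shield one
#' another. The partition is exact and deterministic.
#'
#' @param seqs unique amplicon sequences.
#' @param abundances per-run dereplicated counts, same length.
#' @param panel optional `mcra_panel` (reference mode skipped if NULL).
#' @param config an `mcra_config`.
#' @return list with `clean` and `flagged` index vectors plus a
#'   `verdicts` data frame (query index, b1, b2, crossover, parents,
#'   mode, flag).
#' @export
filter_chimeras <- function(seqs, abundances, panel = NULL,
                            config = pipeline_config()) {
  n <- length(seqs)
  stopifnot(length(abundances) == n)
  flagged <- logical(n)
  verdicts <- list()
  refpool <- if (!is.null(panel))
    data.frame(id = panel$taxonomy$id,
               seq = unname(panel$nucleotides[panel$taxonomy$id]),
               abundance = 1) else NULL
  accepted <- integer(0)
  for (i in order(-abundances, seqs)) {
    pool <- data.frame(id = as.character(accepted),
                       seq = seqs[accepted],
                       abundance = abundances[accepted])
    best <- NULL
    for (mode in c("denovo", "reference")) {
      cand <- if (mode == "denovo")
        candidate_parents_sided(seqs[i], abundances[i], pool, "denovo",
                                config$chimera_skew, config$chimera_k)
      else if (!is.null(refpool))
        candidate_parents_sided(seqs[i], abundances[i], refpool,
                                "reference", config$chimera_skew,
                                config$chimera_k)
      else NULL
      if (is.null(cand) || nrow(cand) < 2) next
      profs <- lapply(cand$seq, function(s) match_profile(seqs[i], s))
      prs <- combn(nrow(cand), 2)
      for (pi in seq_len(ncol(prs))) {
        a <- prs[1, pi]; b <- prs[2, pi]
        v <- score_from_profiles(profs[[a]], profs[[b]], nchar(seqs[i]),
                                 config$chimera_delta,
                                 config$chimera_min_b2)
        if (is.null(best) || v$b2 - v$b1 > best$b2 - best$b1) {
          best <- v
          best$parent_a <- cand$id[a]; best$parent_b <- cand$id[b]
          best$mode <- mode
        }
        if (v$is_chimera) flagged[i] <- TRUE
      }
      if (flagged[i]) break
    }
    if (!flagged[i]) accepted <- c(accepted, i)
    if (!is.null(best))
      verdicts[[length(verdicts) + 1L]] <-
        data.frame(query = i, b1 = best$b1, b2 = best$b2,
                   crossover = best$crossover,
                   parent_a = best$parent_a, parent_b = best$parent_b,
                   mode = best$mode, is_chimera = flagged[i])
  }
  list(clean = which(!flagged), flagged = which(flagged),
       verdicts = if (length(verdicts)) do.call(rbind, verdicts)
       else data.frame())
}
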