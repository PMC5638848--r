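# Six-frame translation of merged amplicons and retention of the single
# stop-free reading frame anchored by the conserved primer translations.

#' Translate a nucleotide sequence in all six reading frames
#'
#' Frames +1..+3 read the sequence from positions 1..3; frames -1..-3
#' read the reverse complement likewise. Standard genetic code; stops are
#' rendered `*`; trailing partial codons are dropped.
#'
#' @param seq nucleotide sequence (A/C/G/T only).
#' @return named character vector of six peptides
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`).
#' @export
translate_six_frames <- function(seq) {
  if (nchar(seq) < 3) stop("sequence shorter than one codon")
  if (grepl("[^ACGT]", seq))
    stop("non-ACGT character in sequence")
  rc <- revcomp(seq)
  out <- c(
    `+1` = translate_nt(seq),
    `+2` = translate_nt(substr(seq, 2L, nchar(seq))),
    `+3` = translate_nt(substr(seq, 3L, nchar(seq))),
    `-1` = translate_nt(rc),
    `-2` = translate_nt(substr(rc, 2L, nchar(rc))),
    `-3` = translate_nt(substr(rc, 3L, nchar(rc))))
  out
}

# Count mismatches of peptide termini against per-position residue sets.
motif_mismatches <- function(residues, sets) {
  sum(!mapply(function(r, s) r %in% s, residues, sets))
}

#' Screen a merged amplicon for its primer-anchored open reading frame
#'
#' Accepts the amplicon iff exactly one of the six frames translates
#' without internal stop codons, begins with residues compatible with the
#' forward-primer motif, ends with residues compatible with the
#' reverse-primer motif (each within `max_motif_mismatches`), and has a
#' length inside the accepted peptide range. Ambiguity (several passing
#' frames) is treated as failure, since a genuine amplicon yields a
#' single conserved frame.
#'
#' @param seq merged amplicon nucleotide sequence.
#' @param primers a [primer_pair()].
#' @param length_range accepted peptide length range (aa), inclusive;
#'   applied to the full translation including primer-encoded residues.
#' @param trim_primers drop the primer-encoded residues from the
#'   returned peptide (default FALSE: downstream clustering sees the
#'   full translated amplicon).
#' @return list with `peptide` and `frame` on acceptance, or
#'   `list(rejected = reason)` with reason one of `no_frame`,
#'   `multiple_frames`, `stop_codon`, `length`, `motif`.
#' @export
screen_orf <- function(seq, primers, length_range = c(155L, 160L),
                       trim_primers = FALSE) {
  frames <- tryCatch(translate_six_frames(seq),
                     error = function(e) NULL)
  if (is.null(frames)) return(list(rejected = "no_frame"))
  mm <- primers$max_motif_mismatches
  nf <- primers$fwd_aa_len; nr <- primers$rev_aa_len
  status <- vapply(frames, function(p) {
    if (!nchar(p)) return("no_frame")
    if (grepl("*", substr(p, 1, nchar(p) - 1L), fixed = TRUE))
      return("stop_codon")
    if (substr(p, nchar(p), nchar(p)) == "*") return("stop_codon")
    if (nchar(p) < nf + nr) return("motif")
    head_res <- strsplit(substr(p, 1, nf), "")[[1]]
    tail_res <- strsplit(substr(p, nchar(p) - nr + 1L, nchar(p)), "")[[1]]
    if (motif_mismatches(head_res, primers$fwd_sets) > mm ||
        motif_mismatches(tail_res, primers$rev_sets) > mm)
      return("motif")
    if (nchar(p) < length_range[1] || nchar(p) > length_range[2])
      return("length")
    "ok"
  }, character(1))
  ok <- which(status == "ok")
  if (length(ok) == 1L) {
    pep <- frames[[ok]]
    if (trim_primers)
      pep <- substr(pep, nf + 1L, nchar(pep) - nr)
    return(list(peptide = pep, frame = names(frames)[ok]))
  }
  if (length(ok) > 1L) return(list(rejected = "multiple_frames"))
  if (any(status == "length")) return(list(rejected = "length"))
  if (any(status == "motif")) return(list(rejected = "motif"))
  if (any(status == "stop_codon")) return(list(rejected = "stop_codon"))
  list(rejected = "no_frame")
}

# Vectorised screen over a table of unique amplicons.
screen_orfs <- function(seqs, primers, length_range = c(155L, 160L)) {
  res <- lapply(seqs, screen_orf, primers = primers,
                length_range = length_range)
  data.frame(
    peptide = vapply(res, function(r) r$peptide %||% NA_character_,
                     character(1)),
    frame = vapply(res, function(r) r$frame %||% NA_character_,
                   character(1)),
    rejected = vapply(res, function(r) r$rejected %||% NA_character_,
                      character(1)))
}
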