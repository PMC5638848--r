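# Low-level sequence helpers shared across stages. Sequences are plain
# character vectors internally; Biostrings is used at the format boundary
# and for alphabet-aware operations.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of nucleotide sequences
#'
#' IUPAC-aware reverse complement for plain character vectors.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split sequences into character matrices / lists.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Translate concrete (non-degenerate) nucleotide sequence in frame 1;
# trailing partial codon dropped; stops rendered "*".
translate_nt <- function(x) {
  gc <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    aa <- unname(gc[codons])
    if (anyNA(aa)) stop("cannot translate codon with ambiguous bases: ",
                        codons[which(is.na(aa))[1]])
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All concrete expansions of one degenerate codon.
expand_codon <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  sets <- IUPAC_NT[b]
  if (any(vapply(sets, is.null, logical(1))))
    stop("invalid IUPAC base in '", codon, "'")
  apply(expand.grid(sets[[1]], sets[[2]], sets[[3]],
                    stringsAsFactors = FALSE), 1, paste, collapse = "")
}

# Residue set encoded by each degenerate codon of a primer-length pattern.
codon_residue_sets <- function(pattern) {
  if (nchar(pattern) %% 3L != 0L)
    stop("primer pattern length must be a multiple of 3")
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(pattern) %/% 3L
  codons <- substring(pattern, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  lapply(codons, function(cd) sort(unique(unname(gc[expand_codon(cd)]))))
}

# Hamming mismatch count between equal-length strings (vectorised over b).
hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  vapply(strsplit(b, ""), function(cb) sum(ca != cb), integer(1))
}

# Identity between equal-length ungapped sequences.
hamming_identity <- function(a, b) 1 - hamming(a, b) / nchar(a)

#' Derive a per-stage seed from one global seed
#'
#' Deterministic fan-out of a single run seed into independent per-stage
#' seeds, so that individual stages are reproducible in isolation. A
#' multiplicative hash of the stage name is mixed with the seed through a
#' few LCG steps and reduced below 2^31.
#'
#' @param seed integer global seed.
#' @param stage stage name.
#' @return an integer seed in `[1, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  x <- (seed %% 2147483647) + h
  for (i in 1:3) x <- (1103515245 * (x %% 65536) + 12345 + x %/% 65536) %%
      2147483647
  as.integer(x %% 2147483600 + 1)
}

# Draw n residues uniformly from the 20-letter alphabet.
random_residues <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
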