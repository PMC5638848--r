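# Readers and writers for the plain-text formats the pipeline touches:
# FASTA, paired FASTQ, TSV count matrices and the sample sheet. Parsers
# reject malformed input rather than silently truncating.

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences; names are record ids and
#'   must be unique.
#' @param path output path (".gz" suffix compresses transparently).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (length(x) && (is.null(names(x)) || anyDuplicated(names(x))))
    stop("FASTA ids must be present and unique")
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path input path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(out)))
    stop("duplicate FASTA ids in ", path)
  out
}

# Strict 4-line FASTQ records as a data frame (id, seq, qual).
parse_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L,
         " in ", path)
  n <- length(lines) %/% 4L
  if (n == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0)))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") |
                 nchar(sq) != nchar(ql))[1]
  if (!is.na(bad))
    stop("malformed FASTQ record ", bad, " in ", path)
  id <- sub("\\s.*$", "", sub("^@", "", hd))
  id <- sub("/[12]$", "", id)
  data.frame(id = id, seq = sq, qual = ql)
}

#' Read paired FASTQ files
#'
#' Ids are matched after stripping `/1` / `/2` suffixes and anything after
#' the first whitespace (Illumina dialect). Desynchronised or malformed
#' records raise an error naming the offending record index.
#'
#' @param r1,r2 paths to the forward and reverse FASTQ files
#'   (gzip-transparent).
#' @return a data frame with columns id, seq1, qual1, seq2, qual2.
#' @export
read_fastq_pairs <- function(r1, r2) {
  a <- parse_fastq(r1)
  b <- parse_fastq(r2)
  if (nrow(a) != nrow(b))
    stop("desynchronised pair files at record ",
         min(nrow(a), nrow(b)) + 1L, ": ", r1, " has ", nrow(a),
         " records, ", r2, " has ", nrow(b))
  mism <- which(a$id != b$id)[1]
  if (!is.na(mism))
    stop("read id mismatch at record ", mism, ": '", a$id[mism],
         "' vs '", b$id[mism], "'")
  data.frame(id = a$id, seq1 = a$seq, qual1 = a$qual,
             seq2 = b$seq, qual2 = b$qual)
}

#' Write paired FASTQ files
#'
#' @param pairs data frame as returned by [read_fastq_pairs()].
#' @param r1,r2 output paths (".gz" compresses).
#' @return c(r1, r2), invisibly.
#' @export
write_fastq_pairs <- function(pairs, r1, r2) {
  wr <- function(id, seq, qual, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(id))
      writeLines(paste0("@", id, "\n", seq, "\n+\n", qual), con)
    else writeLines(character(0), con)
  }
  wr(pairs$id, pairs$seq1, pairs$qual1, r1)
  wr(pairs$id, pairs$seq2, pairs$qual2, r2)
  invisible(c(r1, r2))
}

#' Write a sample x cluster count matrix as TSV
#'
#' @param m integer matrix, rows samples, columns clusters, with
#'   dimnames; counts must be nonnegative.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  if (any(m < 0)) stop("negative counts are not allowed")
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample x cluster count matrix from TSV
#'
#' @param path input path.
#' @return integer matrix with samples as rows; column order as written.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample") stop("count matrix must start with a 'sample' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(m < 0)) stop("negative counts in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  m
}

#' Read a sample sheet
#'
#' TSV with columns `sample`, `treatment`, `r1`, `r2`.
#'
#' @param path input path.
#' @param treatments declared treatment label set.
#' @return data frame with validated columns.
#' @export
read_sample_sheet <- function(path, treatments = c("R", "A", "RA", "AA")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "treatment", "r1", "r2")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample))
    stop("duplicate sample ids in sample sheet")
  bad <- setdiff(unique(df$treatment), treatments)
  if (length(bad))
    stop("undeclared treatment labels: ", paste(bad, collapse = ", "))
  df
}

#' Write a sample sheet
#' @param sheet data frame with columns sample, treatment, r1, r2.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
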