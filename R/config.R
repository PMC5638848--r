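#' Primer pair definition
#'
#' Defines the forward and reverse amplification primers as IUPAC
#' degenerate nucleotide patterns, together with the derived amino-acid
#' motif sets used by the open-reading-frame screen. The translated
#' amplicon is expected to begin with a residue string compatible with the
#' forward primer codons and end with one compatible with the reverse
#' complement of the reverse primer.
#'
#' The packaged defaults are synthetic placeholder patterns with the
#' length and degeneracy structure of the mcrA amplification primers used
#' in rumen methanogen surveys (Mlas-forward / mcrA-reverse style); the
#' true primer sequences are configuration and should be supplied by the
#' user for real libraries (user-verifiable).
#'
#' @param forward forward primer, IUPAC nucleotides, length a multiple
#'   of 3.
#' @param reverse reverse primer (as sequenced, i.e. reverse-complement
#'   strand), IUPAC nucleotides, length a multiple of 3.
#' @param max_motif_mismatches allowed residue mismatches against each
#'   primer motif during the ORF screen (default 0: the primer
#'   translations are treated as strictly conserved).
#' @return an object of class `primer_pair`.
#' @export
primer_pair <- function(forward = "GGNGGNGTNGGNTTYACNCARTAY",
                        reverse = "GCCCCACATRTTNGCNGCNGGRTA",
                        max_motif_mismatches = 0L) {
  stopifnot(nchar(forward) %% 3 == 0, nchar(reverse) %% 3 == 0,
            max_motif_mismatches >= 0)
  fwd_sets <- codon_residue_sets(forward)
  rev_sets <- codon_residue_sets(revcomp(reverse))
  if (any(vapply(fwd_sets, function(s) "*" %in% s && length(s) == 1,
                 logical(1))) ||
      any(vapply(rev_sets, function(s) "*" %in% s && length(s) == 1,
                 logical(1))))
    stop("primer codons translate only to stop")
  structure(list(forward = forward, reverse = reverse,
                 fwd_sets = fwd_sets, rev_sets = rev_sets,
                 fwd_aa_len = length(fwd_sets),
                 rev_aa_len = length(rev_sets),
                 max_motif_mismatches = as.integer(max_motif_mismatches)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("primer pair\n  forward:", x$forward, "\n  reverse:", x$reverse,
      "\n  motif lengths:", x$fwd_aa_len, "/", x$rev_aa_len,
      "aa, max mismatches", x$max_motif_mismatches, "\n")
  invisible(x)
}

config_defaults <- function() {
  list(
    amplicon_length       = 472L,
    amplicon_tolerance    = 1L,
    peptide_length_min    = 155L,
    peptide_length_max    = 160L,
    cluster_identity      = 0.97,
    cluster_min_fraction  = 0.001,
    bootstrap_reps        = 500L,
    collapse_support      = 0.30,
    site_coverage_min     = 0.85,
    random_addition_reps  = 10L,
    spr_level             = 1L,
    fdr_alpha             = 0.05,
    min_overlap           = 20L,
    max_mismatch_rate     = 0.1,
    chimera_skew          = 2.0,
    chimera_k             = 4L,
    chimera_delta         = 0.02,
    chimera_min_b2        = 0.99,
    bootstrap_addition_reps = 2L,
    nmds_restarts         = 50L,
    nmds_maxit            = 500L,
    nmds_tol              = 1e-6,
    seed                  = 1L
  )
}

#' Pipeline configuration
#'
#' Central run configuration with the pipeline's tunable parameters. All
#' defaults are the values the analysis is calibrated to: amplicons are
#' size-selected at 472 +/- 1 nt, accepted peptides are 155-160 aa,
#' peptides are clustered at 97% identity, clusters below 0.1% of total
#' peptides are discarded, tree search uses 10 random-addition replicates
#' with SPR level 1, 500 bootstrap replicates with branches below 30%
#' support collapsed, and alignment columns with less than 85% site
#' coverage are masked.
#'
#' @param ... named overrides of the defaults (see
#'   [config_fields()] for the full list).
#' @param primers a [primer_pair()].
#' @return an object of class `mcra_config`.
#' @export
pipeline_config <- function(..., primers = primer_pair()) {
  cfg <- config_defaults()
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg$primers <- primers
  validate_config(cfg)
  structure(cfg, class = "mcra_config")
}

#' Configuration field names
#' @return character vector of valid configuration keys.
#' @export
config_fields <- function() names(config_defaults())

validate_config <- function(cfg) {
  fr <- c("cluster_identity", "cluster_min_fraction", "collapse_support",
          "site_coverage_min", "fdr_alpha", "max_mismatch_rate",
          "chimera_delta", "chimera_min_b2")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]")
  pos <- c("amplicon_length", "peptide_length_min", "peptide_length_max",
           "bootstrap_reps", "random_addition_reps", "min_overlap",
           "chimera_k", "bootstrap_addition_reps", "nmds_restarts",
           "nmds_maxit")
  for (f in pos)
    if (cfg[[f]] < 1) stop(f, " must be positive")
  if (cfg$amplicon_tolerance < 0) stop("amplicon_tolerance must be >= 0")
  if (!inherits(cfg$primers, "primer_pair"))
    stop("primers must be a primer_pair object")
  invisible(cfg)
}

#' Read a flat key = value configuration file
#'
#' One `key = value` assignment per line; `#` starts a comment; unknown
#' keys are an error; omitted keys take the documented defaults. The keys
#' `primer_forward`, `primer_reverse` and `max_motif_mismatches` populate
#' the primer definition.
#'
#' @param path file path.
#' @return an `mcra_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3
  if (any(bad))
    stop("malformed configuration line: '", lines[which(bad)[1]], "'")
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  vals <- gsub('^"|"$', "", vals)
  names(vals) <- keys
  pr_keys <- c("primer_forward", "primer_reverse", "max_motif_mismatches")
  defaults <- config_defaults()
  unknown <- setdiff(keys, c(names(defaults), pr_keys))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  pargs <- list()
  if ("primer_forward" %in% keys) pargs$forward <- vals[["primer_forward"]]
  if ("primer_reverse" %in% keys) pargs$reverse <- vals[["primer_reverse"]]
  if ("max_motif_mismatches" %in% keys)
    pargs$max_motif_mismatches <-
      as.integer(vals[["max_motif_mismatches"]])
  overrides <- vals[intersect(keys, names(defaults))]
  typed <- lapply(names(overrides), function(k) {
    proto <- defaults[[k]]
    if (is.integer(proto)) as.integer(overrides[[k]])
    else as.numeric(overrides[[k]])
  })
  names(typed) <- names(overrides)
  do.call(pipeline_config,
          c(typed, list(primers = do.call(primer_pair, pargs))))
}

#' @export
print.mcra_config <- function(x, ...) {
  cat("mcrA pipeline configuration\n")
  for (f in config_fields())
    cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  print(x$primers)
  invisible(x)
}
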