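# Synthetic-community generator: labelled MCRA reference panels,
# community profiles, and paired-end amplicon reads with a complete
# per-read truth table, so every downstream stage is testable without
# external sequencing data.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify one methanogen clade for panel generation
#'
#' A clade is a star-shaped group of closely related MCRA peptide
#' sequences with shared family/genus/clade labels. `divergence_from_root`
#' controls how far the clade sits from the other clades: two clades with
#' settings d1 and d2 end up approximately `(d1 + d2) / 2` substitutions
#' per site apart (substituted sites are allocated disjointly across
#' clades, so divergences add along the two branches).
#' `within_member_divergence` is the substitutions per site separating
#' each member from its clade root; member substitutions are placed on
#' disjoint sites so members are roughly twice that far from each other.
#'
#' @param name clade identifier used in member ids.
#' @param family,genus,clade taxonomy labels (non-empty).
#' @param n_members number of member sequences (>= 1).
#' @param divergence_from_root substitutions per site in `[0, 1]`.
#' @param within_member_divergence substitutions per site in `[0, 1]`.
#' @param member_ids optional explicit member ids (length `n_members`).
#' @return an object of class `clade_spec`.
#' @export
clade_spec <- function(name, family, genus, clade, n_members = 1L,
                       divergence_from_root = 0.1,
                       within_member_divergence = 0,
                       member_ids = NULL) {
  stopifnot(nzchar(name), nzchar(family), nzchar(genus), nzchar(clade),
            n_members >= 1,
            divergence_from_root >= 0, divergence_from_root <= 1,
            within_member_divergence >= 0, within_member_divergence <= 1)
  if (is.null(member_ids))
    member_ids <- paste0(name, "_", seq_len(n_members))
  if (length(member_ids) != n_members)
    stop("member_ids must have length n_members")
  structure(list(name = name, family = family, genus = genus,
                 clade = clade, n_members = as.integer(n_members),
                 divergence_from_root = divergence_from_root,
                 within_member_divergence = within_member_divergence,
                 member_ids = member_ids),
            class = "clade_spec")
}

# One concrete expansion of a degenerate primer pattern.
concretize_pattern <- function(pattern) {
  b <- strsplit(pattern, "")[[1]]
  paste(vapply(IUPAC_NT[b], function(s) s[sample.int(length(s), 1)],
               character(1)), collapse = "")
}

mutate_at <- function(chars, sites) {
  for (s in sites) {
    cur <- chars[s]
    chars[s] <- sample(setdiff(AA_ALPHABET, cur), 1)
  }
  chars
}

#' Generate a labelled MCRA reference panel
#'
#' Builds peptide and nucleotide sequences for the members of the given
#' clades around a random ancestral peptide. All sequences share
#' primer-encoded N- and C-terminal residues (one concrete expansion of
#' the degenerate primers, drawn once per panel); substitutions are
#' applied only to the interior. The generated panel is checked against
#' its separation contracts: members of different clades are at most 96%
#' identical, members are at least 98% identical to their own clade root.
#' Settings that cannot satisfy these contracts raise a
#' "panel not separable" error.
#'
#' @param clade_specs list of [clade_spec()] objects.
#' @param peptide_length total peptide length in residues (155-160).
#' @param primers a [primer_pair()].
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return an object of class `mcra_panel` with elements `peptides`,
#'   `nucleotides` (named character vectors), `taxonomy` (data frame with
#'   id/family/genus/clade), `peptide_length` and the concretized primers.
#' @export
generate_reference_panel <- function(clade_specs, peptide_length = 157L,
                                     primers = primer_pair(),
                                     seed = 1L) {
  if (!length(clade_specs)) stop("need at least one clade spec")
  if (peptide_length < 155 || peptide_length > 160)
    stop("peptide_length must lie in [155, 160]")
  with_seed(seed, {
    fwd <- concretize_pattern(primers$forward)
    rev <- concretize_pattern(primers$reverse)
    nterm <- translate_nt(fwd)
    cterm <- translate_nt(revcomp(rev))
    if (grepl("*", paste0(nterm, cterm), fixed = TRUE))
      stop("primer translation contains a stop codon")
    ilen <- peptide_length - nchar(nterm) - nchar(cterm)
    if (ilen < 10) stop("peptide too short for the primer motifs")
    root <- strsplit(random_residues(ilen), "")[[1]]

    nsub <- vapply(clade_specs, function(cs)
      as.integer(round(cs$divergence_from_root * peptide_length / 2)),
      integer(1))
    if (sum(nsub) > ilen)
      stop("panel not separable: clade divergences need ", sum(nsub),
           " interior sites but only ", ilen, " exist")
    pool <- sample.int(ilen)
    offs <- cumsum(c(0L, nsub))
    ids <- character(0); peps <- character(0)
    tax <- list()
    for (ci in seq_along(clade_specs)) {
      cs <- clade_specs[[ci]]
      csites <- if (nsub[ci] > 0)
        pool[(offs[ci] + 1L):(offs[ci] + nsub[ci])] else integer(0)
      croot <- mutate_at(root, csites)
      croot_pep <- paste0(nterm, paste(croot, collapse = ""), cterm)
      msub <- as.integer(round(cs$within_member_divergence *
                                 peptide_length))
      mpool <- sample(setdiff(seq_len(ilen), csites))
      if (msub * cs$n_members > length(mpool))
        stop("panel not separable: member divergence needs ",
             msub * cs$n_members, " disjoint interior sites in clade '",
             cs$name, "'")
      for (mi in seq_len(cs$n_members)) {
        msites <- if (msub > 0)
          mpool[((mi - 1L) * msub + 1L):(mi * msub)] else integer(0)
        mem <- mutate_at(croot, msites)
        pep <- paste0(nterm, paste(mem, collapse = ""), cterm)
        if (hamming_identity(pep, croot_pep) < 0.98)
          stop("panel not separable: member '", cs$member_ids[mi],
               "' falls below 98% identity to its clade root")
        ids <- c(ids, cs$member_ids[mi])
        peps <- c(peps, pep)
        tax[[length(tax) + 1L]] <-
          data.frame(id = cs$member_ids[mi], family = cs$family,
                     genus = cs$genus, clade = cs$clade,
                     clade_name = cs$name)
      }
    }
    if (anyDuplicated(ids)) stop("duplicate member ids across clades")
    names(peps) <- ids
    taxonomy <- do.call(rbind, tax)
    nt <- vapply(peps, function(p) {
      interior <- substr(p, nchar(nterm) + 1L,
                         nchar(p) - nchar(cterm))
      paste0(fwd, back_translate_impl(interior), revcomp(rev))
    }, character(1))
    panel <- structure(list(peptides = peps, nucleotides = nt,
                            taxonomy = taxonomy,
                            peptide_length = as.integer(peptide_length),
                            forward_primer = fwd, reverse_primer = rev,
                            seed = seed),
                       class = "mcra_panel")
    audit_panel_separation(panel)
    panel
  })
}

# Contract audit: cross-clade members <= 0.96 identity, members >= 0.98
# to their clade consensus (approximated by the most central member).
audit_panel_separation <- function(panel) {
  tax <- panel$taxonomy
  peps <- panel$peptides
  cls <- unique(tax$clade_name)
  if (length(cls) > 1) {
    for (i in seq_along(cls)[-1]) for (j in seq_len(i - 1)) {
      a <- peps[tax$id[tax$clade_name == cls[i]]]
      b <- peps[tax$id[tax$clade_name == cls[j]]]
      for (s in a) {
        ident <- hamming_identity(s, b)
        if (any(ident > 0.96))
          stop("panel not separable: members of clades '", cls[i],
               "' and '", cls[j], "' reach identity ",
               format(max(ident), digits = 4))
      }
    }
  }
  invisible(panel)
}

back_codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

back_translate_impl <- function(peptide) {
  tbl <- back_codon_table()
  chars <- strsplit(peptide, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad))
    stop("residue outside the standard alphabet: ", bad[1])
  paste(vapply(tbl[chars], function(cods)
    cods[sample.int(length(cods), 1)], character(1)), collapse = "")
}

#' Back-translate a peptide into a nucleotide sequence
#'
#' Each residue is encoded by a codon drawn uniformly among its synonymous
#' codons under the standard genetic code, so the frame-1 translation of
#' the result reproduces the input exactly.
#'
#' @param peptide amino-acid sequence using the 20 standard residues.
#' @param seed integer seed.
#' @return nucleotide sequence of length `3 * nchar(peptide)`.
#' @export
back_translate <- function(peptide, seed = 1L) {
  with_seed(seed, back_translate_impl(peptide))
}

#' Community profile
#'
#' @param proportions named nonnegative numeric vector; sums to 1 (or to
#'   100 when expressed in percent, in which case it is renormalised).
#' @param treatment treatment label.
#' @return an object of class `community_profile`.
#' @export
community_profile <- function(proportions, treatment) {
  if (is.null(names(proportions)) || !all(nzchar(names(proportions))))
    stop("proportions must be named")
  if (any(proportions < 0)) stop("proportions must be nonnegative")
  s <- sum(proportions)
  if (abs(s - 100) < 1) proportions <- proportions / s
  else if (abs(s - 1) > 1e-9) stop("proportions must sum to 1 (or 100%)")
  structure(list(proportions = proportions / sum(proportions),
                 treatment = treatment),
            class = "community_profile")
}

#' Simulate one paired-end amplicon library
#'
#' Draws read templates multinomially from the community profile, applies
#' the artefact model (PCR chimeras as single-crossover concatenations of
#' two templates, off-length indel variants of 3-30 nt, single-nucleotide
#' frameshifts, per-base substitution errors) and emits paired reads with
#' constant Q30 qualities plus a complete truth table.
#'
#' @param panel an `mcra_panel`; its nucleotide sequences are the
#'   amplification templates.
#' @param profile a [community_profile()] whose names are panel ids.
#' @param n_reads number of read pairs.
#' @param read_length read length (forward and reverse).
#' @param error_rate per-base substitution probability.
#' @param chimera_rate,offlength_rate,frameshift_rate artefact fractions;
#'   artefact classes are mutually exclusive per read.
#' @param seed integer seed.
#' @param sample_id id prefix for read names.
#' @return list with `pairs` (data frame id/seq1/qual1/seq2/qual2) and
#'   `truth` (one row per read).
#' @export
simulate_sample <- function(panel, profile, n_reads, read_length = 250L,
                            error_rate = 0, chimera_rate = 0,
                            offlength_rate = 0, frameshift_rate = 0,
                            seed = 1L, sample_id = "S1") {
  rates <- c(error_rate, chimera_rate, offlength_rate, frameshift_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (chimera_rate + offlength_rate + frameshift_rate > 1)
    stop("artefact rates sum above 1")
  empty <- list(
    pairs = data.frame(id = character(0), seq1 = character(0),
                       qual1 = character(0), seq2 = character(0),
                       qual2 = character(0)),
    truth = data.frame(id = character(0), sample = character(0),
                       source = character(0), is_chimera = logical(0),
                       parent_a = character(0), parent_b = character(0),
                       crossover = integer(0), is_offlength = logical(0),
                       is_frameshifted = logical(0)))
  if (n_reads == 0) return(empty)
  ids <- names(profile$proportions)
  missing <- setdiff(ids, names(panel$nucleotides))
  if (length(missing))
    stop("profile ids absent from panel: ", paste(missing, collapse = ", "))
  with_seed(seed, {
    p <- profile$proportions
    src <- sample(ids, n_reads, replace = TRUE, prob = p)
    cat_p <- c(normal = 1 - chimera_rate - offlength_rate -
                 frameshift_rate, chimera = chimera_rate,
               offlength = offlength_rate, frameshift = frameshift_rate)
    category <- sample(names(cat_p), n_reads, replace = TRUE,
                       prob = cat_p)
    tmpl <- unname(panel$nucleotides[src])
    parent_a <- parent_b <- rep(NA_character_, n_reads)
    crossover <- rep(NA_integer_, n_reads)

    ch <- which(category == "chimera")
    for (i in ch) {
      a <- src[i]
      b <- sample(ids, 1, prob = p)
      while (length(ids) > 1 && b == a) b <- sample(ids, 1, prob = p)
      la <- nchar(panel$nucleotides[[a]])
      lb <- nchar(panel$nucleotides[[b]])
      x <- sample(2:(min(la, lb) - 1L), 1)
      tmpl[i] <- paste0(substr(panel$nucleotides[[a]], 1, x),
                        substr(panel$nucleotides[[b]], x + 1L, lb))
      parent_a[i] <- a; parent_b[i] <- b; crossover[i] <- x
    }
    off <- which(category == "offlength")
    for (i in off) {
      k <- sample(3:30, 1) * sample(c(-1L, 1L), 1)
      tmpl[i] <- apply_indel(tmpl[i], k)
    }
    fs <- which(category == "frameshift")
    for (i in fs) tmpl[i] <- apply_indel(tmpl[i], sample(c(-1L, 1L), 1))

    len <- nchar(tmpl)
    r1 <- substr(tmpl, 1L, pmin(read_length, len))
    r2 <- revcomp(substr(tmpl, pmax(1L, len - read_length + 1L), len))
    if (error_rate > 0) {
      r1 <- add_substitutions(r1, error_rate)
      r2 <- add_substitutions(r2, error_rate)
    }
    rid <- sprintf("%s_r%06d", sample_id, seq_len(n_reads))
    pairs <- data.frame(id = rid, seq1 = r1, qual1 = strrep("?", nchar(r1)),
                        seq2 = r2, qual2 = strrep("?", nchar(r2)))
    truth <- data.frame(id = rid, sample = sample_id,
                        source = ifelse(category == "chimera",
                                        NA_character_, src),
                        is_chimera = category == "chimera",
                        parent_a = parent_a, parent_b = parent_b,
                        crossover = crossover,
                        is_offlength = category == "offlength",
                        is_frameshifted = category == "frameshift")
    list(pairs = pairs, truth = truth)
  })
}

# Insert (k > 0) or delete (k < 0) |k| bases at a random interior
# position, keeping a margin so read ends are unaffected structurally.
apply_indel <- function(seq, k) {
  l <- nchar(seq)
  margin <- min(40L, l %/% 4L)
  pos <- sample(seq.int(margin, l - margin - abs(k)), 1)
  if (k > 0) {
    ins <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                 collapse = "")
    paste0(substr(seq, 1, pos), ins, substr(seq, pos + 1L, l))
  } else {
    paste0(substr(seq, 1, pos), substr(seq, pos - k + 1L, l))
  }
}

add_substitutions <- function(reads, rate) {
  nerr <- rbinom(length(reads), nchar(reads), rate)
  idx <- which(nerr > 0)
  for (i in idx) {
    chars <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(chars), nerr[i])
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' Mean community profiles of the 25 MCRA clusters
#'
#' The built-in community fixture: mean relative abundances (percent) of
#' 25 mcrA transcript peptide clusters observed in rumen digesta of cattle
#' under four feeding regimes (R restricted, A ad libitum, RA restricted
#' then re-alimented, AA ad libitum throughout), together with the
#' taxonomic assignment of each cluster (family, genus, clade). Columns
#' sum to approximately 100 within rounding.
#'
#' @return data frame with columns cluster, R, A, RA, AA, family, genus,
#'   clade.
#' @export
reference_profiles <- function() {
  tab <- read.delim(text =
"cluster\tR\tA\tRA\tAA\tgroup
0\t0.5\t0.8\t1.0\t0.9\tmmc
1\t56.1\t21.0\t30.7\t28.6\tgottschalkii
2\t0.2\t0.3\t0.9\t0.9\tmmc
3\t17.4\t34.7\t23.6\t25.3\tmbr_basal
4\t3.1\t3.2\t3.4\t3.6\tmsp
6\t4.0\t4.0\t8.0\t9.0\tmmc
10\t1.2\t3.9\t2.7\t2.9\tmbr_basal
11\t2.4\t0.5\t2.0\t2.8\tmmc
13\t0.1\t0.5\t0.8\t1.6\tmmc
14\t0.0\t0.6\t0.4\t0.5\tmmc
32\t0.0\t0.7\t1.2\t0.8\tmmc
144\t0.0\t3.4\t3.8\t4.63\tmmc
883\t0.0\t4.1\t3.8\t3.5\truminantium
7083\t11.5\t3.6\t4.6\t2.7\tgottschalkii
7084\t1.9\t0.3\t0.7\t1.0\tgottschalkii
7087\t0.2\t0.1\t0.2\t0.2\tmbr_basal
7089\t0.3\t0.2\t0.2\t0.4\tmbr_basal
7092\t0.4\t0.1\t0.1\t0.1\tgottschalkii
7094\t0.0\t10.0\t7.8\t6.8\truminantium
7105\t0.2\t0.2\t0.1\t0.3\tgottschalkii
7159\t0.1\t0.6\t0.5\t0.4\tmbr_basal
22291\t0.3\t2.8\t1.1\t0.9\tmsp
23687\t0.0\t4.1\t2.3\t1.8\tmsp
23941\t0.0\t0.1\t0.1\t0.4\tmsp
23942\t0.0\t0.2\t0.2\t0.1\tmsp
", stringsAsFactors = FALSE)
  grp <- clade_label_table()
  m <- match(tab$group, grp$group)
  data.frame(cluster = as.character(tab$cluster),
             R = tab$R, A = tab$A, RA = tab$RA, AA = tab$AA,
             family = grp$family[m], genus = grp$genus[m],
             clade = grp$clade[m])
}

clade_label_table <- function() {
  data.frame(
    group  = c("gottschalkii", "ruminantium", "mbr_basal", "msp", "mmc"),
    family = c(rep("Methanobacteriaceae", 4), "Methanomassiliicoccaceae"),
    genus  = c(rep("Methanobrevibacter", 3), "Methanosphaera",
               "Methanomassiliicoccus"),
    clade  = c("gottschalkii clade", "ruminantium clade", "smithii clade",
               "stadtmanae clade", "luminyensis clade"))
}

#' Per-treatment community profiles, renormalised to fractions
#'
#' @return named list of four [community_profile()] objects (R, A, RA,
#'   AA); proportion names are panel ids of the form `cl<cluster>`.
#' @export
treatment_profiles <- function() {
  tab <- reference_profiles()
  out <- lapply(c("R", "A", "RA", "AA"), function(tr) {
    p <- tab[[tr]]
    names(p) <- paste0("cl", tab$cluster)
    community_profile(p, tr)
  })
  names(out) <- c("R", "A", "RA", "AA")
  out
}

#' Default clade specifications for the simulated study
#'
#' Five clades mirroring the taxonomic structure of the community
#' fixture: three Methanobrevibacter clades (gottschalkii, ruminantium
#' and a basal clade), Methanosphaera, and Methanomassiliicoccaceae. Each
#' clade holds its community clusters plus `n_refs` labelled reference
#' sequences for tree placement.
#'
#' @param n_refs reference sequences per clade.
#' @return list of [clade_spec()] objects.
#' @export
default_clade_specs <- function(n_refs = 3L) {
  tab <- reference_profiles()
  grp <- clade_label_table()
  div <- c(gottschalkii = 0.12, ruminantium = 0.12, mbr_basal = 0.12,
           msp = 0.20, mmc = 0.30)
  lapply(grp$group, function(g) {
    row <- grp[grp$group == g, ]
    cl_ids <- paste0("cl", tab$cluster[tab$clade == row$clade])
    ref_ids <- sprintf("ref_%s_%d", g, seq_len(n_refs))
    clade_spec(name = g, family = row$family, genus = row$genus,
               clade = row$clade,
               n_members = length(cl_ids) + n_refs,
               divergence_from_root = div[[g]],
               within_member_divergence = 0.019,
               member_ids = c(cl_ids, ref_ids))
  })
}

#' Subset a panel to its labelled reference entries (ids `ref_*`)
#' @param panel an `mcra_panel`.
#' @return an `mcra_panel` restricted to reference entries.
#' @export
panel_references <- function(panel) {
  keep <- grepl("^ref_", panel$taxonomy$id)
  structure(list(peptides = panel$peptides[panel$taxonomy$id[keep]],
                 nucleotides = panel$nucleotides[panel$taxonomy$id[keep]],
                 taxonomy = panel$taxonomy[keep, , drop = FALSE],
                 peptide_length = panel$peptide_length,
                 forward_primer = panel$forward_primer,
                 reverse_primer = panel$reverse_primer,
                 seed = panel$seed),
            class = "mcra_panel")
}

#' Simulate the full multi-treatment amplicon experiment
#'
#' Generates the default study layout: 54 libraries split 13 R / 12 A /
#' 15 RA / 14 AA, each drawn from its treatment's community profile over
#' the default 25-cluster panel. Per-sample seeds are derived from the
#' global seed, so the experiment is reproducible end to end.
#'
#' @param n_per_treatment named integer vector of library counts.
#' @param n_reads read pairs per library (default 65000, the order of
#'   magnitude of a multiplexed MiSeq run split over 54 libraries).
#' @param panel an `mcra_panel`; default is built from
#'   [default_clade_specs()].
#' @param profiles named list of [community_profile()]s per treatment.
#' @param error_rate,chimera_rate,offlength_rate,frameshift_rate artefact
#'   settings passed to [simulate_sample()].
#' @param read_length read length.
#' @param seed global seed.
#' @return list with `samples` (named list of per-sample `pairs` data
#'   frames), `sheet` (sample sheet data frame), `truth` (combined truth
#'   table) and `panel`.
#' @export
simulate_experiment <- function(n_per_treatment = c(R = 13L, A = 12L,
                                                    RA = 15L, AA = 14L),
                                n_reads = 65000L,
                                panel = NULL,
                                profiles = treatment_profiles(),
                                error_rate = 0, chimera_rate = 0,
                                offlength_rate = 0, frameshift_rate = 0,
                                read_length = 250L, seed = 1L) {
  if (is.null(panel))
    panel <- generate_reference_panel(default_clade_specs(),
                                      seed = derive_seed(seed, "panel"))
  samples <- list()
  truth <- list()
  sheet <- list()
  for (tr in names(n_per_treatment)) {
    if (!tr %in% names(profiles))
      stop("no profile for treatment ", tr)
    for (i in seq_len(n_per_treatment[[tr]])) {
      sid <- sprintf("%s%02d", tr, i)
      sim <- simulate_sample(panel, profiles[[tr]], n_reads,
                             read_length = read_length,
                             error_rate = error_rate,
                             chimera_rate = chimera_rate,
                             offlength_rate = offlength_rate,
                             frameshift_rate = frameshift_rate,
                             seed = derive_seed(seed, sid),
                             sample_id = sid)
      samples[[sid]] <- sim$pairs
      truth[[sid]] <- sim$truth
      sheet[[sid]] <- data.frame(sample = sid, treatment = tr,
                                 r1 = "", r2 = "")
    }
  }
  list(samples = samples, sheet = do.call(rbind, sheet),
       truth = do.call(rbind, truth), panel = panel)
}

#' Write a simulated experiment to disk
#'
#' Paired FASTQ per library, sample sheet, truth table TSV, and the panel
#' as FASTA plus taxonomy TSV.
#'
#' @param exp result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @param gzip compress FASTQ files.
#' @return the sample sheet with populated paths, invisibly.
#' @export
write_experiment <- function(exp, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  sheet <- exp$sheet
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample[i]
    sheet$r1[i] <- file.path(dir, paste0(sid, "_R1", ext))
    sheet$r2[i] <- file.path(dir, paste0(sid, "_R2", ext))
    write_fastq_pairs(exp$samples[[sid]], sheet$r1[i], sheet$r2[i])
  }
  write_sample_sheet(sheet, file.path(dir, "samples.tsv"))
  write.table(exp$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta(exp$panel$nucleotides, file.path(dir, "panel_nt.fasta"))
  write_fasta(exp$panel$peptides, file.path(dir, "panel_aa.fasta"))
  write.table(exp$panel$taxonomy, file.path(dir, "panel_taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sheet)
}
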