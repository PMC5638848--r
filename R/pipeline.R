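# End-to-end orchestration: merge -> size selection -> chimera removal
# -> ORF screen -> peptide clustering -> parsimony placement ->
# community statistics, with per-stage count conservation reports.
# Read pairs are dereplicated before merging (identical pairs merge
# identically), so all downstream stages operate on unique sequences
# with multiplicities.

stage_report <- function(stage, input, output, rejected = c(none = 0)) {
  data.frame(stage = stage, input = input, output = output,
             rejected = sum(rejected),
             reasons = paste(sprintf("%s=%d", names(rejected),
                                     as.integer(rejected)),
                             collapse = ";"))
}

derep_pairs <- function(pairs) {
  key <- paste(pairs$seq1, pairs$seq2, sep = "\r")
  idx <- !duplicated(key)
  data.frame(seq1 = pairs$seq1[idx], qual1 = pairs$qual1[idx],
             seq2 = pairs$seq2[idx], qual2 = pairs$qual2[idx],
             count = as.integer(table(factor(key, levels = key[idx]))))
}

#' Run the full mcrA amplicon pipeline
#'
#' @param samples named list of read-pair data frames (columns id, seq1,
#'   qual1, seq2, qual2), or a sample sheet data frame with columns
#'   sample, treatment, r1, r2 pointing at FASTQ files.
#' @param treatments named character vector of treatment labels per
#'   sample (ignored when `samples` is a sample sheet).
#' @param panel `mcra_panel` of labelled references used for
#'   reference-mode chimera screening and tree placement (optional; when
#'   NULL both are skipped).
#' @param config an `mcra_config`.
#' @param do_phylo,do_stats switch off the placement or statistics layer
#'   (e.g. for stage-level testing).
#' @param verbose log one line per stage to stderr.
#' @return an object of class `mcra_run`; see Details.
#'
#' @details The returned object bundles per-stage `reports`, the
#'   `counts` and `relative` sample x cluster matrices, cluster
#'   `centroids`, `retained_fraction` of peptides after the cluster
#'   floor, the collapsed parsimony `tree` with `taxonomy` assignments,
#'   and a `stats` list (diversity, Bray-Curtis, PCoA, nMDS, dendrogram,
#'   heatmap grid, Kruskal-Wallis, pairwise Wilcoxon letters, ANOVA +
#'   Tukey on diversity indices).
#' @export
run_pipeline <- function(samples, treatments = NULL, panel = NULL,
                         config = pipeline_config(), do_phylo = TRUE,
                         do_stats = TRUE, verbose = TRUE) {
  log1 <- function(...) if (verbose) message(sprintf(...))
  if (is.data.frame(samples)) {
    sheet <- samples
    if (!nrow(sheet)) stop("no samples")
    treatments <- setNames(sheet$treatment, sheet$sample)
    samples <- lapply(seq_len(nrow(sheet)), function(i)
      read_fastq_pairs(sheet$r1[i], sheet$r2[i]))
    names(samples) <- sheet$sample
  }
  if (!length(samples)) stop("no samples")
  sample_ids <- names(samples)
  if (is.null(treatments))
    stop("treatments must be supplied for in-memory samples")
  treatments <- treatments[sample_ids]
  reports <- list()

  # merge + size selection, per sample on dereplicated pairs ----------
  raw_n <- vapply(samples, nrow, integer(1))
  merged_tabs <- list()
  merge_rej <- 0L
  size_rej <- 0L
  for (s in sample_ids) {
    dp <- derep_pairs(samples[[s]])
    n <- nrow(dp)
    seqs <- character(n); ok <- logical(n)
    for (i in seq_len(n)) {
      r <- merge_pair(dp$seq1[i], dp$qual1[i], dp$seq2[i], dp$qual2[i],
                      config$min_overlap, config$max_mismatch_rate)
      if (is.null(r$rejected)) { ok[i] <- TRUE; seqs[i] <- r$merged }
    }
    merge_rej <- merge_rej + sum(dp$count[!ok])
    keep <- ok & length_filter(nchar(seqs), config$amplicon_length,
                               config$amplicon_tolerance)
    size_rej <- size_rej + sum(dp$count[ok & !keep])
    merged_tabs[[s]] <- data.frame(seq = seqs[keep],
                                   count = dp$count[keep])
  }
  total_raw <- sum(raw_n)
  total_merged <- total_raw - merge_rej
  total_sized <- total_merged - size_rej
  reports$merge <- stage_report("merge", total_raw, total_merged,
                                c(no_overlap = merge_rej))
  reports$size <- stage_report("size_select", total_merged, total_sized,
                               c(off_length = size_rej))
  log1("stage merge: %d pairs in, %d merged, %d rejected",
       total_raw, total_merged, merge_rej)
  log1("stage size_select: %d in, %d kept, %d off-length",
       total_merged, total_sized, size_rej)

  # pool and dereplicate across the run -------------------------------
  all_seqs <- unlist(lapply(merged_tabs, `[[`, "seq"), use.names = FALSE)
  if (!length(all_seqs)) stop("no amplicons survived merging")
  uniq <- unique(all_seqs)
  counts <- matrix(0L, length(uniq), length(sample_ids),
                   dimnames = list(NULL, sample_ids))
  for (s in sample_ids) {
    t0 <- merged_tabs[[s]]
    idx <- match(t0$seq, uniq)
    counts[cbind(idx, match(s, sample_ids))] <-
      counts[cbind(idx, match(s, sample_ids))] + t0$count
  }
  run_counts <- rowSums(counts)

  # chimera removal ---------------------------------------------------
  chim <- filter_chimeras(uniq, run_counts, panel, config)
  chim_rej <- sum(run_counts[chim$flagged])
  reports$chimera <- stage_report("chimera", total_sized,
                                  total_sized - chim_rej,
                                  c(chimera = chim_rej))
  log1("stage chimera: %d unique amplicons screened, %d flagged (%d reads)",
       length(uniq), length(chim$flagged), chim_rej)
  uniq <- uniq[chim$clean]
  counts <- counts[chim$clean, , drop = FALSE]

  # ORF screen --------------------------------------------------------
  scr <- screen_orfs(uniq, config$primers,
                     c(config$peptide_length_min,
                       config$peptide_length_max))
  acc <- !is.na(scr$peptide)
  rej_reasons <- vapply(c("no_frame", "multiple_frames", "stop_codon",
                          "length", "motif"), function(rs)
    sum(rowSums(counts)[!acc][scr$rejected[!acc] == rs]), numeric(1))
  orf_total_in <- sum(counts)
  orf_total_out <- sum(counts[acc, , drop = FALSE])
  reports$orf <- stage_report("orf_screen", orf_total_in, orf_total_out,
                              rej_reasons)
  log1("stage orf_screen: %d reads in, %d accepted", orf_total_in,
       orf_total_out)
  peptides <- scr$peptide[acc]
  counts <- counts[acc, , drop = FALSE]

  # dereplicate peptides ----------------------------------------------
  up <- unique(peptides)
  pcounts <- matrix(0L, length(up), length(sample_ids),
                    dimnames = list(NULL, sample_ids))
  for (i in seq_along(peptides)) {
    j <- match(peptides[i], up)
    pcounts[j, ] <- pcounts[j, ] + counts[i, ]
  }

  # clustering + floor -------------------------------------------------
  cl <- greedy_cluster(up, rowSums(pcounts), config$cluster_identity)
  cm <- build_count_matrix(cl, pcounts)
  totals <- colSums(cm$counts)
  floor_res <- apply_min_fraction(totals, config$cluster_min_fraction)
  kept_cl <- floor_res$retained
  cluster_counts <- cm$counts[, kept_cl, drop = FALSE]
  centroids <- cm$centroids[kept_cl]
  reports$cluster <- stage_report(
    "cluster", sum(cm$counts), sum(cluster_counts),
    c(below_floor = sum(cm$counts) - sum(cluster_counts)))
  log1("stage cluster: %d clusters, %d retained (%.1f%% of peptides)",
       length(totals), length(kept_cl),
       100 * floor_res$retained_fraction)
  rel <- relative_abundance(cluster_counts)

  # parsimony placement -----------------------------------------------
  tree <- NULL; taxonomy <- NULL
  if (do_phylo && !is.null(panel)) {
    aln <- align_to_panel(centroids, panel)
    aln <- mask_columns(aln, config$site_coverage_min)
    tree <- bootstrap_support(aln, reps = config$bootstrap_reps,
                              collapse_below = config$collapse_support,
                              seed = derive_seed(config$seed, "phylo"),
                              search_reps = config$random_addition_reps,
                              boot_reps = config$bootstrap_addition_reps)
    taxonomy <- assign_taxonomy(tree, panel$taxonomy, names(centroids))
    log1("stage phylo: %d positions, parsimony length %d, %d splits kept",
         aln$n_positions, tree$length, length(tree$splits))
  }

  # community statistics ----------------------------------------------
  stats <- NULL
  if (do_stats) {
    groups <- factor(unname(treatments))
    empty <- attr(rel, "empty_samples")
    use <- setdiff(sample_ids, empty)
    relu <- rel[use, , drop = FALSE]
    gu <- droplevels(groups[match(use, sample_ids)])
    d <- braycurtis_matrix(relu)
    stats <- list(
      diversity = diversity_table(cluster_counts[use, , drop = FALSE]),
      bray = d,
      pcoa = pcoa(d),
      nmds = nmds(d, k = 2, n_restarts = config$nmds_restarts,
                  maxit = config$nmds_maxit, tol = config$nmds_tol,
                  seed = derive_seed(config$seed, "nmds")),
      dendrogram = upgma_dendrogram(d),
      heatmap = heatmap_export(relu),
      kruskal = kruskal_bh(relu, gu),
      wilcoxon = pairwise_wilcoxon_bh(relu, gu, config$fdr_alpha),
      excluded_samples = empty)
    if (!is.null(taxonomy)) {
      tx <- taxonomy
      names(tx)[names(tx) == "cluster"] <- "cluster"
      stats$family <- aggregate_taxa(relu, tx, "family")
      stats$genus <- aggregate_taxa(relu, tx, "genus")
      stats$clade <- aggregate_taxa(relu, tx, "clade")
    }
    stats$anova <- anova_tukey(stats$diversity, gu, config$fdr_alpha)
    log1("stage stats: %d samples analysed, %d excluded as empty",
         length(use), length(empty))
  }

  structure(list(config = config,
                 reports = do.call(rbind, reports),
                 counts = cluster_counts, relative = rel,
                 centroids = centroids,
                 assignments = cl,
                 retained_fraction = floor_res$retained_fraction,
                 chimera_verdicts = chim$verdicts,
                 tree = tree, taxonomy = taxonomy,
                 treatments = treatments, stats = stats),
            class = "mcra_run")
}

#' @export
print.mcra_run <- function(x, ...) {
  cat("mcrA amplicon pipeline run\n")
  cat("  samples:", nrow(x$counts), " clusters retained:",
      ncol(x$counts), sprintf(" (%.1f%% of peptides)\n",
                              100 * x$retained_fraction))
  print(x$reports[, c("stage", "input", "output", "rejected")],
        row.names = FALSE)
  if (!is.null(x$taxonomy)) {
    cat("  taxonomy (family counts):\n")
    print(table(x$taxonomy$family, useNA = "ifany"))
  }
  invisible(x)
}

#' Export the run's main tables as TSV files
#'
#' Count matrix, relative abundances, taxonomy, diversity, test results
#' and ordination coordinates.
#'
#' @param run an `mcra_run`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(run$counts, file.path(dir, "cluster_counts.tsv"))
  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(data.frame(sample = rownames(run$relative), run$relative,
                check.names = FALSE), "relative_abundance.tsv")
  if (!is.null(run$taxonomy)) wt(run$taxonomy, "taxonomy.tsv")
  if (!is.null(run$tree)) write_tree(run$tree, file.path(dir, "tree.nwk"))
  if (!is.null(run$stats)) {
    for (rk in c("family", "genus", "clade"))
      if (!is.null(run$stats[[rk]]))
        wt(data.frame(sample = rownames(run$stats[[rk]]),
                      run$stats[[rk]], check.names = FALSE),
           paste0("abundance_", rk, ".tsv"))
    wt(run$stats$diversity, "diversity.tsv")
    wt(run$stats$kruskal, "kruskal_bh.tsv")
    wt(run$stats$wilcoxon$tests, "wilcoxon_bh.tsv")
    wt(data.frame(sample = rownames(run$stats$pcoa$coordinates),
                  run$stats$pcoa$coordinates), "pcoa.tsv")
    wt(data.frame(sample = rownames(run$stats$nmds$coordinates),
                  run$stats$nmds$coordinates,
                  stress = run$stats$nmds$stress), "nmds.tsv")
    wt(data.frame(sample = rownames(run$stats$heatmap$grid),
                  run$stats$heatmap$grid, check.names = FALSE),
       "heatmap_grid.tsv")
  }
  invisible(dir)
}
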