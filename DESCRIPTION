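Package: mcrapipe
Title: Profiling Transcriptionally Active Rumen Methanogens from mcrA
    cDNA Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for functional-gene amplicon profiling of
    methanogenic archaea via the mcrA transcript. Paired-end cDNA amplicon
    reads are overlap-merged, size selected, screened for PCR chimeras
    (de novo and against a reference panel), translated in six reading
    frames with a conserved primer-motif check, and clustered into peptide
    clusters at 97% identity. Cluster centroids are placed among labelled
    reference MCRA proteins by maximum parsimony (random-addition starting
    trees, SPR hill climbing, bootstrap supports) and assigned
    family/genus/clade labels. A community-statistics layer provides
    relative-abundance aggregation, alpha diversity, square-root
    Bray-Curtis ordination (nMDS and PCoA), UPGMA dendrograms, heatmap
    export, Kruskal-Wallis and pairwise Wilcoxon tests with
    Benjamini-Hochberg correction, and one-way ANOVA with Tukey HSD. A
    synthetic-community simulator generates reference panels and paired-end
    reads with known truth so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    vegan,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
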