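---
title: "Profiling transcriptionally active rumen methanogens from mcrA amplicons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mcrapipe methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Methanogenic archaea in the rumen produce methane during enteric
fermentation. Because DNA surveys count organisms whether or not they are
metabolically active, transcript-level profiling of *mcrA* — the gene for
subunit A of methyl-coenzyme M reductase, the enzyme catalysing the final
step of methanogenesis — is used as a marker of which methanogens are
*actively* producing methane. The measurement unit is the **MCRA
cluster**: a 97%-identity cluster of translated *mcrA* cDNA amplicon
peptides. mcrapipe implements the full computational path from paired-end
amplicon reads to per-treatment community statistics:

1. overlap-merge read pairs into amplicons and size-select at 472 ± 1 nt;
2. remove PCR chimeras de novo and against a reference panel;
3. translate each amplicon in six frames and keep the single stop-free,
   primer-anchored frame (155–160 aa);
4. cluster peptides greedily at 97% identity and discard clusters below
   0.1% of total peptides;
5. place cluster centroids among labelled reference MCRA proteins by
   maximum parsimony and assign family/genus/clade;
6. compute relative abundances, alpha diversity, square-root Bray–Curtis
   ordinations, and treatment contrasts.

A synthetic-community simulator generates reference panels and reads with
a complete per-read truth table, so every stage is testable without
external sequencing data.

## The synthetic-data generator

The generator *defines the study conditions* the package is validated
under; it is not a tuning dial.

**Reference panels.** Clades are simulated as a star phylogeny around a
random ancestral peptide. Each clade's `divergence_from_root` is split in
half and applied to sites allocated disjointly across clades, so two
clades with settings $d_1$ and $d_2$ end up approximately
$(d_1 + d_2)/2$ substitutions per site apart; with the default setting
of 0.10 for two clades, between-clade identity lands near 0.90. Member
sequences receive `within_member_divergence` substitutions on sites
disjoint across members of a clade, so members sit twice that distance
from each other. The generated panel is audited against its contracts
(cross-clade identity ≤ 0.96, member-to-root identity ≥ 0.98) and a
"panel not separable" error is raised when the settings cannot satisfy
them. The default study panel uses five clades mirroring the fixture
taxonomy — three *Methanobrevibacter* clades (gottschalkii, ruminantium
and a basal clade), *Methanosphaera*, and Methanomassiliicoccaceae —
with divergences 0.12/0.12/0.12/0.20/0.30 and member divergence 0.019.
The member setting is chosen so that distinct community members are
~3.8% apart (distinct clusters at the 97% threshold) while remaining
≥ 98% identical to their clade root.

**Primers.** The translated amplicon is anchored by the conserved
translations of the amplification primers. The packaged primer patterns
are synthetic placeholders with the length and degeneracy structure of
the Mlas-forward/mcrA-reverse pair used for rumen methanogens; the true
sequences are configuration (`primer_pair()`), since different labs run
different variants. One concrete expansion of each degenerate pattern is
drawn per panel and becomes the nucleotide sequence of the primer-encoded
termini.

**Nucleotide templates.** Panel nucleotide sequences are built by
uniform-synonymous back-translation of the interior peptide plus the
concretized primers. Because each member is back-translated
independently, synonymous sites are uncorrelated between members; real
within-clade sequences would share most silent sites. This makes
nucleotide-level divergence higher than in real data — a conservative
regime for read merging, and one to keep in mind when interpreting the
chimera benchmark (parent divergence at the nucleotide level is what the
filter sees).

**Reads and artefacts.** Templates are drawn multinomially from the
community profile. Artefact classes are mutually exclusive per read:
chimeras are single-crossover concatenations of two profile-weighted
templates with the crossover uniform over interior positions; off-length
fragments are ±3–30 nt indel variants; frameshifts are single ±1 nt
indels inside the insert. Sequencing errors are i.i.d. per-base
substitutions. Qualities are constant Q30 — the pipeline makes no
quality-based filtering decision after merging, so modelling
quality decay would add nothing testable. Default depth is 65,000 read
pairs per library (the order of magnitude of a multiplexed MiSeq run
split across 54 libraries); validation runs use 50,000. The default
layout is 54 libraries split 13 R / 12 A / 15 RA / 14 AA (restricted,
ad libitum, restricted-then-realimented, ad libitum throughout).

**The community fixture.** `reference_profiles()` carries the mean
relative abundances of the 25 MCRA clusters per treatment together with
their taxonomic assignment; `treatment_profiles()` renormalises each
column to fractions. These profiles are the generating truth for
end-to-end recovery: simulate 54 libraries, run the pipeline, and the
group-mean cluster abundances must come back within three multinomial
standard errors, with every cluster assigned to its generating
family/genus/clade.

## Read preparation

Merging scans the 3' end of read 1 against the reverse complement of
read 2 and accepts the longest overlap (≥ 20 nt) whose mismatch rate is
≤ 0.1; at overlap mismatches the higher-quality base wins, read 1 on
ties. These are merge-tool-style defaults; they are configuration, not
estimates. Merged amplicons outside 472 ± 1 nt are discarded. A
per-cycle min/mean/max quality summary is reported, but no read is
dropped on quality.

## Chimera screen

A query is modelled as a two-parent, single-crossover chimera. For a
candidate pair (A, B), the query is globally aligned to each parent
(match +1, mismatch 0, affine gaps), giving per-position match profiles;
for every crossover position the fraction of query positions explained
by A on the left and B on the right (and the reverse orientation) is
computed. `b2` is the best such fraction, `b1` the best single-parent
identity, and the query is chimeric iff `b2 − b1 ≥ 0.02` and
`b2 ≥ 0.99`. Queries are processed in decreasing dereplicated
abundance; only sequences already accepted as non-chimeric are eligible
de novo parents (a chimera cannot outnumber its parents, enforced by the
2.0 abundance skew), and the reference panel is screened second.
Candidates are ranked by shared 8-mers with each quarter of the query
(top 4 per segment): for any crossover position at least one quarter is
pure parent sequence, so both true parents stay in the candidate set
even when the crossover is far from the middle.

**Detectability bound.** With `b2 = 1` for an error-free bimera, the
chimera call requires the minority parent segment to contribute at least
2% of alignment columns as mismatches: a crossover within distance
$0.02 L / d$ of either end (with $d$ the parent divergence) is
information-theoretically indistinguishable from its majority parent at
these thresholds. Under a uniform crossover law this bounds attainable
sensitivity at $1 - 2 \cdot 0.02/d$ per parent pair — about 86% for
parents 28% divergent at the nucleotide level, and lower for closer
parents. Two effects lift the measured benchmark above this naive
bound: bimeras whose minority segment happens to carry no differing
site are sequence-identical to a parent, collapse into it at
dereplication and so never enter the chimeric truth set; and
sensitivity is measured over the remaining unique, distinguishable
bimeras. At the packaged benchmark settings the filter reaches ~91%
sensitivity with zero false positives; crossovers very near an amplicon
end remain undetectable in principle at these thresholds.

## ORF screen

Each surviving amplicon is translated in all six frames (+1..+3 on the
sequence, −1..−3 on its reverse complement, trailing partial codons
dropped). A frame is acceptable when it has no stop codon, begins with
residues compatible with the forward-primer motif sets, ends compatible
with the reverse motif sets (0 mismatches by default — "conserved" is
read strictly; configurable to 1), and falls in 155–160 aa. Exactly one
acceptable frame must exist; ambiguity ("multiple_frames") is a
rejection, because a genuine amplicon yields a single conserved frame.
Primer-encoded residues are kept in the peptide (the identity threshold
refers to the full translated amplicon).

## Clustering

Identity is defined by global alignment (match +1, mismatch 0, affine
gap open 10 / extend 1) as matches over alignment columns excluding
terminal-gap columns — with fixed-length amplicons terminal gaps rarely
arise, but the denominator convention is stated because tools differ.
Clustering is greedy and abundance-sorted: peptides are processed in
decreasing total abundance (ties broken lexicographically, which makes
equal-abundance input order irrelevant) and join the first centroid at
≥ 97% identity, else found a new cluster. The 0.1% floor applies to the
pooled run total, inclusive at the boundary. Cluster labels C1, C2, …
are assigned by decreasing total abundance and are arbitrary; they carry
no meaning beyond this run.

## Parsimony placement

Cluster centroids and the labelled references are aligned progressively
(pairwise Gotoh under BLOSUM62, gap open 10 / extend 1, guided by a
UPGMA tree over 3-mer Jaccard distances), then columns with < 85%
site coverage are masked. Tree length is the weighted Fitch count over
unordered amino-acid states with gaps as missing data (the conventional
default for protein parsimony; the choice matters little after
masking). The search builds a random stepwise-addition starting tree per
replicate (10 by default) and hill-climbs with first-improvement SPR
until no rearrangement shortens the tree; "search level 1" is read as
single-SPR-radius neighbourhoods. Bootstrap supports come from 500
column resamples, each re-searched with 2 random-addition starts (a
documented reduction of the headline search effort for tractability);
the support of a split is the percentage of replicate best trees
containing it. Splits of the strict consensus of all equally
parsimonious trees with support below 30% are collapsed.

Taxonomy assignment works on the collapsed tree's splits: each cluster
takes the smallest split side containing it and at least one reference
leaf (the whole leaf set as fallback), inheriting each label level on
which all references in that side agree and "unassigned" where they
disagree. Working with split sides makes the rule well-defined on
unrooted trees without choosing a root.

## Community statistics

Relative abundances are percentages per sample (rows sum to 100;
all-zero samples are flagged and excluded from tests). Aggregation to
family/genus/clade sums member clusters and preserves row sums exactly.
Alpha diversity uses observed clusters $S$, Margalef's
$d = (S-1)/\ln N$ (the conventional "richness" of marine-ecology
software, consistent in magnitude with reported rumen values), Shannon
$H' = -\sum p_i \ln p_i$ with natural log, and Simpson $1 - \sum p_i^2$.
Bray–Curtis dissimilarity is computed on square-root transformed
relative abundances. PCoA is classical scaling of the double-centred
squared dissimilarities with negative eigenvalues reported, never
silently dropped. nMDS minimises Kruskal stress-1 by majorisation
(Guttman transform) alternated with isotonic regression, best of 50
starts (first start seeded from PCoA, the rest random; 500 iterations,
tolerance 1e-6); stress is non-increasing within a start. The dendrogram
and heatmap ordering use group-average (UPGMA) clustering.

Hypothesis testing follows the two-track convention of the field:
Kruskal–Wallis per cluster as the omnibus test with Benjamini–Hochberg
correction across clusters, and pairwise Wilcoxon rank-sum tests with BH
across the pairs × clusters family feeding a compact letter display
(groups sharing a letter are not significantly different; letters label
maximal cliques of the non-significance graph, ordered by group means).
Diversity indices are compared by one-way ANOVA with Tukey HSD. The BH
family boundaries (within-omnibus vs pairs × clusters) are a documented
choice, configurable by running the tests on any column subset.

## Numerical and design choices

- All randomness flows through explicit seeds; one global seed fans out
  to per-stage seeds via a documented hash (`derive_seed()`), so stages
  are reproducible in isolation and identical seeds give byte-identical
  outputs.
- Alignment tracebacks prefer diagonal, then gap-in-second, making
  alignments deterministic.
- Degenerate inputs are defined, not crashed on: zero reads give valid
  empty outputs; an all-masked alignment, all-zero sample pairs in
  Bray–Curtis, and a zero peptide total are explicit errors; a
  zero-variance test column reports p = 1.
- Ties in the parsimony search are kept and summarised by strict
  consensus before taxonomy assignment.

## Problem sizes used in validation

The packaged validation runs use: the full 54-library layout at 50,000
reads per library (noise-free) for end-to-end recovery with the default
500 bootstrap replicates; 2,500-read libraries for the chimera
benchmark; exhaustive-enumeration oracles at 5–7 taxa for the tree
search and ≤ 8 sequences for clustering; smaller libraries (300–3,000
reads) for stage-level tests. These sizes are the package's validation
design; the pipeline itself has no built-in limits.

## Known limitations

- The simulator has no PCR-cycle amplification bias, no quality decay,
  no multi-crossover (3+ parent) chimeras, and synonymous sites
  uncorrelated between panel members; passing its tests demonstrates
  correctness of the computational pipeline, not robustness to every
  real-library artefact.
- Greedy clustering is order-dependent by design (abundance-sorted); it
  matches the exhaustive optimum on small well-separated instances but
  is not a global optimiser.
- Bootstrap replicates use reduced search effort; very weakly supported
  splits may be less stable than a full re-search would give.
- The chimera filter's sensitivity is bounded by the Δ = 0.02 threshold
  as analysed above; crossovers very near an amplicon end are
  undetectable in principle at these settings.
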