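# mcrapipe

Profiling transcriptionally active rumen methanogens from paired-end
*mcrA* cDNA amplicon sequencing.

Methane from enteric fermentation is a major agricultural greenhouse-gas
source. DNA surveys of the rumen count methanogens whether or not they
are active; sequencing transcripts of *mcrA* — the gene for subunit A of
methyl-coenzyme M reductase, which catalyses the final step of
methanogenesis — profiles the methanogens that are actually producing
methane. This package is for microbiome researchers who run
functional-gene amplicon studies of that kind: it turns raw paired reads
into **MCRA clusters** (97%-identity clusters of translated amplicon
peptides), places them on a maximum-parsimony tree among labelled
reference MCRA proteins, and computes the community statistics used to
compare feeding treatments.

## The pipeline

| stage | method |
|---|---|
| merge | overlap merging of read pairs (longest overlap ≥ 20 nt with mismatch rate ≤ 0.1, higher-quality consensus base) |
| size selection | amplicons kept at 472 ± 1 nt |
| chimera screen | two-parent single-crossover model, de novo (abundance-skew 2.0) and against a reference panel; chimeric iff best crossover identity b2 ≥ 0.99 and b2 − b1 ≥ 0.02 |
| ORF screen | six-frame translation; exactly one stop-free frame of 155–160 aa anchored by the conserved primer translations |
| clustering | greedy abundance-sorted centroids at 97% identity; clusters below 0.1% of total peptides discarded |
| placement | progressive BLOSUM62 alignment, 85% site-coverage mask, Fitch parsimony with random-addition + SPR search, 500 bootstraps, branches < 30% support collapsed, clade/genus/family assignment |
| statistics | relative abundance, alpha diversity (observed, Margalef, Shannon, Simpson), sqrt Bray–Curtis nMDS/PCoA/UPGMA dendrogram/heatmap export, Kruskal–Wallis + BH, pairwise Wilcoxon + BH with letter display, ANOVA + Tukey HSD |

A synthetic-community simulator (`simulate_experiment()`) generates
reference panels and reads with a per-read truth table, so the whole
pipeline is testable without external data. Its built-in community
fixture carries the mean relative abundances of 25 MCRA clusters across
four cattle feeding groups (R restricted, A ad libitum, RA
restricted-then-realimented, AA ad libitum throughout) in a 54-library
layout (13/12/15/14).

## Worked example

```r
library(mcrapipe)

# simulate a small noise-free study: 4 libraries, 3000 read pairs each
panel <- generate_reference_panel(default_clade_specs(), seed = 11)
profs <- treatment_profiles()
samples <- list(
  R01 = simulate_sample(panel, profs$R, 3000, seed = 101, sample_id = "R01")$pairs,
  R02 = simulate_sample(panel, profs$R, 3000, seed = 102, sample_id = "R02")$pairs,
  A01 = simulate_sample(panel, profs$A, 3000, seed = 103, sample_id = "A01")$pairs,
  A02 = simulate_sample(panel, profs$A, 3000, seed = 104, sample_id = "A02")$pairs)

run <- run_pipeline(samples,
                    treatments = c(R01 = "R", R02 = "R", A01 = "A", A02 = "A"),
                    panel = panel_references(panel),
                    config = pipeline_config(bootstrap_reps = 50))
#> stage merge: 12000 pairs in, 12000 merged, 0 rejected
#> stage size_select: 12000 in, 12000 kept, 0 off-length
#> stage chimera: 25 unique amplicons screened, 0 flagged (0 reads)
#> stage orf_screen: 12000 reads in, 12000 accepted
#> stage cluster: 25 clusters, 24 retained (99.9% of peptides)
#> stage phylo: 157 positions, parsimony length 184, 5 splits kept
#> stage stats: 4 samples analysed, 0 excluded as empty

head(run$taxonomy, 3)
#>   cluster              family              genus              clade support
#> 1      C1 Methanobacteriaceae Methanobrevibacter gottschalkii clade     100
#> 2      C2 Methanobacteriaceae Methanobrevibacter      smithii clade     100
#> 3      C3 Methanobacteriaceae Methanobrevibacter gottschalkii clade     100

round(run$relative[, 1:4], 1)
#>       C1   C2   C3   C4
#> R01 55.1 18.0 11.8  0.0
#> R02 57.7 17.3 10.8  0.0
#> A01 19.9 35.3  3.7  9.6
#> A02 21.5 34.1  3.7 10.1
```

Reading the output: each merged, screened read becomes a peptide; the
simulated community members come back as clusters C1, C2, … labelled by
decreasing pooled abundance (24 of 25 clear the 0.1% floor at this
depth), each placed on the reference tree with 100% bootstrap support
for its clade. The per-sample relative abundances reproduce the
generating treatment profiles: C1, the dominant gottschalkii-clade
cluster, sits near 56% in the restricted libraries and 21% in the ad
libitum ones, while C4 — a ruminantium-clade cluster — is absent from
restricted libraries, the signature contrast between the feeding
regimes. `run$stats` holds the diversity table, ordinations and test
results; `export_run(run, dir)` writes them as TSV.

A thin command-line wrapper is installed at
`inst/scripts/mcrapipe` (`mcrapipe simulate`, `mcrapipe run`).

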