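# Shared fixtures: small panels, profiles and simulated libraries built
# in code at test time.

two_clade_panel <- function(seed = 21, divergence = 0.10,
                            within = 0.019, n = 3) {
  generate_reference_panel(
    list(clade_spec("a", "FamA", "GenA", "cladeA", n, divergence, within),
         clade_spec("b", "FamB", "GenB", "cladeB", n, divergence, within)),
    seed = seed)
}

uniform_profile <- function(panel, treatment = "R") {
  ids <- panel$taxonomy$id
  community_profile(setNames(rep(1 / length(ids), length(ids)), ids),
                    treatment)
}

# Merge + size-select one simulated library into unique amplicons.
merge_simulated <- function(sim, config = pipeline_config()) {
  dp <- mcrapipe:::derep_pairs(sim$pairs)
  merged <- character(nrow(dp)); ok <- logical(nrow(dp))
  for (i in seq_len(nrow(dp))) {
    r <- merge_pair(dp$seq1[i], dp$qual1[i], dp$seq2[i], dp$qual2[i],
                    config$min_overlap, config$max_mismatch_rate)
    if (is.null(r$rejected)) { ok[i] <- TRUE; merged[i] <- r$merged }
  }
  keep <- ok & length_filter(nchar(merged), config$amplicon_length,
                             config$amplicon_tolerance)
  list(seq = merged[keep], count = dp$count[keep])
}

# All unrooted binary topologies over the given tip labels (n <= 7),
# built by recursive edge insertion; returns a list of phylo objects.
all_topologies <- function(tips) {
  n <- length(tips)
  stopifnot(n >= 3, n <= 7)
  base <- structure(list(edge = cbind(4L, 1:3), tip.label = tips[1:3],
                         Nnode = 1L), class = "phylo")
  trees <- list(base)
  for (k in 4:n) {
    if (k > n) break
    out <- list()
    for (tr in trees)
      for (e in seq_len(nrow(tr$edge)))
        out[[length(out) + 1L]] <- insert_tip(tr, e, tips[k])
    trees <- out
    if (k == n) break
  }
  if (n == 3) trees else trees
}

# Insert a new tip into edge e of a phylo (ape numbering maintained).
insert_tip <- function(tr, e, label) {
  ntip <- length(tr$tip.label)
  edge <- tr$edge
  # renumber: tips 1..ntip stay, new tip = ntip+1; old internal i ->
  # i+1; new internal node = ntip + 2
  edge[edge > ntip] <- edge[edge > ntip] + 1L
  newtip <- ntip + 1L
  newnode <- ntip + 1L + tr$Nnode + 1L
  parent <- edge[e, 1]; child <- edge[e, 2]
  edge[e, 2] <- newnode
  edge <- rbind(edge, c(newnode, child), c(newnode, newtip))
  structure(list(edge = edge, tip.label = c(tr$tip.label, label),
                 Nnode = tr$Nnode + 1L), class = "phylo")
}

# Random peptide alignment (no gaps) as a masked_alignment.
random_alignment <- function(ntaxa, nsites, seed,
                             alphabet = c("A", "C", "D", "E")) {
  set.seed(seed)
  rows <- vapply(seq_len(ntaxa), function(i)
    paste(sample(alphabet, nsites, TRUE), collapse = ""), character(1))
  names(rows) <- paste0("t", seq_len(ntaxa))
  structure(list(rows = rows, kept = seq_len(nsites),
                 n_positions = nsites), class = "masked_alignment")
}

# Enumerate all set partitions of seq_len(n) (n <= 8).
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  rec <- function(i, blocks) {
    if (i > n) { out[[length(out) + 1L]] <<- blocks; return() }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      rec(i + 1L, nb)
    }
    rec(i + 1L, c(blocks, list(i)))
  }
  rec(2L, list(1L))
  out
}
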