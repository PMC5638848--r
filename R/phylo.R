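# Maximum-parsimony placement of cluster centroids among labelled
# references: weighted Fitch length, random-addition + SPR hill-climbing
# search (compiled), bootstrap supports, collapse of weakly supported
# branches, and strict consensus across equally parsimonious trees.

# Bitmask-encoded character states of the masked alignment: one bit per
# residue; gaps and unknown residues are missing data (all bits set).
state_masks <- function(aln) {
  m <- alignment_matrix(aln, masked = TRUE)
  full <- bitwShiftL(1L, length(AA_ALPHABET)) - 1L
  idx <- match(m, AA_ALPHABET)
  v <- ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  matrix(as.integer(v), nrow(m), ncol(m), dimnames = dimnames(m))
}

# Compress identical site patterns into weights.
compress_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[u])))
  list(states = states[, u, drop = FALSE], weights = w)
}

#' Parsimony length of a tree by the Fitch algorithm
#'
#' Counts the minimum number of unordered state changes over the kept
#' alignment columns, treating gaps as missing data. The tree may be
#' binary or rooted at a trifurcation (the usual storage of an unrooted
#' binary tree); other multifurcations are not supported.
#'
#' @param tree an `ape::phylo`; tip labels must match alignment rows.
#' @param aln a `masked_alignment`.
#' @return parsimony length (number of changes).
#' @export
fitch_length <- function(tree, aln) {
  states <- state_masks(aln)
  if (!all(tree$tip.label %in% rownames(states)))
    stop("tree tips absent from alignment: ",
         paste(setdiff(tree$tip.label, rownames(states)), collapse = ", "))
  states <- states[tree$tip.label, , drop = FALSE]
  cp <- compress_patterns(states)
  fitch_length_states(tree, cp$states, cp$weights)
}

fitch_length_states <- function(tree, states, weights) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  full <- bitwShiftL(1L, length(AA_ALPHABET)) - 1L
  node_states <- matrix(full, ntip + nnode, ncol(states))
  node_states[seq_len(ntip), ] <- states
  seen <- logical(ntip + nnode)
  seen[seq_len(ntip)] <- TRUE
  len <- 0
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (!seen[p]) {
      node_states[p, ] <- node_states[ch, ]
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(node_states[p, ], node_states[ch, ])
      zero <- inter == 0L
      len <- len + sum(weights[zero])
      inter[zero] <- bitwOr(node_states[p, zero],
                            node_states[ch, zero])
      node_states[p, ] <- inter
    }
  }
  len
}

# Convert the 1-based undirected edge list from the compiled search
# (tips 1..n, internals n+1..2n-2) into an ape phylo rooted at the
# internal node adjacent to tip 1 (a trifurcation).
edges_to_phylo <- function(edges, tip_labels) {
  n <- length(tip_labels)
  nb <- vector("list", 2 * n - 2)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    nb[[u]] <- c(nb[[u]], v)
    nb[[v]] <- c(nb[[v]], u)
  }
  root_old <- nb[[1]][1]
  newid <- integer(2 * n - 2)
  newid[seq_len(n)] <- seq_len(n)
  nxt <- n + 1L
  parent <- integer(2 * n - 2)
  stack <- root_old
  parent[root_old] <- 0L
  order <- integer(0)
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    order <- c(order, u)
    newid[u] <- nxt; nxt <- nxt + 1L
    for (v in nb[[u]]) if (v != parent[u] && v > n) {
      parent[v] <- u
      stack <- c(stack, v)
    }
  }
  edge <- matrix(0L, 0, 2)
  for (u in order)
    for (v in nb[[u]])
      if (v != parent[u])
        edge <- rbind(edge, c(newid[u], if (v > n) newid[v] else v))
  structure(list(edge = edge, tip.label = tip_labels,
                 Nnode = n - 2L),
            class = "phylo")
}

# Non-trivial splits of a tree as canonical keys: the tip-label set of
# the side not containing the first tip label, sorted, pasted with "|".
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  tree <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (anchor %in% side)
      side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Maximum-parsimony tree search
#'
#' For each replicate a starting tree is built by random stepwise
#' addition (each taxon inserted at its best position) and then improved
#' by first-improvement SPR hill climbing until no rearrangement shortens
#' the tree. The shortest distinct topologies over all replicates are
#' returned. Deterministic given the seed.
#'
#' @param aln a `masked_alignment`.
#' @param random_addition_reps number of random-addition replicates.
#' @param seed integer seed.
#' @return list with `trees` (equally shortest distinct `phylo` trees),
#'   `length` (their parsimony length) and `lengths` (per replicate).
#' @export
mp_search <- function(aln, random_addition_reps = 10L, seed = 1L) {
  states <- state_masks(aln)
  labels <- rownames(states)
  ntaxa <- length(labels)
  if (ntaxa < 3) stop("need at least 3 taxa")
  if (ntaxa == 3) {
    tree <- structure(list(edge = cbind(4L, 1:3), tip.label = labels,
                           Nnode = 1L), class = "phylo")
    cp <- compress_patterns(states)
    return(list(trees = list(tree),
                length = fitch_length_states(tree, cp$states,
                                             cp$weights),
                lengths = NA_real_))
  }
  cp <- compress_patterns(states)
  res <- with_seed(seed,
                   .mp_search_cpp(cp$states, cp$weights,
                                  as.integer(random_addition_reps),
                                  as.integer(200 + 20 * ntaxa)))
  lens <- res$lengths
  best <- min(lens)
  trees <- lapply(which(lens <= best + 1e-9), function(i)
    edges_to_phylo(res$edges[[i]], labels))
  keys <- vapply(trees, function(t)
    paste(sort(tree_splits(t)), collapse = ";"), character(1))
  trees <- trees[!duplicated(keys)]
  list(trees = trees, length = best, lengths = lens)
}

# Strict consensus splits across a list of trees.
consensus_splits <- function(trees) {
  splits <- lapply(trees, tree_splits)
  Reduce(intersect, splits)
}

# Build a (possibly multifurcating) rooted phylo from nested canonical
# splits; supports become node labels. Splits are clades of the rooting
# at the anchor (first tip alphabetically), which they are by
# construction of the canonical keys.
tree_from_splits <- function(tip_labels, splits, supports = NULL) {
  sets <- lapply(splits, function(s) strsplit(s, "|", fixed = TRUE)[[1]])
  ord <- order(-lengths(sets))
  sets <- sets[ord]
  supports <- if (!is.null(supports)) supports[ord]
  n <- length(tip_labels)
  nnode <- length(sets) + 1L
  parent_of_tip <- rep(1L, n)          # internal index (1 = root)
  parent_of_node <- rep(NA_integer_, nnode)
  names(parent_of_tip) <- tip_labels
  for (k in seq_along(sets)) {
    node <- k + 1L
    members <- sets[[k]]
    # parent = current common parent of members (smallest enclosing)
    parent_of_node[node] <- parent_of_tip[members[1]]
    parent_of_tip[members] <- node
  }
  edge <- matrix(0L, 0, 2)
  for (k in seq_along(sets))
    edge <- rbind(edge, c(parent_of_node[k + 1L] + n, k + 1L + n))
  for (t in seq_len(n))
    edge <- rbind(edge, c(parent_of_tip[t] + n, t))
  node_label <- c("", if (length(sets))
    formatC(supports %||% rep(NA_real_, length(sets)), format = "g"))
  structure(list(edge = edge, tip.label = tip_labels,
                 Nnode = nnode, node.label = node_label),
            class = "phylo")
}

#' Bootstrap supports and collapsed consensus tree
#'
#' Columns of the masked alignment are resampled with replacement; each
#' replicate is re-searched (with a reduced number of random-addition
#' starts) and the support of a split is the percentage of replicates
#' whose best tree contains it. Splits of the strict consensus of the
#' equally most-parsimonious trees with support below `collapse_below`
#' are collapsed to polytomies.
#'
#' @param aln a `masked_alignment`.
#' @param reps bootstrap replicates (default 500).
#' @param collapse_below support threshold in `[0, 1]` (default 0.30).
#' @param seed integer seed.
#' @param search_reps random-addition replicates for the initial search.
#' @param boot_reps random-addition replicates within each bootstrap
#'   replicate (default 2).
#' @return an `mcra_tree`: list with `tree` (collapsed consensus phylo,
#'   node labels = supports in percent), `splits`, `supports` (percent,
#'   aligned with `splits`), `length` (parsimony length of the best
#'   trees) and `n_trees` (number of tied topologies).
#' @export
bootstrap_support <- function(aln, reps = 500L, collapse_below = 0.30,
                              seed = 1L, search_reps = 10L,
                              boot_reps = 2L) {
  states <- state_masks(aln)
  labels <- rownames(states)
  search <- mp_search(aln, search_reps, seed = derive_seed(seed, "mp"))
  base_splits <- consensus_splits(search$trees)
  tally <- setNames(numeric(length(base_splits)), base_splits)
  nsite <- ncol(states)
  with_seed(derive_seed(seed, "bootstrap"), {
    for (r in seq_len(reps)) {
      idx <- sample.int(nsite, nsite, replace = TRUE)
      bs <- states[, idx, drop = FALSE]
      cp <- compress_patterns(bs)
      res <- .mp_search_cpp(cp$states, cp$weights,
                            as.integer(boot_reps),
                            as.integer(200 + 20 * length(labels)))
      btree <- edges_to_phylo(res$edges[[which.min(res$lengths)]],
                              labels)
      hit <- base_splits %in% tree_splits(btree)
      tally[hit] <- tally[hit] + 1
    }
  })
  supports <- 100 * tally / reps
  keep <- supports / 100 >= collapse_below
  tree <- tree_from_splits(sort(labels), base_splits[keep],
                           supports[keep])
  structure(list(tree = tree, splits = base_splits[keep],
                 supports = supports[keep],
                 all_splits = base_splits, all_supports = supports,
                 length = search$length,
                 n_trees = length(search$trees)),
            class = "mcra_tree")
}

#' @export
print.mcra_tree <- function(x, ...) {
  cat("maximum-parsimony placement: length", x$length, "(",
      x$n_trees, "tied trees ),", length(x$splits),
      "splits retained after collapse\n")
  invisible(x)
}

#' Write the collapsed tree with supports as Newick
#' @param x an `mcra_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(x, path) {
  ape::write.tree(x$tree, path)
  invisible(path)
}
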