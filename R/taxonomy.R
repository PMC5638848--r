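# Clade/genus/family assignment of cluster centroids from the collapsed
# parsimony tree: each cluster takes the labels shared by all reference
# panel members of the smallest surviving clade that contains it together
# with at least one panel leaf.

#' Assign taxonomy to cluster leaves from a support-collapsed tree
#'
#' For every cluster leaf the smallest split side (over all surviving
#' splits of the collapsed tree, plus the full leaf set as fallback)
#' containing the cluster and at least one panel leaf is located; the
#' cluster inherits each taxonomy level on which all panel members of
#' that side agree, and is "unassigned" (NA) at levels where they
#' disagree. Deterministic and total over the supplied clusters.
#'
#' @param tree_obj an `mcra_tree` from [bootstrap_support()].
#' @param taxonomy panel taxonomy data frame (id, family, genus, clade).
#' @param cluster_ids leaf names to assign.
#' @return data frame: cluster, family, genus, clade, support (percent
#'   support of the defining branch; NA when the fallback whole-tree set
#'   was used).
#' @export
assign_taxonomy <- function(tree_obj, taxonomy, cluster_ids) {
  tips <- tree_obj$tree$tip.label
  panel_ids <- intersect(taxonomy$id, tips)
  if (!length(panel_ids))
    stop("tree contains no panel leaves")
  sides <- list()
  side_support <- numeric(0)
  for (i in seq_along(tree_obj$splits)) {
    s <- strsplit(tree_obj$splits[i], "|", fixed = TRUE)[[1]]
    sides[[length(sides) + 1L]] <- s
    side_support <- c(side_support, tree_obj$supports[i])
    sides[[length(sides) + 1L]] <- setdiff(tips, s)
    side_support <- c(side_support, tree_obj$supports[i])
  }
  sides[[length(sides) + 1L]] <- tips
  side_support <- c(side_support, NA_real_)
  out <- lapply(cluster_ids, function(cl) {
    if (!cl %in% tips) stop("cluster ", cl, " is not a tree leaf")
    ok <- vapply(sides, function(s)
      cl %in% s && any(panel_ids %in% s), logical(1))
    cand <- which(ok)
    sizes <- lengths(sides[cand])
    keys <- vapply(sides[cand], function(s)
      paste(sort(s), collapse = "|"), character(1))
    pick <- cand[order(sizes, keys)][1]
    members <- intersect(panel_ids, sides[[pick]])
    tx <- taxonomy[match(members, taxonomy$id), , drop = FALSE]
    lvl <- function(v) if (length(unique(v)) == 1) v[1] else NA_character_
    data.frame(cluster = cl, family = lvl(tx$family),
               genus = lvl(tx$genus), clade = lvl(tx$clade),
               support = unname(side_support[pick]))
  })
  do.call(rbind, out)
}
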