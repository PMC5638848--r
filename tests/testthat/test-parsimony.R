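aln_from_rows <- function(...) {
  rows <- c(...)
  structure(list(rows = rows, kept = seq_len(nchar(rows[[1]])),
                 n_positions = nchar(rows[[1]])),
            class = "masked_alignment")
}

test_that("Fitch length matches hand-computed cases", {
  # 3 taxa, single column {A, A, C} -> 1 change
  aln <- aln_from_rows(t1 = "A", t2 = "A", t3 = "C")
  star <- structure(list(edge = cbind(4L, 1:3),
                         tip.label = c("t1", "t2", "t3"), Nnode = 1L),
                    class = "phylo")
  expect_equal(fitch_length(star, aln), 1)
  # 4 taxa {A,A,C,C}: grouping matters
  aln4 <- aln_from_rows(t1 = "A", t2 = "A", t3 = "C", t4 = "C")
  good <- ape::read.tree(text = "((t1,t2),(t3,t4));")
  bad <- ape::read.tree(text = "((t1,t3),(t2,t4));")
  expect_equal(fitch_length(good, aln4), 1)
  expect_equal(fitch_length(bad, aln4), 2)
  # an invariant column costs nothing on any topology
  alni <- aln_from_rows(t1 = "AA", t2 = "AA", t3 = "AC", t4 = "AC")
  expect_equal(fitch_length(good, alni), 1)
  expect_equal(fitch_length(bad, alni), 2)
  # gaps are missing data
  alng <- aln_from_rows(t1 = "A", t2 = "-", t3 = "C", t4 = "C")
  expect_equal(fitch_length(good, alng), 1)
})

test_that("Fitch length is invariant under rerooting", {
  aln <- random_alignment(6, 30, seed = 61)
  tr <- ape::rtree(6, tip.label = names(aln$rows))
  tr$edge.length <- NULL
  l0 <- fitch_length(ape::unroot(tr), aln)
  for (og in c("t2", "t4")) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(fitch_length(rr, aln), l0)
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  skip_if_not_installed("phangorn")
  for (seed in 1:5) {
    aln <- random_alignment(7, 40, seed = seed)
    tr <- ape::unroot(ape::rtree(7, tip.label = names(aln$rows)))
    tr$edge.length <- NULL
    m <- alignment_matrix(aln)
    pd <- phangorn::phyDat(m, type = "AA")
    expect_equal(fitch_length(tr, aln),
                 as.numeric(phangorn::parsimony(tr, pd)))
  }
})

test_that("SPR search attains the exhaustive optimum on small instances", {
  for (spec in list(c(5, 20), c(6, 25), c(7, 30))) {
    n <- spec[1]
    aln <- random_alignment(n, spec[2], seed = n * 7)
    res <- mp_search(aln, random_addition_reps = 5, seed = 99)
    topos <- all_topologies(names(aln$rows))
    lens <- vapply(topos, fitch_length, numeric(1), aln = aln)
    expect_equal(res$length, min(lens))
  }
})

test_that("search recovers a strongly supported generating topology", {
  # two 4-taxon groups separated by 30 fixed differences
  blockA <- paste(rep("A", 30), collapse = "")
  blockC <- paste(rep("C", 30), collapse = "")
  noise <- function(seed) {
    set.seed(seed)
    paste(sample(c("D", "E"), 10, TRUE), collapse = "")
  }
  rows <- c(a1 = paste0(blockA, noise(1)), a2 = paste0(blockA, noise(2)),
            a3 = paste0(blockA, noise(3)), a4 = paste0(blockA, noise(4)),
            b1 = paste0(blockC, noise(5)), b2 = paste0(blockC, noise(6)),
            b3 = paste0(blockC, noise(7)), b4 = paste0(blockC, noise(8)))
  aln <- structure(list(rows = rows, kept = 1:40, n_positions = 40),
                   class = "masked_alignment")
  bs <- bootstrap_support(aln, reps = 100, collapse_below = 0.30,
                          seed = 5, search_reps = 3)
  central <- paste(sort(c("b1", "b2", "b3", "b4")), collapse = "|")
  expect_true(central %in% bs$splits ||
                paste(sort(c("a1", "a2", "a3", "a4")),
                      collapse = "|") %in% bs$splits)
  idx <- match(central, bs$all_splits)
  if (!is.na(idx)) expect_gte(bs$all_supports[idx], 99)
})

test_that("supports lie in [0, 100] and collapsed splits nest in the originals", {
  aln <- random_alignment(6, 40, seed = 71)
  bs <- bootstrap_support(aln, reps = 50, seed = 6, search_reps = 3)
  expect_true(all(bs$all_supports >= 0 & bs$all_supports <= 100))
  expect_true(all(bs$splits %in% bs$all_splits))
  expect_true(all(bs$supports >= 30))
})

test_that("an invariant alignment collapses completely", {
  rows <- setNames(rep(strrep("A", 20), 5), paste0("t", 1:5))
  aln <- structure(list(rows = rows, kept = 1:20, n_positions = 20),
                   class = "masked_alignment")
  res <- mp_search(aln, random_addition_reps = 2, seed = 3)
  expect_equal(res$length, 0)
  bs <- bootstrap_support(aln, reps = 20, seed = 3, search_reps = 2)
  expect_length(bs$splits, 0)
})

test_that("tree search is deterministic given the seed", {
  aln <- random_alignment(8, 30, seed = 81)
  r1 <- mp_search(aln, random_addition_reps = 4, seed = 11)
  r2 <- mp_search(aln, random_addition_reps = 4, seed = 11)
  expect_equal(r1$length, r2$length)
  expect_identical(lapply(r1$trees, tree_key <- function(t)
    paste(sort(mcrapipe:::tree_splits(t)), collapse = ";")),
    lapply(r2$trees, tree_key))
})
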