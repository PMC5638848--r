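rand_pep <- function(n, seed) {
  set.seed(seed)
  paste(sample(mcrapipe:::AA_ALPHABET, n, TRUE), collapse = "")
}

mutate_pep <- function(pep, sites) {
  ch <- strsplit(pep, "")[[1]]
  for (s in sites) ch[s] <- setdiff(mcrapipe:::AA_ALPHABET, ch[s])[1]
  paste(ch, collapse = "")
}

test_that("pairwise identity matches direct counts", {
  a <- rand_pep(157, 1)
  expect_equal(pairwise_identity(a, a), 1.0)
  b <- mutate_pep(a, c(3, 40, 77, 101, 150))
  expect_equal(pairwise_identity(a, b), 152 / 157)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # identity to own prefix is 1 under terminal-gap exclusion
  expect_equal(pairwise_identity(a, substr(a, 1, 150)), 1.0)
  expect_error(pairwise_identity("", a), "non-empty")
})

test_that("greedy clustering assigns by abundance-ordered centroids", {
  p1 <- rand_pep(157, 2)
  p2 <- mutate_pep(p1, 1:3)        # 0.981 to p1
  p3 <- mutate_pep(p1, seq(1, 150, by = 10)) # far from both
  cl <- greedy_cluster(c(p1, p2, p3), c(100, 50, 1), 0.97)
  expect_equal(max(cl$cluster), 2)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_false(cl$cluster[3] == cl$cluster[1])
  expect_identical(attr(cl, "centroids")[1], p1)
  # all-identical input collapses to one cluster
  cl2 <- greedy_cluster(rep(p1, 3), c(3, 2, 1), 0.97)
  expect_equal(max(cl2$cluster), 1)
  # threshold 1.0 on distinct sequences gives singletons
  cl3 <- greedy_cluster(c(p1, p2, p3), c(3, 2, 1), 1.0)
  expect_equal(max(cl3$cluster), 3)
})

test_that("members always reach the identity threshold to their centroid", {
  set.seed(3)
  peps <- unique(vapply(1:20, function(i) {
    base <- rand_pep(157, i %% 4 + 10)
    mutate_pep(base, sample(157, sample(0:4, 1)))
  }, character(1)))
  ab <- seq_along(peps)
  cl <- greedy_cluster(peps, ab, 0.97)
  cents <- attr(cl, "centroids")
  for (i in seq_along(peps))
    expect_gte(pairwise_identity(peps[i], cents[cl$cluster[i]]), 0.97)
})

test_that("equal-abundance input order does not change the centroid set", {
  p1 <- rand_pep(157, 5)
  p2 <- mutate_pep(p1, 1:10)
  p3 <- mutate_pep(p2, 20:30)
  peps <- c(p1, p2, p3)
  ab <- c(5, 5, 5)
  cents <- lapply(list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1)), function(o)
    sort(attr(greedy_cluster(peps[o], ab[o], 0.97), "centroids")))
  expect_identical(cents[[1]], cents[[2]])
  expect_identical(cents[[1]], cents[[3]])
})

test_that("greedy matches the exhaustive minimum-cluster oracle", {
  # instances with well-separated tight groups, <= 8 sequences
  for (seed in 1:4) {
    set.seed(seed)
    roots <- vapply(1:3, function(i) rand_pep(60, seed * 10 + i),
                    character(1))
    peps <- unique(unlist(lapply(roots, function(r)
      c(r, mutate_pep(r, 1)))))
    n <- length(peps)
    ab <- rev(seq_len(n))
    valid_block <- function(idx)
      any(vapply(idx, function(c0) all(vapply(idx, function(j)
        pairwise_identity(peps[j], peps[c0]) >= 0.97, logical(1))),
        logical(1)))
    parts <- all_partitions(n)
    sizes <- vapply(parts, function(bl)
      if (all(vapply(bl, valid_block, logical(1)))) length(bl)
      else NA_integer_, integer(1))
    kmin <- min(sizes, na.rm = TRUE)
    best <- parts[which(sizes == kmin)]
    cl <- greedy_cluster(peps, ab, 0.97)
    expect_equal(max(cl$cluster), kmin)
    # when the optimal clustering is unique, greedy reproduces it
    if (length(best) == 1) {
      canon <- function(blocks) sort(unname(vapply(blocks, function(b)
        paste(sort(b), collapse = ","), character(1))))
      expect_identical(canon(split(seq_len(n), cl$cluster)),
                       canon(best[[1]]))
    }
  }
})

test_that("the abundance floor is inclusive and reports retained fraction", {
  totals <- setNames(c(9965, 10, 9, 16), paste0("C", 1:4))
  res <- apply_min_fraction(totals, 0.001)
  expect_true("C2" %in% res$retained)   # exactly 0.1%: retained
  expect_true("C3" %in% res$discarded)  # 9 of 10000: discarded
  expect_equal(res$retained_fraction, (10000 - 9) / 10000)
  expect_error(apply_min_fraction(c(a = 0)), "zero")
})

test_that("count matrix conserves counts and computes relative abundance", {
  p1 <- rand_pep(157, 7); p2 <- mutate_pep(p1, 1:10)
  cl <- greedy_cluster(c(p1, p2), c(3, 1), 0.97)
  counts <- matrix(c(3L, 1L, 0L, 0L), 2, 2,
                   dimnames = list(NULL, c("s1", "s2")))
  cm <- build_count_matrix(cl, counts)
  expect_equal(sum(cm$counts), 4)
  expect_equal(unname(cm$relative["s1", ]), c(75, 25))
  # empty sample flagged
  expect_identical(attr(cm$relative, "empty_samples"), "s2")
})
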