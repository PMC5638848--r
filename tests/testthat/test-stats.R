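test_that("taxonomic aggregation preserves row sums exactly", {
  tab <- reference_profiles()
  rel <- t(as.matrix(tab[, c("R", "A", "RA", "AA")]))
  colnames(rel) <- tab$cluster
  tax <- data.frame(cluster = tab$cluster, family = tab$family,
                    genus = tab$genus, clade = tab$clade)
  fam <- aggregate_taxa(rel, tax, "family")
  expect_equal(rowSums(fam), rowSums(rel))
  gen <- aggregate_taxa(rel, tax, "genus")
  expect_equal(rowSums(gen), rowSums(rel))
  # single-cluster taxonomy: aggregation is the identity
  one <- rel[, 1, drop = FALSE]
  expect_equal(unname(aggregate_taxa(one, tax, "family")[, 1]),
               unname(one[, 1]))
  # unassigned clusters pool into "unassigned"
  tax2 <- tax; tax2$clade[1:3] <- NA
  cl <- aggregate_taxa(rel, tax2, "clade")
  expect_true("unassigned" %in% colnames(cl))
  expect_error(aggregate_taxa(rel, tax, "species"))
})

test_that("alpha diversity matches closed forms", {
  d1 <- alpha_diversity(c(10, 0, 0))
  expect_equal(d1$S, 1)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$simpson, 0)
  d2 <- alpha_diversity(rep(5, 4))
  expect_equal(d2$shannon, log(4))
  expect_equal(d2$simpson, 0.75)
  d3 <- alpha_diversity(c(96, 1, 1, 1, 1))
  expect_equal(d3$margalef, 4 / log(100))
  expect_true(is.na(alpha_diversity(c(1, 0))$margalef))
  expect_error(alpha_diversity(c(-1, 2)), "nonnegative")
})

test_that("diversity formulas match an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(10)
  for (i in 1:20) {
    x <- rpois(25, 30)
    d <- alpha_diversity(x)
    expect_equal(d$shannon, unname(vegan::diversity(x, "shannon")),
                 tolerance = 1e-12)
    expect_equal(d$simpson, unname(vegan::diversity(x, "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("Bray-Curtis on sqrt abundances matches hand computation", {
  m <- rbind(s1 = c(4, 1), s2 = c(1, 4))
  d <- braycurtis_matrix(m)
  expect_equal(d["s1", "s2"], 1 / 3)
  expect_equal(diag(d), c(s1 = 0, s2 = 0))
  # identical samples -> 0; disjoint supports -> 1
  m2 <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 7))
  d2 <- braycurtis_matrix(m2)
  expect_equal(d2["a", "b"], 0)
  expect_equal(d2["a", "c"], 1)
  expect_error(braycurtis_matrix(rbind(a = c(0, 0), b = c(0, 0))),
               "all-zero")
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # collinear points 0, 1, 2
  d <- as.matrix(dist(matrix(c(0, 1, 2), 3, 1)))
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  res <- pcoa(d)
  ax1 <- res$coordinates[, 1]
  expect_equal(unname(abs(diff(sort(ax1)))), c(1, 1))
  expect_lt(abs(res$eigenvalues[2]), 1e-9)
  # general Euclidean input: distances reproduced
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  dd <- as.matrix(dist(X))
  r2 <- pcoa(dd)
  expect_equal(as.matrix(dist(r2$coordinates)), unname(dd),
               tolerance = 1e-9, ignore_attr = TRUE)
  # identical points: all eigenvalues 0
  d0 <- matrix(0, 3, 3)
  expect_true(all(abs(pcoa(d0)$eigenvalues) < 1e-12))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PCoA of Euclidean distances equals PCA scores up to sign", {
  set.seed(12)
  X <- matrix(rnorm(40), 10, 4)
  d <- as.matrix(dist(X))
  res <- pcoa(d)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  k <- 3
  for (j in seq_len(k)) {
    cors <- abs(cor(res$coordinates[, j], pc$x[, j]))
    expect_equal(cors, 1, tolerance = 1e-6)
  }
})

test_that("nMDS reaches near-zero stress on embeddable data and never
          increases stress within a start", {
  set.seed(13)
  X <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(X))
  rownames(d) <- colnames(d) <- paste0("s", 1:8)
  res <- nmds(d, k = 2, n_restarts = 5, seed = 14)
  expect_lt(res$stress, 0.01)
  expect_true(all(diff(res$trace) <= 1e-8))
  # two points embed exactly
  d2 <- matrix(c(0, 3, 3, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(nmds(d2, k = 1)$stress, 0)
  expect_error(nmds(d, k = 7), "dimension")
})

test_that("UPGMA reproduces ultrametric heights and pairs tight groups", {
  # ultrametric input
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  hc <- upgma_dendrogram(d)
  expect_equal(sort(hc$height), c(2, 4, 8))
  expect_true(all(diff(hc$height) >= 0))
  ch <- as.matrix(cophenetic(hc))[letters[1:4], letters[1:4]]
  expect_equal(ch, d)
  # n = 2: single merge at the dissimilarity
  d2 <- matrix(c(0, 5, 5, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma_dendrogram(d2)$height, 5)
})

test_that("heatmap export preserves sqrt values and dendrogram order", {
  set.seed(15)
  m <- matrix(runif(24, 0, 50), 4, 6,
              dimnames = list(paste0("s", 1:4), paste0("C", 1:6)))
  m <- 100 * m / rowSums(m)
  hm <- heatmap_export(m)
  expect_equal(sort(as.vector(hm$grid)), sort(as.vector(sqrt(m))))
  expect_identical(hm$row_order,
                   rownames(m)[upgma_dendrogram(
                     braycurtis_matrix(m))$order])
  # zero column stays zero
  m2 <- cbind(m, Z = 0)
  expect_true(all(heatmap_export(m2)$grid[, "Z"] == 0))
})

test_that("Kruskal-Wallis + BH matches the step-up oracle", {
  groups <- factor(rep(c("R", "A"), each = 4))
  m <- matrix(1, 8, 2, dimnames = list(NULL, c("C1", "C2")))
  res <- kruskal_bh(m, groups)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p, c(1, 1))
  # BH step-up hand oracle: p = (.01,.02,.03,.04), m = 4 -> all .04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_error(kruskal_bh(m, factor(c("R", rep("A", 7)))), ">= 2")
})

test_that("BH keeps the false-discovery fraction controlled under the null", {
  set.seed(16)
  reps <- 300
  hits <- numeric(reps)
  groups <- factor(rep(c("R", "A", "RA", "AA"), each = 6))
  for (r in seq_len(reps)) {
    m <- matrix(rnorm(24 * 10), 24, 10,
                dimnames = list(NULL, paste0("C", 1:10)))
    res <- kruskal_bh(m, groups)
    hits[r] <- any(res$p_adj < 0.05)
  }
  # family-wise error under the global null is at most ~alpha
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lte(mean(hits), 0.05 + 3 * se)
})

test_that("pairwise Wilcoxon letters separate a shifted group", {
  set.seed(17)
  groups <- factor(rep(c("R", "A", "RA", "AA"), each = 13))
  base <- rnorm(52)
  m <- cbind(C1 = base + ifelse(groups == "R", 10, 0),
             C2 = rnorm(52))
  rownames(m) <- paste0("s", 1:52)
  res <- pairwise_wilcoxon_bh(m, groups)
  lt <- res$letters
  expect_false(lt["C1", "R"] %in% lt["C1", c("A", "RA", "AA")])
  expect_true(all(lt["C2", ] == lt["C2", 1]))
  expect_true(all(res$tests$p_adj >= res$tests$p))
  # adjusted p monotone in raw p
  ord <- order(res$tests$p)
  expect_true(all(diff(res$tests$p_adj[ord]) >= -1e-12))
})

test_that("ANOVA reduces to the pooled t-test with two groups", {
  set.seed(18)
  y <- c(rnorm(8), rnorm(8) + 1)
  g <- factor(rep(c("a", "b"), each = 8))
  div <- data.frame(sample = paste0("s", 1:16), S = y)
  res <- anova_tukey(div, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$anova$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$anova$F, unname(tt$statistic)^2, tolerance = 1e-12)
})

test_that("Tukey letters mark the separated group and adjust upward", {
  g <- factor(rep(c("a", "b", "c"), each = 3))
  div <- data.frame(sample = paste0("s", 1:9),
                    S = c(1, 2, 3, 1, 2, 3, 11, 12, 13))
  res <- anova_tukey(div, g)
  lt <- res$letters["S", ]
  expect_false(lt[["c"]] %in% c(lt[["a"]], lt[["b"]]))
  expect_identical(lt[["a"]], lt[["b"]])
  # Tukey adjusted p >= raw pairwise t-test p
  raw <- t.test(div$S[g == "a"], div$S[g == "b"],
                var.equal = TRUE)$p.value
  pab <- res$tukey$p_adj[res$tukey$pair == "b-a"]
  expect_gte(pab + 1e-12, raw)
})
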