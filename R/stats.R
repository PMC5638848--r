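# Community statistics over the sample x cluster abundance matrix:
# taxonomic aggregation, alpha diversity, square-root Bray-Curtis
# dissimilarity, ordination (PCoA, nMDS), UPGMA dendrogram, heatmap
# export, and the hypothesis-testing layer (Kruskal-Wallis + BH,
# pairwise Wilcoxon + BH with compact letter display, one-way ANOVA +
# Tukey HSD).

#' Aggregate cluster abundances to a taxonomic rank
#'
#' @param rel samples x clusters relative-abundance matrix (% rows sum
#'   to 100).
#' @param taxonomy data frame with columns cluster, family, genus, clade
#'   (NA = unassigned).
#' @param rank one of "family", "genus", "clade".
#' @return samples x taxa matrix; row sums are preserved exactly;
#'   unassigned clusters pool into "unassigned".
#' @export
aggregate_taxa <- function(rel, taxonomy, rank = c("family", "genus",
                                                   "clade")) {
  rank <- match.arg(rank)
  lab <- taxonomy[[rank]][match(colnames(rel), taxonomy$cluster)]
  lab[is.na(lab)] <- "unassigned"
  taxa <- unique(lab)
  out <- sapply(taxa, function(tx)
    rowSums(rel[, lab == tx, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(rel),
                                       dimnames = list(rownames(rel),
                                                       taxa))
  out
}

#' Alpha diversity of one count vector
#'
#' Observed clusters S, Margalef richness `(S - 1)/ln N`, Shannon
#' `H' = -sum p_i ln p_i` (natural log) and Simpson `1 - sum p_i^2`.
#'
#' @param counts nonnegative counts for one sample.
#' @return data frame with S, margalef, shannon, simpson (margalef is NA
#'   when N <= 1).
#' @export
alpha_diversity <- function(counts) {
  if (any(counts < 0)) stop("counts must be nonnegative")
  N <- sum(counts)
  S <- sum(counts > 0)
  p <- counts[counts > 0] / N
  data.frame(S = S,
             margalef = if (N > 1) (S - 1) / log(N) else NA_real_,
             shannon = if (N > 0) -sum(p * log(p)) else 0,
             simpson = if (N > 0) 1 - sum(p^2) else 0)
}

#' Alpha diversity table for a count matrix
#' @param counts samples x clusters count matrix.
#' @return data frame, one row per sample.
#' @export
diversity_table <- function(counts) {
  rows <- lapply(rownames(counts), function(s)
    cbind(data.frame(sample = s), alpha_diversity(counts[s, ])))
  do.call(rbind, rows)
}

#' Bray-Curtis dissimilarity on square-root transformed abundances
#'
#' `BC(x, y) = sum |sqrt(x) - sqrt(y)| / sum (sqrt(x) + sqrt(y))`.
#'
#' @param rel samples x clusters relative abundance matrix.
#' @param transform "sqrt" (default) or "none".
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
braycurtis_matrix <- function(rel, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  if (any(rel < 0)) stop("abundances must be nonnegative")
  zero <- rownames(rel)[rowSums(rel) == 0]
  if (length(zero) > 1)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(zero, collapse = ", "))
  x <- if (transform == "sqrt") sqrt(rel) else rel
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  dimnames(d) <- list(rownames(rel), rownames(rel))
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Eigendecomposition of the double-centred squared dissimilarity
#' matrix. Negative eigenvalues are reported, not dropped; coordinates
#' are returned for axes with positive eigenvalues, ordered by
#' eigenvalue.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return list with `coordinates` (samples x axes) and `eigenvalues`
#'   (all n values).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > 1e-9 * max(abs(e$values), 1e-300))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  rownames(coords) <- rownames(d)
  if (length(pos))
    colnames(coords) <- paste0("PCo", seq_along(pos))
  list(coordinates = coords, eigenvalues = e$values)
}

# Kruskal stress-1 for a configuration given target disparities.
stress1 <- function(dconf, dhat) {
  sqrt(sum((dconf - dhat)^2) / sum(dconf^2))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimised by iterative majorisation (Guttman
#' transform) alternated with monotone regression of configuration
#' distances on the rank order of the dissimilarities; the best of
#' `n_restarts` random starts is returned. Stress is non-increasing over
#' iterations within a start.
#'
#' @param d symmetric dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts.
#' @param maxit majorisation iterations per start.
#' @param tol convergence tolerance on stress.
#' @param seed integer seed.
#' @return list with `coordinates`, `stress`, and `trace` (stress per
#'   iteration of the winning start).
#' @export
nmds <- function(d, k = 2L, n_restarts = 50L, maxit = 500L,
                 tol = 1e-6, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n == 2) {
    co <- matrix(c(0, d[1, 2], rep(0, 2 * (k - 1))), 2, k)
    rownames(co) <- rownames(d)
    return(list(coordinates = co, stress = 0, trace = 0))
  }
  if (k >= n - 1) stop("embedding dimension too large: k must be < n - 1")
  ut <- upper.tri(d)
  delta <- d[ut]
  ord <- order(delta)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      X <- matrix(runif(n * k, -1, 1), n, k)
      if (r == 1) {
        # one deterministic metric start via classical scaling
        pc <- tryCatch(pcoa(d)$coordinates, error = function(e) NULL)
        if (!is.null(pc) && ncol(pc) >= 1) {
          kk <- min(k, ncol(pc))
          X[, seq_len(kk)] <- pc[, seq_len(kk)]
        }
      }
      trace <- numeric(0)
      prev <- Inf
      for (it in seq_len(maxit)) {
        dc <- as.matrix(dist(X))[ut]
        ir <- isoreg(seq_along(ord), dc[ord])
        dhat <- numeric(length(dc))
        dhat[ord] <- ir$yf
        # scale disparities to the configuration (Kruskal's convention)
        s <- stress1(dc, dhat)
        trace <- c(trace, s)
        if (prev - s < tol) break
        prev <- s
        # Guttman transform
        Dhat <- matrix(0, n, n)
        Dhat[ut] <- dhat
        Dhat <- Dhat + t(Dhat)
        Dc <- as.matrix(dist(X))
        ratio <- ifelse(Dc > 1e-12, Dhat / Dc, 0)
        Bm <- -ratio
        diag(Bm) <- -rowSums(Bm)
        X <- Bm %*% X / n
      }
      s <- trace[length(trace)]
      if (is.null(best) || s < best$stress)
        best <- list(coordinates = X, stress = s, trace = trace)
    }
  })
  rownames(best$coordinates) <- rownames(d)
  colnames(best$coordinates) <- paste0("MDS", seq_len(k))
  best
}

#' UPGMA dendrogram of samples
#'
#' Group-average agglomeration; merge heights are non-decreasing.
#'
#' @param d symmetric dissimilarity matrix.
#' @return an `hclust` object.
#' @export
upgma_dendrogram <- function(d) {
  hclust(as.dist(d), method = "average")
}

#' Export a square-root transformed, dendrogram-ordered heatmap grid
#'
#' @param rel samples x clusters relative abundance matrix.
#' @param transform "sqrt" (default) or "none".
#' @return list with `grid` (transformed values, rows/columns reordered
#'   by UPGMA dendrograms of samples and clusters), `row_order`,
#'   `col_order`.
#' @export
heatmap_export <- function(rel, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  g <- if (transform == "sqrt") sqrt(rel) else rel
  rord <- if (nrow(g) > 2)
    upgma_dendrogram(braycurtis_matrix(rel))$order else seq_len(nrow(g))
  cord <- if (ncol(g) > 2)
    upgma_dendrogram(as.matrix(dist(t(g))))$order else seq_len(ncol(g))
  list(grid = g[rord, cord, drop = FALSE],
       row_order = rownames(g)[rord],
       col_order = colnames(g)[cord])
}

#' Kruskal-Wallis tests per cluster with BH correction
#'
#' @param rel samples x clusters abundance matrix.
#' @param groups factor of treatment labels per sample.
#' @return data frame: cluster, statistic, p, p_adj (BH across
#'   clusters).
#' @export
kruskal_bh <- function(rel, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  res <- lapply(colnames(rel), function(cl) {
    x <- rel[, cl]
    if (var(x) == 0)
      return(data.frame(cluster = cl, statistic = 0, p = 1))
    kt <- kruskal.test(x, groups)
    data.frame(cluster = cl, statistic = unname(kt$statistic),
               p = kt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

# Compact letter display: groups sharing a letter are not significantly
# different. Letters label the maximal cliques of the
# "not-significantly-different" graph, ordered by group means.
letter_display <- function(levels_ord, sig_pairs) {
  k <- length(levels_ord)
  adj <- matrix(TRUE, k, k, dimnames = list(levels_ord, levels_ord))
  for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs[i, 1]; b <- sig_pairs[i, 2]
    adj[a, b] <- adj[b, a] <- FALSE
  }
  # maximal cliques by brute force over subsets (k is small)
  cliques <- list()
  for (size in k:1) {
    for (sub in utils::combn(k, size, simplify = FALSE)) {
      if (all(adj[sub, sub])) {
        contained <- any(vapply(cliques, function(cq)
          all(sub %in% cq), logical(1)))
        if (!contained) cliques[[length(cliques) + 1L]] <- sub
      }
    }
  }
  ord <- order(vapply(cliques, min, numeric(1)))
  cliques <- cliques[ord]
  letters_out <- setNames(rep("", k), levels_ord)
  for (ci in seq_along(cliques))
    letters_out[cliques[[ci]]] <-
      paste0(letters_out[cliques[[ci]]], letters[ci])
  letters_out
}

#' Pairwise Wilcoxon rank-sum tests per cluster with BH correction
#'
#' Rank-sum tests for every treatment pair within every cluster, BH
#' correction across the whole pairs x clusters family, and a compact
#' letter display per cluster (groups sharing a letter do not differ at
#' `alpha`).
#'
#' @param rel samples x clusters abundance matrix.
#' @param groups factor of treatment labels.
#' @param alpha significance level for the letters (default 0.05).
#' @return list with `tests` (cluster, group1, group2, statistic, p,
#'   p_adj) and `letters` (clusters x groups character matrix).
#' @export
pairwise_wilcoxon_bh <- function(rel, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  lev <- levels(groups)
  prs <- utils::combn(lev, 2)
  rows <- list()
  for (cl in colnames(rel)) {
    for (pi in seq_len(ncol(prs))) {
      g1 <- prs[1, pi]; g2 <- prs[2, pi]
      x <- rel[groups == g1, cl]; y <- rel[groups == g2, cl]
      if (var(c(x, y)) == 0) {
        w <- NA_real_; p <- 1
      } else {
        wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
        w <- unname(wt$statistic); p <- wt$p.value
      }
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, group1 = g1, group2 = g2,
                   statistic = w, p = p)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_adj <- p.adjust(tests$p, "BH")
  letters_mat <- t(vapply(colnames(rel), function(cl) {
    sub <- tests[tests$cluster == cl, ]
    sig <- sub[sub$p_adj < alpha, c("group1", "group2"), drop = FALSE]
    means <- vapply(lev, function(g) mean(rel[groups == g, cl]),
                    numeric(1))
    lo <- lev[order(-means)]
    lt <- letter_display(lo, as.matrix(sig))
    lt[lev]
  }, character(length(lev))))
  colnames(letters_mat) <- lev
  list(tests = tests, letters = letters_mat)
}

#' One-way ANOVA with Tukey HSD per diversity index
#'
#' @param div diversity table from [diversity_table()].
#' @param groups factor of treatment labels (aligned with rows).
#' @param alpha significance level for the letter display.
#' @return list with `anova` (index, F, p), `tukey` (index, pair,
#'   difference, p_adj) and `letters` (index x group matrix).
#' @export
anova_tukey <- function(div, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  idx <- setdiff(names(div), "sample")
  lev <- levels(groups)
  an <- list(); tk <- list(); lt <- list()
  for (v in idx) {
    y <- div[[v]]
    ok <- !is.na(y)
    g <- droplevels(groups[ok])
    if (nlevels(g) < 2 || any(table(g) < 2))
      stop("need >= 2 groups with >= 2 observations for index ", v)
    if (var(y[ok]) == 0) {
      an[[v]] <- data.frame(index = v, F = 0, p = 1)
      tk[[v]] <- data.frame(index = v,
                            pair = apply(utils::combn(lev, 2), 2, paste,
                                         collapse = "-"),
                            difference = 0, p_adj = 1)
      lt[[v]] <- setNames(rep("a", length(lev)), lev)
      next
    }
    fit <- aov(y[ok] ~ g)
    sm <- summary(fit)[[1]]
    an[[v]] <- data.frame(index = v, F = sm$`F value`[1],
                          p = sm$`Pr(>F)`[1])
    th <- TukeyHSD(fit)$g
    tk[[v]] <- data.frame(index = v, pair = rownames(th),
                          difference = th[, "diff"],
                          p_adj = th[, "p adj"])
    sig <- do.call(rbind, strsplit(rownames(th)[th[, "p adj"] < alpha],
                                   "-", fixed = TRUE))
    means <- vapply(levels(g), function(gr) mean(y[ok][g == gr]),
                    numeric(1))
    lo <- levels(g)[order(-means)]
    lt[[v]] <- letter_display(lo, if (is.null(sig))
      matrix(character(0), 0, 2) else sig)[levels(g)]
  }
  letters_mat <- do.call(rbind, lt)
  rownames(letters_mat) <- idx
  list(anova = do.call(rbind, an), tukey = do.call(rbind, tk),
       letters = letters_mat)
}
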