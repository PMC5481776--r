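test_that("normalize_cells rescales totals to the median and drops empty cells", {
  e <- expression_matrix(matrix(c(60, 40, 150, 50), 2, byrow = TRUE,
                               dimnames = list(c("c1", "c2"), c("g1", "g2"))))
  n <- normalize_cells(e)
  expect_equal(unname(rowSums(n)), c(150, 150))
  expect_equal(unname(n["c1", ]), c(90, 60))
  same <- expression_matrix(matrix(c(1, 2, 2, 1), 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(unclass(normalize_cells(same)), unclass(same))
  withzero <- expression_matrix(matrix(c(1, 0, 2, 0), 2,
                                       dimnames = list(c("a", "z"), c("x", "y"))))
  expect_warning(nz <- normalize_cells(withzero), "all-zero")
  expect_equal(rownames(nz), "a")
})

test_that("correlation features equal brute-force pairwise Pearson", {
  withr::local_seed(41)
  e <- expression_matrix(matrix(stats::rexp(10 * 12, 1 / 50), 10,
                                dimnames = list(sprintf("c%02d", 1:10),
                                                sprintf("g%02d", 1:12))))
  feats <- correlation_features(e)
  # brute force straight from the definition
  lx <- log2(unclass(e) + 1)
  brute <- function(x, y) {
    n <- length(x)
    sum((x - mean(x)) * (y - mean(y))) /
      (stats::sd(x) * stats::sd(y) * (n - 1))
  }
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(feats[i, j], brute(lx[i, ], lx[j, ]), tolerance = 1e-12)
  }
  expect_equal(unname(diag(feats)), rep(1, 10))
  # duplicated cell correlates perfectly with its twin
  e2 <- expression_matrix(rbind(unclass(e), dup = unclass(e)[1, ]))
  expect_equal(correlation_features(e2)["dup", 1], 1)
})

test_that("constant-profile cells get correlation 0 against all others", {
  x <- matrix(c(1, 2, 3,
                3, 1, 2,
                5, 5, 5), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "flat"), c("g1", "g2", "g3")))
  feats <- correlation_features(expression_matrix(x), log_transform = FALSE)
  expect_equal(unname(feats["flat", c("a", "b")]), c(0, 0))
  expect_equal(unname(feats["flat", "flat"]), 1)
})

test_that("k-means recovers two well-separated planted subpopulations", {
  sets <- split(sprintf("Gpcr%03d", 1:40), rep(1:2, each = 20))
  mk <- function(i, n) {
    po <- rep(0.1, 40)
    names(po) <- sprintf("Gpcr%03d", 1:40)
    po[sets[[i]]] <- 0.9
    list(n_cells = n, target = "smc", prob_override = po)
  }
  sim <- simulate_ct_matrix(sim_config(
    subpops = list(a = mk(1, 40L), b = mk(2, 40L)), n_gpcr = 40L, seed = 17))
  e <- lod_transform(sim$ct)
  feats <- correlation_features(normalize_cells(e))
  km <- kmeans_cluster(feats, cluster_params(k = 2, seed = 3))
  expect_gte(mclust::adjustedRandIndex(km$labels, sim$truth$subpop), 0.95)
  # determinism
  km2 <- kmeans_cluster(feats, cluster_params(k = 2, seed = 3))
  expect_identical(km$labels, km2$labels)
  # label invariance under cell permutation, up to renaming
  perm <- withr::with_seed(99, sample(nrow(feats)))
  km3 <- kmeans_cluster(feats[perm, ], cluster_params(k = 2, seed = 3))
  expect_equal(mclust::adjustedRandIndex(km3$labels, km$labels[perm]), 1)
})

test_that("identical cells yield a degenerate single cluster with a warning", {
  feats <- matrix(0.5, 6, 6, dimnames = list(paste0("c", 1:6), paste0("c", 1:6)))
  expect_warning(km <- kmeans_cluster(feats, cluster_params(k = "auto", seed = 1)),
                 "degenerate")
  expect_true(all(km$labels == km$labels[1]))
})

test_that("the binomial marker p-value equals exact tail enumeration", {
  # small instance: N_c = 10, pi = 0.2, n_gc = 6
  enum_two_sided <- function(x, n, p) {
    lower <- sum(stats::dbinom(0:x, n, p))
    upper <- sum(stats::dbinom(x:n, n, p))
    min(1, 2 * min(lower, upper))
  }
  p_impl <- scgpcr:::binom_two_sided(6L, 10L, 0.2)
  expect_equal(p_impl, enum_two_sided(6L, 10L, 0.2), tolerance = 1e-12)
  # a symmetric case lands at exactly 1
  expect_equal(scgpcr:::binom_two_sided(5L, 10L, 0.5), 1)
})

test_that("planted 4-fold markers are flagged; cluster means conserve the total", {
  pl <- planted_subpop_config(seed = 11)
  sim <- simulate_ct_matrix(pl$cfg)
  e <- lod_transform(sim$ct)
  labels <- as.integer(factor(sim$truth$subpop))   # true labels
  mt <- cluster_marker_genes(e, labels, cluster_params(k = 3))
  for (i in 1:3) {
    rows <- mt[mt$cluster == i & mt$gene %in% pl$marker_sets[[i]], ]
    expect_gte(mean(rows$significant & rows$fold_change > 1.5), 0.9)
  }
  # conservation: size-weighted cluster means equal the global mean
  sizes <- table(labels)
  for (g in unique(mt$gene)[1:10]) {
    rows <- mt[mt$gene == g, ]
    wavg <- sum(rows$cluster_mean * as.numeric(sizes[rows$cluster])) / sum(sizes)
    expect_equal(wavg, rows$all_mean[1], tolerance = 1e-9)
  }
  # hence fold changes cannot all exceed 1 for one gene
  fc_by_gene <- tapply(mt$fold_change, mt$gene, function(f) all(f > 1))
  expect_false(any(fc_by_gene, na.rm = TRUE))
})

test_that("t-SNE is deterministic, runs at minimal size, and separates groups", {
  withr::local_seed(19)
  # two tight groups in feature space
  feats <- rbind(matrix(stats::rnorm(20 * 5, 0, 0.1), 20),
                 matrix(stats::rnorm(20 * 5, 4, 0.1), 20))
  rownames(feats) <- sprintf("c%02d", 1:40)
  p <- cluster_params(tsne_seed = 8)
  emb <- tsne_embed(feats, p)
  expect_identical(tsne_embed(feats, p), emb)
  # silhouette of the true grouping in the embedded plane is positive
  grp <- rep(1:2, each = 20)
  d <- as.matrix(stats::dist(emb[, c("x", "y")]))
  sil <- vapply(1:40, function(i) {
    a <- sum(d[i, grp == grp[i]]) / (sum(grp == grp[i]) - 1)  # excl. self (d=0)
    b <- mean(d[i, grp != grp[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
  # minimal case: 4 cells, perplexity 1
  tiny <- matrix(stats::rnorm(4 * 3), 4, dimnames = list(paste0("c", 1:4), NULL))
  expect_silent(tsne_embed(tiny, cluster_params(tsne_perplexity = 1,
                                                tsne_seed = 1)))
  expect_error(tsne_embed(tiny, cluster_params(tsne_perplexity = 10)),
               class = "scgpcr_input_error")
})
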