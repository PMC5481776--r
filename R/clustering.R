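#' Clustering parameters
#'
#' @param k number of clusters, or `"auto"` to choose k in `2..k_max` by the
#'   largest gap in the Calinski-Harabasz index.
#' @param k_max upper bound for automatic k selection.
#' @param n_restarts number of random k-means restarts; the best solution by
#'   total within-cluster sum of squares is kept.
#' @param seed RNG seed making the clustering deterministic.
#' @param alpha significance level for the binomial cluster-marker test.
#' @param fc_up,fc_down fold-change thresholds: a significant marker must
#'   additionally have fold change `> fc_up` or `< fc_down`.
#' @param tsne_perplexity t-SNE perplexity; `NULL` picks
#'   `min(30, (n_cells - 1) / 3)`.
#' @param tsne_seed seed for the t-SNE embedding.
#' @return a `ClusterParams` list.
#' @export
cluster_params <- function(k = "auto", k_max = 10L, n_restarts = 50L,
                           seed = 1L, alpha = 0.05, fc_up = 1.5,
                           fc_down = 0.7, tsne_perplexity = NULL,
                           tsne_seed = 1L) {
  if (!identical(k, "auto")) {
    if (!is.numeric(k) || k < 2) stop_input("`k` must be >= 2 or \"auto\"")
    k <- as.integer(k)
  }
  if (!(fc_down < 1 && 1 < fc_up)) stop_input("need fc_down < 1 < fc_up")
  if (!(alpha > 0 && alpha < 1)) stop_input("`alpha` must be in (0, 1)")
  structure(list(k = k, k_max = as.integer(k_max),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 alpha = alpha, fc_up = fc_up, fc_down = fc_down,
                 tsne_perplexity = tsne_perplexity,
                 tsne_seed = as.integer(tsne_seed)),
            class = "ClusterParams")
}

#' Rescale cells to a common total signal
#'
#' Each cell's expression vector is rescaled so its total equals the median
#' of the per-cell totals; zeros stay zero. Cells with all-zero profiles are
#' dropped with a warning.
#'
#' @param e an `ExpressionMatrix`.
#' @return a normalized `ExpressionMatrix`.
#' @export
normalize_cells <- function(e) {
  tot <- rowSums(e)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero cell(s): %s", sum(zero),
                    paste(utils::head(rownames(e)[zero], 5L), collapse = ", ")))
    e <- e[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  if (!nrow(e)) stop_input("no cells with signal")
  target <- stats::median(tot)
  out <- unclass(e) * (target / tot)
  expression_matrix(out, lod_ct = attr(e, "lod_ct") %||% 24)
}

#' Cell-cell correlation feature matrix
#'
#' Builds the feature space the clustering operates in: the Pearson (or
#' Spearman) correlation matrix of per-cell `log2(value + 1)` profiles. Cell
#' i's feature vector is row i of the matrix, so k-means on Euclidean
#' distances between rows clusters cells by the similarity of their
#' correlation pattern. Cells with constant profiles get correlation 0
#' against all others.
#'
#' @param e an `ExpressionMatrix` with >= 3 cells.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param log_transform apply `log2(value + 1)` before correlating.
#' @return an n_cells x n_cells correlation matrix with unit diagonal.
#' @export
correlation_features <- function(e, method = c("pearson", "spearman"),
                                 log_transform = TRUE) {
  method <- match.arg(method)
  if (nrow(e) < 3L) stop_input("need >= 3 cells")
  x <- unclass(e)
  if (log_transform) x <- log2(x + 1)
  profiles <- t(x)                      # genes x cells; cor() works on columns
  const <- apply(profiles, 2L, stats::sd) == 0
  cc <- suppressWarnings(stats::cor(profiles, method = method))
  if (any(const)) {
    cc[const, ] <- 0
    cc[, const] <- 0
  }
  diag(cc) <- 1
  cc
}

calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2L) return(NA_real_)
  overall <- colMeans(x)
  bss <- 0; wss <- 0
  for (c in unique(labels)) {
    xc <- x[labels == c, , drop = FALSE]
    mu <- colMeans(xc)
    bss <- bss + nrow(xc) * sum((mu - overall)^2)
    wss <- wss + sum(sweep(xc, 2L, mu)^2)
  }
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}

#' K-means clustering of cells on correlation features
#'
#' Runs k-means (Euclidean distance, multiple random restarts, best solution
#' by within-cluster sum of squares) on the rows of the correlation feature
#' matrix. With `k = "auto"` the index of Calinski-Harabasz is computed for
#' k in `2..k_max` and the k preceding the largest drop in the index is
#' chosen (largest-gap rule); ties fall to the smaller k. Deterministic for a
#' fixed `p$seed`. Labels are renumbered by order of first appearance so the
#' labelling does not depend on the restart that won.
#'
#' @param features numeric matrix, one row per cell (see
#'   [correlation_features()]).
#' @param p a [cluster_params()].
#' @return list with `labels` (named integer vector 1..k), `k`, `tot_withinss`
#'   and, for automatic selection, `criterion` (the per-k index values).
#' @export
kmeans_cluster <- function(features, p = cluster_params()) {
  n <- nrow(features)
  auto <- identical(p$k, "auto")
  ks <- if (auto) 2:min(p$k_max, n - 1L) else p$k
  if (!auto && p$k > n) stop_input("k exceeds the number of cells")
  fits <- withr::with_seed(p$seed, {
    lapply(ks, function(k) {
      tryCatch(suppressWarnings(
        stats::kmeans(features, centers = k, nstart = p$n_restarts,
                      iter.max = 100L)),
        error = function(e) NULL)   # fewer distinct points than centers
    })
  })
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) {
    warning("degenerate split: no k-means partition possible; single cluster")
    labels <- stats::setNames(rep(1L, n), rownames(features))
    return(list(labels = labels, k = 1L, tot_withinss = 0))
  }
  fits <- fits[ok]; ks <- ks[ok]
  if (auto) {
    crit <- vapply(seq_along(ks), function(i) {
      calinski_harabasz(features, fits[[i]]$cluster)
    }, numeric(1L))
    if (any(!is.finite(crit))) {
      warning("degenerate split: criterion not finite; using smallest k tested")
      pick <- 1L
    } else if (length(ks) == 1L) {
      pick <- 1L
    } else {
      drops <- crit[-length(crit)] - crit[-1L]   # gap after each k
      pick <- which.max(drops)
    }
    fit <- fits[[pick]]
    k_used <- ks[pick]
  } else {
    fit <- fits[[1L]]
    k_used <- ks[1L]
    crit <- NULL
  }
  labels <- fit$cluster
  # canonical numbering: clusters in order of first appearance
  relabel <- match(labels, unique(labels))
  names(relabel) <- rownames(features)
  out <- list(labels = relabel, k = k_used, tot_withinss = fit$tot.withinss)
  if (auto) out$criterion <- stats::setNames(crit, ks)
  out
}

# exact two-sided binomial tail probability: min(1, 2 * min(lower, upper))
binom_two_sided <- function(x, size, prob) {
  lower <- stats::pbinom(x, size, prob)
  upper <- stats::pbinom(x - 1L, size, prob, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Cluster-specific genes by binomial testing
#'
#' Tests, for every (cluster, gene) pair, whether the gene's summed
#' expression in the cluster deviates from its expectation under homogeneity.
#' Expression values are treated as transcript-count proxies and rounded to
#' pseudo-counts; the cluster's count for a gene is compared against a
#' binomial null with the cluster's total count as the number of trials and
#' the gene's global count share as success probability. The two-sided exact
#' p-value is `min(1, 2 * min(lower tail, upper tail))`. A gene is flagged
#' significant in a cluster when `p < alpha` *and* its fold change (cluster
#' mean over all-cells mean) exceeds `fc_up` or falls below `fc_down`.
#' Genes undetected globally are excluded.
#'
#' @param e an `ExpressionMatrix` (cells matching `labels`).
#' @param labels integer cluster labels, one per cell.
#' @param p a [cluster_params()].
#' @return data frame with columns `cluster`, `gene`, `cluster_mean`,
#'   `all_mean`, `fold_change`, `p_value`, `significant`.
#' @export
cluster_marker_genes <- function(e, labels, p = cluster_params()) {
  if (length(labels) != nrow(e)) stop_input("labels must match cells")
  x <- unclass(e)
  counts <- round(x)
  global_gene <- colSums(counts)
  keep <- global_gene > 0
  total <- sum(global_gene)
  pi_g <- global_gene / total
  all_mean <- colMeans(x)
  res <- lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    xc <- x[in_cl, , drop = FALSE]
    n_gc <- colSums(counts[in_cl, , drop = FALSE])
    N_c <- sum(n_gc)
    pv <- binom_two_sided(n_gc, N_c, pi_g)
    cm <- colMeans(xc)
    fc <- ifelse(all_mean > 0, cm / all_mean, NA_real_)
    data.frame(cluster = cl, gene = colnames(x), cluster_mean = cm,
               all_mean = all_mean, fold_change = fc, p_value = pv,
               row.names = NULL, stringsAsFactors = FALSE)[keep, ]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$significant <- out$p_value < p$alpha &
    (out$fold_change > p$fc_up | out$fold_change < p$fc_down)
  out
}

#' t-SNE embedding of the correlation features
#'
#' Two-dimensional t-SNE map of cells; deterministic for a fixed
#' `p$tsne_seed`. Perplexity defaults to `min(30, (n - 1) / 3)`.
#'
#' @param features numeric matrix, one row per cell.
#' @param p a [cluster_params()].
#' @return data frame with columns `cell`, `x`, `y`.
#' @export
tsne_embed <- function(features, p = cluster_params()) {
  n <- nrow(features)
  if (n < 4L) stop_input("need >= 4 cells for t-SNE")
  perp <- p$tsne_perplexity %||% min(30, (n - 1) / 3)
  if (perp >= n) stop_input("perplexity must be < number of cells")
  emb <- withr::with_seed(p$tsne_seed, {
    Rtsne::Rtsne(features, dims = 2L, perplexity = perp,
                 check_duplicates = FALSE, pca = FALSE,
                 max_iter = 500L, verbose = FALSE)
  })
  data.frame(cell = rownames(features) %||% as.character(seq_len(n)),
             x = emb$Y[, 1L], y = emb$Y[, 2L], stringsAsFactors = FALSE)
}
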