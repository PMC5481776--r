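#' Spearman's rank correlation coefficient
#'
#' Computed from first principles as the Pearson correlation of
#' average-ranked values; ties receive average ranks, which reduces to the
#' classic `1 - 6 * sum(d^2) / (n * (n^2 - 1))` formula when no ties are
#' present.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`, or `NA` when either vector is constant (rank
#'   correlation undefined).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("need >= 3 paired observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  rxc <- rx - mean(rx); ryc <- ry - mean(ry)
  sum(rxc * ryc) / sqrt(sum(rxc^2) * sum(ryc^2))
}

#' Build a gene-gene Spearman co-expression network
#'
#' Computes all pairwise Spearman correlations between the selected genes
#' over the retained cells and keeps edges above the display threshold. The
#' default mode keeps only positive correlations `rho > threshold`;
#' `mode = "absolute"` keeps `|rho| > threshold`, admitting anti-correlated
#' pairs. Undetected values enter the ranking as 0 (tied ranks); with
#' `detected_only = TRUE` each pair is correlated over the cells in which
#' both genes are detected (pairs with < 3 such cells are skipped).
#'
#' @param e an `ExpressionMatrix` with >= 3 cells.
#' @param genes genes to include (default: all).
#' @param threshold display threshold on rho (default 0.3).
#' @param mode `"positive_only"` (default) or `"absolute"`.
#' @param detected_only restrict each pair to doubly-detected cells.
#' @return a `CorrelationNetwork` list: `nodes`, `edges` (data frame
#'   `source`, `target`, `rho`, endpoints ordered `source < target` and rows
#'   sorted lexicographically), `threshold`, `mode`.
#' @export
build_network <- function(e, genes = colnames(e), threshold = 0.3,
                          mode = c("positive_only", "absolute"),
                          detected_only = FALSE) {
  mode <- match.arg(mode)
  if (nrow(e) < 3L) stop_input("need >= 3 cells")
  missing <- setdiff(genes, colnames(e))
  if (length(missing)) stop_input("genes not in matrix: ",
                                  paste(utils::head(missing, 5L), collapse = ", "))
  x <- unclass(e)[, genes, drop = FALSE]
  gpairs <- utils::combn(sort(genes), 2L)
  rho <- vapply(seq_len(ncol(gpairs)), function(i) {
    a <- x[, gpairs[1L, i]]; b <- x[, gpairs[2L, i]]
    if (detected_only) {
      keep <- a > 0 & b > 0
      if (sum(keep) < 3L) return(NA_real_)
      a <- a[keep]; b <- b[keep]
    }
    spearman_rho(a, b)
  }, numeric(1L))
  keep <- !is.na(rho) & if (mode == "positive_only") rho > threshold else abs(rho) > threshold
  edges <- data.frame(source = gpairs[1L, keep], target = gpairs[2L, keep],
                      rho = rho[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(genes), edges = edges, threshold = threshold,
                 mode = mode), class = "CorrelationNetwork")
}

#' @export
print.CorrelationNetwork <- function(x, ...) {
  cat(sprintf("CorrelationNetwork: %d nodes, %d edges (|rho| > %g, %s)\n",
              length(x$nodes), nrow(x$edges), x$threshold, x$mode))
  invisible(x)
}

#' Write a correlation network as a TSV edge list
#'
#' Tab-separated columns `source`, `target`, `rho`; deterministic
#' lexicographic row order. This is the exchange format for downstream graph
#' tools.
#'
#' @param network a `CorrelationNetwork`.
#' @param path output file path.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "CorrelationNetwork"))
  edges <- network$edges
  edges$rho <- sprintf("%.17g", edges$rho)
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV edge list back into a bare network
#'
#' @param path edge-list file written by [write_edge_list()].
#' @param threshold,mode metadata to attach (not re-derivable from the file).
#' @return a `CorrelationNetwork` whose nodes are the union of endpoints.
#' @export
read_edge_list <- function(path, threshold = 0.3, mode = "positive_only") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"),
                          check.names = FALSE)
  if (!all(c("source", "target", "rho") %in% names(df))) {
    stop_format("edge list needs columns source, target, rho")
  }
  df <- df[order(df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(nodes = sort(unique(c(df$source, df$target))), edges = df,
                 threshold = threshold, mode = mode),
            class = "CorrelationNetwork")
}
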