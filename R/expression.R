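#' Decide whether a Ct entry counts as detected
#'
#' A reaction is detected when it amplified (not `NA`) strictly below the
#' limit-of-detection cycle. Entries at or beyond the LoD carry no more
#' information than a failed reaction and are treated as undetected, which
#' keeps the detection rule consistent with the expression transform
#' (detected values are `> 1` on the expression scale).
#'
#' @param entry numeric vector of Ct values; `NA` = no amplification.
#' @param lod_ct limit-of-detection Ct in cycles (default 24).
#' @return logical vector.
#' @export
detect <- function(entry, lod_ct = 24) {
  assert_scalar_number(lod_ct, "lod_ct", positive = TRUE)
  !is.na(entry) & is.finite(entry) & entry < lod_ct
}

#' Transform Ct values to the LoD-anchored expression scale
#'
#' Detected entries map to `2^(lod_ct - Ct)`, so a transcript detected right
#' at the limit of detection would score 1 and each cycle earlier doubles the
#' value. Undetected entries (no amplification, or `Ct >= lod_ct`) are set to
#' 0. The transform is exactly invertible on detected entries:
#' `Ct = lod_ct - log2(value)`.
#'
#' @param m a `CtMatrix`.
#' @param lod_ct limit-of-detection Ct in cycles (default 24).
#' @return an `ExpressionMatrix`: a numeric cells x genes matrix of class
#'   `ExpressionMatrix` with attribute `lod_ct`; 0 means undetected.
#' @export
lod_transform <- function(m, lod_ct = 24) {
  stopifnot(inherits(m, "CtMatrix"))
  assert_scalar_number(lod_ct, "lod_ct", positive = TRUE)
  ct <- m$ct
  if (any(ct < 0, na.rm = TRUE)) stop_input("negative Ct values")
  vals <- ifelse(detect(ct, lod_ct), 2^(lod_ct - ct), 0)
  vals <- matrix(vals, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  expression_matrix(vals, lod_ct = lod_ct)
}

#' Construct an ExpressionMatrix
#'
#' @param values numeric cells x genes matrix, 0 = undetected, with dimnames.
#' @param lod_ct the limit-of-detection Ct the values are anchored to.
#' @return the matrix with class `ExpressionMatrix` and attribute `lod_ct`.
#' @export
expression_matrix <- function(values, lod_ct = 24) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_input("`values` must be a numeric matrix")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop_input("expression values must be finite and >= 0")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_input("expression matrix needs cell and gene names")
  }
  structure(values, class = c("ExpressionMatrix", "matrix", "array"),
            lod_ct = lod_ct)
}

#' Per-gene expression frequency
#'
#' Fraction of cells in which each gene is detected (value > 0), the
#' statistic shown as horizontal frequency bars alongside single-cell
#' expression heat maps.
#'
#' @param e an `ExpressionMatrix`.
#' @param genes genes to tabulate (default: all).
#' @return data frame with columns `gene`, `n_detected`, `n_cells`,
#'   `frequency`.
#' @export
expression_frequency <- function(e, genes = colnames(e)) {
  missing <- setdiff(genes, colnames(e))
  if (length(missing)) stop_input("genes not in matrix: ",
                                  paste(utils::head(missing, 5L), collapse = ", "))
  if (nrow(e) < 1L) stop_input("no cells in expression matrix")
  sub <- unclass(e)[, genes, drop = FALSE]
  nd <- colSums(sub > 0)
  data.frame(gene = genes, n_detected = as.integer(nd), n_cells = nrow(sub),
             frequency = nd / nrow(sub), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Number of GPCRs detected per cell
#'
#' Counts, for every cell, how many analyzable (intron-spanning) GPCRs from
#' the panel are detected. The summary reports mean +/- s.e.m. across cells.
#'
#' @param e an `ExpressionMatrix` of retained cells.
#' @param panel a `GenePanel`; only intron-spanning `gpcr` genes are counted.
#' @return integer vector, one count per cell, with a `summary` attribute
#'   (list: mean, sem, n_cells, n_gpcrs_tested).
#' @export
receptors_per_cell <- function(e, panel) {
  gp <- panel$gene[panel$category == "gpcr" & panel$intron_spanning]
  gp <- intersect(gp, colnames(e))
  counts <- if (length(gp)) {
    as.integer(rowSums(unclass(e)[, gp, drop = FALSE] > 0))
  } else rep(0L, nrow(e))
  names(counts) <- rownames(e)
  n <- length(counts)
  sem <- if (n > 1L) stats::sd(counts) / sqrt(n) else NA_real_
  attr(counts, "summary") <- list(mean = mean(counts), sem = sem,
                                  n_cells = n, n_gpcrs_tested = length(gp))
  counts
}

#' Compare expression between groups by t-test
#'
#' Two modes mirroring common qPCR reporting: `two_sample` compares two
#' groups of per-cell values with Student's two-sample t-test (equal
#' variances; Welch via `welch = TRUE`); `one_sample_vs_1` tests whether the
#' mean of values normalized to a control (control set to 1) differs from 1.
#' Both are two-sided.
#'
#' @param a numeric vector of per-cell values.
#' @param b second group (ignored for the one-sample mode).
#' @param mode `"two_sample"` or `"one_sample_vs_1"`.
#' @param welch use Welch's unequal-variance t-test in two-sample mode.
#' @return list with `statistic` (t), `p_value`, `df`, `estimate`.
#' @export
group_compare <- function(a, b = NULL,
                          mode = c("two_sample", "one_sample_vs_1"),
                          welch = FALSE) {
  mode <- match.arg(mode)
  a <- a[is.finite(a)]
  if (mode == "two_sample") {
    b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) stop_input("need >= 2 values per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate: no variance anywhere; equal means carry no evidence
      if (mean(a) == mean(b)) {
        return(list(statistic = 0, p_value = 1,
                    df = length(a) + length(b) - 2L,
                    estimate = mean(a) - mean(b)))
      }
      return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                  df = length(a) + length(b) - 2L,
                  estimate = mean(a) - mean(b)))
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), estimate = mean(a) - mean(b))
  } else {
    if (length(a) < 2L) stop_input("need >= 2 values")
    if (stats::sd(a) == 0) {
      if (mean(a) == 1) {
        return(list(statistic = 0, p_value = 1, df = length(a) - 1L,
                    estimate = mean(a)))
      }
      return(list(statistic = sign(mean(a) - 1) * Inf, p_value = 0,
                  df = length(a) - 1L, estimate = mean(a)))
    }
    tt <- stats::t.test(a, mu = 1)
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), estimate = mean(a))
  }
}
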