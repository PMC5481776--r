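#' Log-odds score matrix of a PWM
#'
#' Converts base counts to log2 odds against a background distribution:
#' entry (b, j) is `log2(((counts[b, j] + pseudocount) / (column total + 4 *
#' pseudocount)) / background[b])`.
#'
#' @param p a [pwm()].
#' @param background named base frequencies (A, C, G, T), strictly positive,
#'   summing to 1.
#' @return 4 x L numeric matrix of log2-odds scores.
#' @export
pwm_log_odds <- function(p, background = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25)) {
  stopifnot(inherits(p, "PWM"))
  background <- background[c("A", "C", "G", "T")]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop_input("background must be positive A/C/G/T frequencies summing to 1")
  }
  cts <- p$counts
  freq <- sweep(cts + p$pseudocount, 2L, colSums(cts) + 4 * p$pseudocount, "/")
  log2(freq / background)
}

#' Base composition of a promoter set
#'
#' @param seqs named character vector of sequences (A/C/G/T/N).
#' @return named frequencies of A, C, G, T among non-N bases.
#' @export
base_frequencies <- function(seqs) {
  tab <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1L]],
                      levels = c("A", "C", "G", "T")))
  if (sum(tab) == 0) stop_input("sequences contain no A/C/G/T bases")
  stats::setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "T"))
}

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)
COMP_CODE <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G

encode_seq <- function(seq) {
  unname(BASE_CODE[strsplit(seq, "")[[1L]]])  # N (or anything else) -> NA
}

#' Reverse-complement a sequence string
#' @param seq A/C/G/T/N string.
#' @return the reverse complement.
#' @export
reverse_complement <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1L]]), collapse = ""))
}

# raw window scores of an encoded sequence against a 4 x L score matrix;
# windows containing NA codes (N bases) score NA
scan_scores <- function(code, S) {
  L <- ncol(S)
  n_win <- length(code) - L + 1L
  if (n_win < 1L) return(numeric(0L))
  sc <- numeric(n_win)
  for (j in seq_len(L)) {
    sc <- sc + S[cbind(code[j:(j + n_win - 1L)], j)]
  }
  sc
}

#' Best normalized PWM hit in a promoter
#'
#' Scans both strands at every offset with the PWM's log-odds matrix and
#' returns the best window score min-max normalized by the score range the
#' PWM can attain: `(s - s_min) / (s_max - s_min)`, where `s_min`/`s_max`
#' are the sums of per-position column minima/maxima. A promoter containing
#' the consensus scores 1; one consisting only of worst-case bases scores 0.
#' Windows containing N are skipped; if every window is skipped, or the
#' sequence is shorter than the motif, `NA` is returned.
#'
#' @param seq promoter sequence (A/C/G/T/N string).
#' @param p a [pwm()].
#' @param background base frequencies for the log-odds scoring.
#' @return normalized best-hit score in `[0, 1]`, or `NA`.
#' @export
best_hit_score <- function(seq, p, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25)) {
  S <- pwm_log_odds(p, background)
  s_min <- sum(apply(S, 2L, min))
  s_max <- sum(apply(S, 2L, max))
  code <- encode_seq(seq)
  rc_code <- COMP_CODE[rev(code)]
  best <- suppressWarnings(max(c(scan_scores(code, S), scan_scores(rc_code, S)),
                               na.rm = TRUE))
  if (!is.finite(best)) return(NA_real_)   # no scannable window
  if (s_max == s_min) return(1)            # degenerate PWM: every window maximal
  (best - s_min) / (s_max - s_min)
}

#' Best-hit scores of many promoters against many PWMs
#'
#' @param seqs named character vector of promoter sequences.
#' @param pwms list of [pwm()] objects.
#' @param background base frequencies; `NULL` recomputes them from `seqs`.
#' @return genes x TFs numeric matrix of normalized best-hit scores.
#' @export
best_hit_scores <- function(seqs, pwms, background = NULL) {
  if (is.null(background)) background <- base_frequencies(seqs)
  out <- vapply(pwms, function(p) {
    vapply(seqs, best_hit_score, numeric(1L), p = p, background = background)
  }, numeric(length(seqs)))
  out <- matrix(out, nrow = length(seqs),
                dimnames = list(names(seqs),
                                vapply(pwms, function(p) p$tf_name,
                                       character(1L))))
  out
}

#' Gene-set enrichment of one TF's binding-site scores
#'
#' Compares the mean best-hit score of a gene set against the global promoter
#' background by a z-test: `z = (mean_set - mean_global) / (sd_global /
#' sqrt(n_set))`, with a two-sided normal p-value. Positive z means the
#' motif is overrepresented in the set's promoters.
#'
#' @param set_genes genes in the set (must be scored).
#' @param scores named numeric vector of best-hit scores over *all* genes
#'   (the global background, which includes the set).
#' @param tf TF name for the output row.
#' @return one-row data frame: `tf`, `n_set`, `mean_set`, `mean_global`,
#'   `sd_global`, `z`, `p_value`, `direction`.
#' @export
set_enrichment <- function(set_genes, scores, tf = "TF") {
  scores <- scores[!is.na(scores)]
  missing <- setdiff(set_genes, names(scores))
  if (length(missing)) stop_input("unscored genes in set: ",
                                  paste(utils::head(missing, 5L), collapse = ", "))
  if (length(set_genes) < 3L) stop_input("gene set must have >= 3 genes")
  mu <- mean(scores)
  sdg <- stats::sd(scores)
  ms <- mean(scores[set_genes])
  if (sdg == 0) {
    z <- 0; pv <- 1
  } else {
    z <- (ms - mu) / (sdg / sqrt(length(set_genes)))
    pv <- 2 * stats::pnorm(-abs(z))
    pv <- max(pv, .Machine$double.xmin)   # keep p in (0, 1]
  }
  data.frame(tf = tf, n_set = length(set_genes), mean_set = ms,
             mean_global = mu, sd_global = sdg, z = z, p_value = pv,
             direction = if (z > 0) "over" else "under",
             stringsAsFactors = FALSE)
}

#' Enrichment of every PWM in every gene set
#'
#' Scores all promoters against all PWMs (the global set is the scoring
#' background) and tests each gene set against the global distribution.
#'
#' @param seqs named character vector of all promoter sequences.
#' @param pwms list of [pwm()] objects.
#' @param gene_sets named list of gene-id vectors.
#' @param background base frequencies; `NULL` recomputes from `seqs`.
#' @return an `EnrichmentTable` data frame with one row per (TF, set):
#'   columns of [set_enrichment()] plus `gene_set` and `z_signed` (the
#'   signed z-transformed p-value used for heat-map display).
#' @export
tfbs_enrichment <- function(seqs, pwms, gene_sets, background = NULL) {
  scores <- best_hit_scores(seqs, pwms, background)
  rows <- lapply(names(gene_sets), function(gs) {
    do.call(rbind, lapply(colnames(scores), function(tf) {
      r <- set_enrichment(gene_sets[[gs]], scores[, tf], tf = tf)
      r$gene_set <- gs
      r
    }))
  })
  out <- do.call(rbind, rows)
  out$z_signed <- z_transform_p(out$p_value, out$direction)
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

# signed z-transform of a two-sided p-value
z_transform_p <- function(p, direction, clip = 8) {
  z <- stats::qnorm(1 - p / 2)
  z <- pmin(z, clip)
  ifelse(direction == "over", z, -z)
}

#' Signed z-transformed p-value matrix for heat-map export
#'
#' Each enrichment p-value is mapped to `sign * qnorm(1 - p/2)` (positive
#' for overrepresentation, negative for underrepresentation), clipped at
#' +/- 8, and arranged as a TF x gene-set matrix.
#'
#' @param rows an `EnrichmentTable` from [tfbs_enrichment()].
#' @return numeric matrix, TFs as rows, gene sets as columns.
#' @export
z_transform_table <- function(rows) {
  tfs <- unique(rows$tf); sets <- unique(rows$gene_set)
  out <- matrix(NA_real_, length(tfs), length(sets),
                dimnames = list(tfs, sets))
  out[cbind(match(rows$tf, tfs), match(rows$gene_set, sets))] <-
    z_transform_p(rows$p_value, rows$direction)
  out
}

#' Extract promoter windows from genome sequences
#'
#' Strand-aware helper for users supplying their own genome FASTA and TSS
#' table: the window covers `[TSS - upstream, TSS + downstream)` on the
#' gene's strand (half-open; `tss` is 1-based as in all file interfaces).
#' Windows truncated at a sequence edge are flagged in the `truncated`
#' attribute.
#'
#' @param genome named character vector of chromosome sequences.
#' @param tss_table data frame with columns `gene`, `chrom`, `tss` (1-based),
#'   `strand` (`"+"`/`"-"`).
#' @param upstream,downstream window extent in bp (defaults 950 and 50).
#' @return named character vector of promoter sequences.
#' @export
extract_promoters <- function(genome, tss_table, upstream = 950L,
                              downstream = 50L) {
  need <- c("gene", "chrom", "tss", "strand")
  if (!all(need %in% names(tss_table))) {
    stop_format("TSS table needs columns: ", paste(need, collapse = ", "))
  }
  truncated <- character(0L)
  out <- vapply(seq_len(nrow(tss_table)), function(i) {
    chrom <- genome[[tss_table$chrom[i]]]
    if (is.null(chrom) || is.na(chrom)) stop_input("unknown chromosome: ",
                                                   tss_table$chrom[i])
    tss <- tss_table$tss[i]
    if (tss_table$strand[i] == "+") {
      from <- tss - upstream; to <- tss + downstream - 1L
    } else {
      from <- tss - downstream + 1L; to <- tss + upstream
    }
    cf <- max(from, 1L); ct <- min(to, nchar(chrom))
    if (cf > from || ct < to) truncated <<- c(truncated, tss_table$gene[i])
    s <- substr(chrom, cf, ct)
    if (tss_table$strand[i] == "-") s <- reverse_complement(s)
    s
  }, character(1L))
  names(out) <- tss_table$gene
  attr(out, "truncated") <- truncated
  out
}
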