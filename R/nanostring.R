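#' Construct a NanoString lane set
#'
#' Holds raw barcode counts for a multiplexed count assay: endogenous probes,
#' positive control spikes (>= 1 probe) and exactly eight negative control
#' probes, for each lane.
#'
#' @param endogenous probes x lanes numeric matrix of endogenous counts,
#'   with probe row names and lane column names.
#' @param positive positive-control probes x lanes matrix.
#' @param negative negative-control probes x lanes matrix (8 probes expected;
#'   deviations warn, or error with `strict = TRUE` downstream).
#' @return a `NanoStringLaneSet` list.
#' @export
nanostring_lanes <- function(endogenous, positive, negative) {
  for (nm in c("endogenous", "positive", "negative")) {
    m <- get(nm)
    if (!is.matrix(m) || !is.numeric(m)) stop_input("`", nm, "` must be a numeric matrix")
    if (any(!is.finite(m)) || any(m < 0)) stop_input("`", nm, "` must be finite and >= 0")
  }
  if (ncol(endogenous) != ncol(positive) || ncol(endogenous) != ncol(negative)) {
    stop_input("all count matrices must cover the same lanes")
  }
  if (nrow(positive) < 1L) stop_input("need at least one positive-control probe")
  structure(list(endogenous = endogenous, positive = positive,
                 negative = negative), class = "NanoStringLaneSet")
}

#' Read a NanoString count table
#'
#' Plain CSV/TSV with a `probe` column, a `class` column (`endogenous`,
#' `positive`, `negative`) and one numeric column per lane.
#'
#' @param path file path.
#' @return a [nanostring_lanes()] object.
#' @export
read_nanostring_counts <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("probe", "class") %in% names(df))) {
    stop_format("count table needs columns probe, class")
  }
  cls <- tolower(df$class)
  bad <- setdiff(unique(cls), c("endogenous", "positive", "negative"))
  if (length(bad)) stop_format("unknown probe class: ", paste(bad, collapse = ", "))
  lanes <- setdiff(names(df), c("probe", "class"))
  mat <- as.matrix(df[, lanes, drop = FALSE])
  if (!is.numeric(mat)) stop_format("lane columns must be numeric")
  rownames(mat) <- df$probe
  nanostring_lanes(mat[cls == "endogenous", , drop = FALSE],
                   mat[cls == "positive", , drop = FALSE],
                   mat[cls == "negative", , drop = FALSE])
}

#' Positive-spike normalization
#'
#' Scales every lane so the geometric means of its positive-control spikes
#' agree across lanes: lane i's factor is the across-lane arithmetic mean of
#' the positive-control geometric means divided by lane i's own geometric
#' mean, and all of lane i's counts are multiplied by it.
#'
#' @param lanes a [nanostring_lanes()] object; every positive-control count
#'   must be > 0.
#' @return the lane set with all matrices scaled and a `factors` element
#'   (named per-lane scale factors).
#' @export
positive_spike_normalize <- function(lanes) {
  stopifnot(inherits(lanes, "NanoStringLaneSet"))
  if (any(lanes$positive <= 0)) stop_input("positive-control counts must be > 0")
  gm <- apply(lanes$positive, 2L, geomean)
  factors <- mean(gm) / gm
  out <- lanes
  for (nm in c("endogenous", "positive", "negative")) {
    out[[nm]] <- sweep(lanes[[nm]], 2L, factors, "*")
  }
  out$factors <- factors
  out
}

#' Negative-control background correction
#'
#' Per lane, the background is the mean plus two sample standard deviations
#' of the eight negative-control counts; it is subtracted from every
#' endogenous count, flooring at 0.
#'
#' @param lanes a (typically spike-normalized) lane set.
#' @param strict error (rather than warn) when the number of negative probes
#'   is not 8.
#' @return the lane set with corrected `endogenous` counts and a
#'   `background` element (named per-lane levels).
#' @export
background_correct <- function(lanes, strict = FALSE) {
  stopifnot(inherits(lanes, "NanoStringLaneSet"))
  n_neg <- nrow(lanes$negative)
  if (n_neg != 8L) {
    msg <- sprintf("expected 8 negative-control probes, found %d", n_neg)
    if (strict) stop_input(msg) else warning(msg)
  }
  bg <- apply(lanes$negative, 2L, function(x) mean(x) + 2 * stats::sd(x))
  out <- lanes
  out$endogenous <- pmax(sweep(lanes$endogenous, 2L, bg, "-"), 0)
  out$background <- bg
  out
}

#' Floor low counts
#'
#' Background-corrected values below the floor are fixed to the floor (the
#' platform's nominal background level) and flagged: they are treated as not
#' expressed downstream.
#'
#' @param lanes a background-corrected lane set.
#' @param floor threshold and replacement value (default 20). With
#'   `mode = "lane_background"` flagged values are set to the lane's computed
#'   background level instead of the constant.
#' @param mode `"constant"` (default) or `"lane_background"`.
#' @return the lane set with floored `endogenous` counts and a logical
#'   `below_floor` matrix flagging replaced entries.
#' @export
floor_low_values <- function(lanes, floor = 20, mode = c("constant",
                                                         "lane_background")) {
  stopifnot(inherits(lanes, "NanoStringLaneSet"))
  mode <- match.arg(mode)
  assert_scalar_number(floor, "floor", positive = TRUE)
  low <- lanes$endogenous < floor
  out <- lanes
  if (mode == "constant") {
    out$endogenous[low] <- floor
  } else {
    if (is.null(lanes$background)) stop_input("lane_background mode needs background_correct() first")
    repl <- matrix(lanes$background, nrow(low), ncol(low), byrow = TRUE)
    out$endogenous[low] <- repl[low]
  }
  out$below_floor <- low
  out
}

#' Full NanoString normalization chain
#'
#' Fixed order: positive-spike normalization, negative-control background
#' subtraction, low-value flooring.
#'
#' @param lanes a [nanostring_lanes()] object.
#' @param floor floor threshold (default 20).
#' @param strict passed to [background_correct()].
#' @return a normalized lane set with `factors`, `background` and
#'   `below_floor` diagnostics.
#' @export
normalize_nanostring <- function(lanes, floor = 20, strict = FALSE) {
  floor_low_values(background_correct(positive_spike_normalize(lanes),
                                      strict = strict), floor = floor)
}

#' geNorm reference-gene stability
#'
#' For every pair of candidate reference genes (j, k), the pairwise variation
#' `V_jk` is the standard deviation over samples of `log2(count_j / count_k)`.
#' A gene's stability measure `M_j` is the mean of its pairwise variations;
#' lower M means more stable expression. Genes exactly proportional across
#' samples have pairwise variation 0.
#'
#' @param ref_counts genes x samples numeric matrix of strictly positive
#'   counts (>= 3 genes, >= 2 samples).
#' @return named numeric vector of M values, sorted ascending (most stable
#'   first), with the full pairwise-variation matrix as attribute `V`.
#' @export
genorm_stability <- function(ref_counts) {
  if (!is.matrix(ref_counts) || nrow(ref_counts) < 3L || ncol(ref_counts) < 2L) {
    stop_input("need a matrix of >= 3 genes x >= 2 samples")
  }
  if (any(ref_counts <= 0)) stop_input("counts must be > 0 for log ratios")
  lg <- log2(ref_counts)
  n <- nrow(lg)
  V <- matrix(0, n, n, dimnames = list(rownames(lg), rownames(lg)))
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      v <- stats::sd(lg[j, ] - lg[k, ])
      V[j, k] <- v; V[k, j] <- v
    }
  }
  M <- rowSums(V) / (n - 1L)
  M <- sort(M)
  attr(M, "V") <- V
  M
}
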