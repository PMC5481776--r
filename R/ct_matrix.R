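#' Construct a Ct matrix
#'
#' A `CtMatrix` holds raw qPCR cycle-threshold (Ct) values for a set of single
#' cells (rows) over a gene panel (columns). Reactions that never crossed the
#' amplification threshold ("no amplification") are stored as `NA`; every
#' other entry is a finite Ct value in cycles, `>= 0`. Lower Ct means more
#' template.
#'
#' @param ct numeric matrix, cells x genes, with row and column names; `NA`
#'   encodes the no-amplification state.
#' @param metadata named list of free-form annotations (tissue, treatment,
#'   mouse id, per-cell group assignments, ...).
#' @return an object of class `CtMatrix`.
#' @export
ct_matrix <- function(ct, metadata = list()) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop_input("`ct` must be a numeric matrix")
  if (is.null(rownames(ct)) || is.null(colnames(ct))) {
    stop_input("`ct` must have cell row names and gene column names")
  }
  obj <- structure(list(ct = ct, metadata = as.list(metadata)), class = "CtMatrix")
  validate_ct_matrix(obj)
}

validate_ct_matrix <- function(x) {
  ct <- x$ct
  if (anyDuplicated(rownames(ct))) stop_format("duplicate cell ids: ",
    paste(unique(rownames(ct)[duplicated(rownames(ct))]), collapse = ", "))
  if (anyDuplicated(colnames(ct))) stop_format("duplicate gene ids: ",
    paste(unique(colnames(ct)[duplicated(colnames(ct))]), collapse = ", "))
  vals <- ct[!is.na(ct)]
  if (any(!is.finite(vals))) stop_format("non-finite Ct values present")
  if (any(vals < 0)) stop_format("negative Ct values present")
  x
}

#' @export
print.CtMatrix <- function(x, ...) {
  cat(sprintf("CtMatrix: %d cells x %d genes, %d no-amplification entries\n",
              nrow(x$ct), ncol(x$ct), sum(is.na(x$ct))))
  invisible(x)
}

#' @export
dim.CtMatrix <- function(x) dim(x$ct)

#' @rdname ct_matrix
#' @param x a `CtMatrix`.
#' @export
cell_ids <- function(x) UseMethod("cell_ids")

#' @export
cell_ids.CtMatrix <- function(x) rownames(x$ct)

#' @rdname ct_matrix
#' @export
gene_ids <- function(x) UseMethod("gene_ids")

#' @export
gene_ids.CtMatrix <- function(x) colnames(x$ct)

#' @export
gene_ids.default <- function(x) colnames(x)

#' Subset a CtMatrix by cells and/or genes
#'
#' @param x a `CtMatrix`.
#' @param cells,genes character or logical/integer index vectors; `NULL` keeps all.
#' @return a `CtMatrix` restricted to the selection; per-cell metadata entries
#'   (vectors with one element per cell) are subset in step.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "CtMatrix"))
  n0 <- nrow(x$ct)
  ct <- x$ct
  if (!is.null(cells)) ct <- ct[cells, , drop = FALSE]
  if (!is.null(genes)) ct <- ct[, genes, drop = FALSE]
  md <- x$metadata
  if (!is.null(cells)) {
    keep <- rownames(ct)
    md <- lapply(md, function(v) {
      if (length(v) == n0 && !is.null(names(v))) v[keep]
      else if (length(v) == n0) v[match(keep, rownames(x$ct))]
      else v
    })
  }
  ct_matrix(ct, md)
}

#' Read a Ct matrix from a delimited text table
#'
#' Expects the wide export convention of microfluidic qPCR runs: a header row
#' of gene names, one row per cell, first column the cell id. A long format
#' with columns `cell`, `gene`, `ct` is read with `long = TRUE`. Entries are
#' plain or scientific-notation numbers; any token in `no_amp_tokens`
#' (compared after trimming whitespace) maps to the no-amplification state.
#'
#' @param path file path (CSV or TSV; delimiter auto-detected from the header).
#' @param no_amp_tokens character vector of tokens that encode failed
#'   amplification. The default covers common export dialects.
#' @param long logical; read the long three-column layout instead.
#' @return a validated [ct_matrix()].
#' @export
read_ct_matrix <- function(path,
                           no_amp_tokens = c("", "NA", "999", "Undetermined"),
                           long = FALSE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                          check.names = FALSE, comment.char = "", quote = "\"",
                          na.strings = NULL)
  if (long) {
    need <- c("cell", "gene", "ct")
    if (!all(need %in% names(df))) stop_format("long format needs columns cell, gene, ct")
    cells <- unique(df$cell); genes <- unique(df$gene)
    if (anyDuplicated(paste(df$cell, df$gene, sep = "\r"))) {
      stop_format("duplicate (cell, gene) pairs in long table")
    }
    ct <- matrix(NA_real_, length(cells), length(genes),
                 dimnames = list(cells, genes))
    val <- trimws(df$ct)
    isna <- val %in% no_amp_tokens
    val[isna] <- NA
    num <- rep(NA_real_, length(val))
    num[!isna] <- parse_numeric(val[!isna])
    ct[cbind(match(df$cell, cells), match(df$gene, genes))] <- num
    return(ct_matrix(ct))
  }
  if (ncol(df) < 2L) stop_format("Ct table needs a cell-id column plus gene columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop_format("duplicate cell ids: ",
    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  raw[] <- trimws(raw)
  isna <- matrix(raw %in% no_amp_tokens, nrow(raw), ncol(raw))
  num <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = list(ids, colnames(raw)))
  if (any(!isna)) num[!isna] <- parse_numeric(raw[!isna])
  ct_matrix(num)
}

#' Write a Ct matrix as a delimited text table
#'
#' Inverse of [read_ct_matrix()]: wide layout, first column `cell`, one column
#' per gene, no-amplification entries written as `no_amp_token`.
#'
#' @param x a `CtMatrix`.
#' @param path output file path.
#' @param no_amp_token token used for no-amplification entries.
#' @param sep field separator.
#' @export
write_ct_matrix <- function(x, path, no_amp_token = "NA", sep = ",") {
  stopifnot(inherits(x, "CtMatrix"))
  # %.17g round-trips IEEE doubles exactly, so write/read is identity
  out <- matrix(sprintf("%.17g", x$ct), nrow(x$ct), ncol(x$ct),
                dimnames = dimnames(x$ct))
  out[is.na(x$ct)] <- no_amp_token
  df <- data.frame(cell = rownames(x$ct), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
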