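PANEL_CATEGORIES <- c("gpcr", "identity", "function", "reference")
PANEL_ROLES <- c("target_ec", "target_smc", "lineage_exclusion",
                 "quality_control", "none")

#' Construct a gene-panel annotation table
#'
#' Describes each assayed gene: its `category` (`gpcr`, `identity`,
#' `function`, `reference`), its `marker_role` in cell gating (`target_ec`,
#' `target_smc`, `lineage_exclusion`, `quality_control`, `none`) and whether
#' the primer pair is intron-spanning. Non-intron-spanning GPCR assays
#' amplify genomic DNA and are excluded from receptor counting by
#' [filter_intron_spanning()].
#'
#' @param gene character vector of unique gene ids.
#' @param category per-gene category, one of `r paste(PANEL_CATEGORIES, collapse=", ")`.
#' @param marker_role per-gene gating role, one of `r paste(PANEL_ROLES, collapse=", ")`.
#' @param intron_spanning logical per gene.
#' @return a `GenePanel` data frame.
#' @export
gene_panel <- function(gene, category, marker_role, intron_spanning) {
  df <- data.frame(gene = as.character(gene),
                   category = as.character(category),
                   marker_role = as.character(marker_role),
                   intron_spanning = as.logical(intron_spanning),
                   stringsAsFactors = FALSE)
  validate_gene_panel(df)
  class(df) <- c("GenePanel", "data.frame")
  df
}

validate_gene_panel <- function(df) {
  if (anyDuplicated(df$gene)) stop_format("duplicate gene ids in panel")
  bad <- setdiff(unique(df$category), PANEL_CATEGORIES)
  if (length(bad)) stop_format("unknown category: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$marker_role), PANEL_ROLES)
  if (length(bad)) stop_format("unknown marker_role: ", paste(bad, collapse = ", "))
  if (any(is.na(df$intron_spanning))) stop_format("intron_spanning must be true/false")
  if (any(df$gene == "")) stop_format("empty gene id")
  ref_bad <- df$category == "reference" & df$marker_role != "quality_control"
  if (any(ref_bad)) {
    stop_format("reference genes must have marker_role quality_control: ",
                paste(df$gene[ref_bad], collapse = ", "))
  }
  invisible(df)
}

#' Check a panel against a Ct matrix
#'
#' Asserts the panel covers every gene in the matrix, carries at least one
#' target marker and at least one quality-control gene.
#'
#' @param panel a `GenePanel`.
#' @param m a `CtMatrix`.
#' @export
check_panel_covers <- function(panel, m) {
  missing <- setdiff(gene_ids(m), panel$gene)
  if (length(missing)) {
    stop_config("panel is missing genes present in the Ct matrix: ",
                paste(utils::head(missing, 5L), collapse = ", "))
  }
  if (!any(panel$marker_role %in% c("target_ec", "target_smc"))) {
    stop_config("panel has no target marker gene")
  }
  if (!any(panel$marker_role == "quality_control")) {
    stop_config("panel has no quality-control gene")
  }
  invisible(TRUE)
}

#' Read a gene panel from CSV
#'
#' Requires columns `gene`, `category`, `marker_role`, `intron_spanning`
#' (true/false, case-insensitive).
#'
#' @param path file path.
#' @return a `GenePanel`.
#' @export
read_gene_panel <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "\"", na.strings = NULL)
  need <- c("gene", "category", "marker_role", "intron_spanning")
  if (!all(need %in% names(df))) {
    stop_format("gene panel needs columns: ", paste(need, collapse = ", "))
  }
  isp <- tolower(trimws(df$intron_spanning))
  if (!all(isp %in% c("true", "false", "1", "0"))) {
    stop_format("intron_spanning entries must be true/false")
  }
  gene_panel(trimws(df$gene), tolower(trimws(df$category)),
             tolower(trimws(df$marker_role)), isp %in% c("true", "1"))
}

#' Write a gene panel to CSV
#' @param panel a `GenePanel`.
#' @param path output file path.
#' @export
write_gene_panel <- function(panel, path) {
  out <- as.data.frame(panel)
  out$intron_spanning <- ifelse(out$intron_spanning, "true", "false")
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a panel's GPCR set to intron-spanning assays
#'
#' Single-exon GPCRs do not allow intron-spanning primer design; their assays
#' detect contaminating genomic DNA in every cell and are removed from the
#' analyzable GPCR set.
#'
#' @param panel a `GenePanel`.
#' @return the panel with non-intron-spanning GPCR rows dropped; the number
#'   removed is attached as attribute `n_removed` and a warning is raised if
#'   no analyzable GPCR remains.
#' @export
filter_intron_spanning <- function(panel) {
  drop <- panel$category == "gpcr" & !panel$intron_spanning
  out <- panel[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("GenePanel", "data.frame")
  attr(out, "n_removed") <- sum(drop)
  if (!any(out$category == "gpcr")) {
    warning("no intron-spanning GPCR assays remain in the panel")
  }
  out
}
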