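#' Gating configuration for cell-identity classification
#'
#' Encodes the marker-panel inclusion rules used to purge contaminating cells
#' from sorted endothelial (EC) or smooth muscle (SMC) preparations: cells
#' must be negative for a set of lineage-exclusion markers (leukocyte,
#' epithelial, skeletal-muscle lineages), positive for the quality-control
#' reference genes, and positive for exactly one of the cell-type target
#' markers (Cdh5 for EC, Myh11 for SMC).
#'
#' @param lineage_exclusion_genes genes whose detection marks a contaminating
#'   lineage.
#' @param target_markers named character vector mapping `target_ec` and
#'   `target_smc` to their marker gene.
#' @param qc_genes reference genes that must all be detected.
#' @param lod_ct limit-of-detection Ct used by the detection rule.
#' @param allow_low_cross_marker optional exception admitting cells that
#'   co-express the *other* target marker at low level, as seen in aortic EC
#'   that carry trace Myh11: a named list `list(marker = "Myh11",
#'   max_expression = 16)` meaning the cross marker may be detected as long as
#'   its LoD-scale expression is at or below `max_expression` (16 = within 4
#'   cycles of the LoD).
#' @return a `GatingConfig` list.
#' @export
gating_config <- function(lineage_exclusion_genes = c("Ptprc", "Itgam", "Cd4",
                                                      "Cd8", "Cd19", "Ly6g",
                                                      "Cdh1", "Tnni2"),
                          target_markers = c(target_ec = "Cdh5",
                                             target_smc = "Myh11"),
                          qc_genes = c("Gapdh", "Hprt"),
                          lod_ct = 24,
                          allow_low_cross_marker = NULL) {
  if (length(intersect(target_markers, lineage_exclusion_genes))) {
    stop_config("target markers must be disjoint from lineage-exclusion genes")
  }
  if (!length(qc_genes)) stop_config("qc_genes must be nonempty")
  if (!all(c("target_ec", "target_smc") %in% names(target_markers))) {
    stop_config("target_markers needs entries target_ec and target_smc")
  }
  if (!is.null(allow_low_cross_marker)) {
    if (!all(c("marker", "max_expression") %in% names(allow_low_cross_marker))) {
      stop_config("allow_low_cross_marker needs fields marker, max_expression")
    }
  }
  structure(list(lineage_exclusion_genes = lineage_exclusion_genes,
                 target_markers = target_markers,
                 qc_genes = qc_genes,
                 lod_ct = lod_ct,
                 allow_low_cross_marker = allow_low_cross_marker),
            class = "GatingConfig")
}

GATING_LABELS <- c("qc_fail", "cdh5_only", "myh11_only", "other_markers",
                   "no_marker")

# expression on the LoD scale for a single Ct entry (NA = no amplification)
ct_to_expression <- function(ct, lod_ct) {
  ifelse(!is.na(ct) & ct < lod_ct, 2^(lod_ct - ct), 0)
}

#' Classify one cell from its Ct row
#'
#' Applies the marker rules in fixed order: any undetected quality-control
#' gene fails QC; any detected lineage-exclusion marker makes the cell
#' `other_markers`; then the cell is labelled by which target markers are
#' detected. Cells positive for both target markers are *not* retained
#' (labelled `other_markers`) unless the configured low-cross-marker
#' exception applies, in which case the cross marker is ignored.
#'
#' @param cell_row named numeric vector of Ct values (`NA` = no
#'   amplification) covering every gene the config mentions.
#' @param cfg a [gating_config()].
#' @return one of `"qc_fail"`, `"cdh5_only"`, `"myh11_only"`,
#'   `"other_markers"`, `"no_marker"`.
#' @export
classify_cell <- function(cell_row, cfg) {
  need <- unique(c(cfg$qc_genes, cfg$lineage_exclusion_genes, cfg$target_markers))
  missing <- setdiff(need, names(cell_row))
  if (length(missing)) {
    stop_config("cell row is missing genes required for gating: ",
                paste(missing, collapse = ", "))
  }
  det <- function(g) detect(cell_row[[g]], cfg$lod_ct)
  if (!all(vapply(cfg$qc_genes, det, logical(1L)))) return("qc_fail")
  if (any(vapply(cfg$lineage_exclusion_genes, det, logical(1L)))) {
    return("other_markers")
  }
  ec_gene <- cfg$target_markers[["target_ec"]]
  smc_gene <- cfg$target_markers[["target_smc"]]
  ec <- det(ec_gene)
  smc <- det(smc_gene)
  exc <- cfg$allow_low_cross_marker
  if (ec && smc && !is.null(exc)) {
    # the cross marker is tolerated when its expression stays at trace level
    cross_expr <- ct_to_expression(cell_row[[exc$marker]], cfg$lod_ct)
    if (cross_expr <= exc$max_expression) {
      if (exc$marker == smc_gene) smc <- FALSE else if (exc$marker == ec_gene) ec <- FALSE
    }
  }
  if (ec && smc) return("other_markers")
  if (ec) return("cdh5_only")
  if (smc) return("myh11_only")
  "no_marker"
}

#' Gate a Ct matrix into identity categories
#'
#' Classifies every cell, retains only the cells carrying the declared target
#' identity (plus any cells admitted by the low-cross-marker exception), and
#' tabulates contamination per sample group in the layout of a
#' contaminating-cells report: percentage of `cdh5_only`, `myh11_only`,
#' `other_markers` and `no_marker` cells among all QC-passing cells.
#'
#' @param m a `CtMatrix`.
#' @param panel a `GenePanel` covering `m`'s genes.
#' @param cfg a [gating_config()].
#' @param target `"ec"` or `"smc"`: which single-positive label is retained.
#' @param groups optional per-cell sample-group factor (defaults to
#'   `m$metadata$group`, else one group `"all"`).
#' @return a `GatingResult` list: `labels` (named character per cell),
#'   `retained` (a `CtMatrix` of retained cells), `contamination` (data frame
#'   of per-group percentages), `double_positive` (diagnostic count of cells
#'   excluded for carrying both target markers), `n_input`.
#' @export
gate_cells <- function(m, panel, cfg = gating_config(),
                       target = c("smc", "ec"), groups = NULL) {
  stopifnot(inherits(m, "CtMatrix"))
  target <- match.arg(target)
  check_panel_covers(panel, m)
  ct <- m$ct
  labels <- vapply(seq_len(nrow(ct)), function(i) {
    classify_cell(ct[i, ], cfg)
  }, character(1L))
  names(labels) <- rownames(ct)

  # diagnostic: double target-positives among QC-passing, lineage-negative cells
  ec_gene <- cfg$target_markers[["target_ec"]]
  smc_gene <- cfg$target_markers[["target_smc"]]
  lin_det <- rowSums(detect(ct[, cfg$lineage_exclusion_genes, drop = FALSE],
                            cfg$lod_ct)) > 0
  qc_ok <- rowSums(!detect(ct[, cfg$qc_genes, drop = FALSE], cfg$lod_ct)) == 0
  dp <- sum(qc_ok & !lin_det &
              detect(ct[, ec_gene], cfg$lod_ct) &
              detect(ct[, smc_gene], cfg$lod_ct) &
              labels == "other_markers")

  keep_label <- if (target == "smc") "myh11_only" else "cdh5_only"
  retained_ids <- names(labels)[labels == keep_label]
  if (!length(retained_ids)) {
    warning("no cells retained after gating")
    retained <- NULL
  } else {
    retained <- subset_cells(m, cells = retained_ids)
  }

  if (is.null(groups)) groups <- m$metadata$group
  if (is.null(groups)) groups <- rep("all", nrow(ct))
  if (!is.null(names(groups))) groups <- groups[rownames(ct)]
  groups <- as.character(groups)

  tab_labels <- setdiff(GATING_LABELS, "qc_fail")
  rows <- lapply(unique(groups), function(g) {
    lg <- labels[groups == g & labels != "qc_fail"]
    n <- length(lg)
    pct <- if (n) 100 * vapply(tab_labels, function(l) mean(lg == l),
                               numeric(1L)) else rep(NA_real_, length(tab_labels))
    cbind(data.frame(group = g, n_cells = n, stringsAsFactors = FALSE),
          as.data.frame(as.list(pct), col.names = tab_labels))
  })
  contamination <- do.call(rbind, rows)

  structure(list(labels = labels, retained = retained,
                 contamination = contamination, double_positive = dp,
                 n_input = nrow(ct), target = target),
            class = "GatingResult")
}

#' @export
print.GatingResult <- function(x, ...) {
  cat(sprintf("GatingResult: %d cells in, %d retained (%s), %d qc_fail\n",
              x$n_input,
              if (is.null(x$retained)) 0L else nrow(x$retained$ct),
              x$target, sum(x$labels == "qc_fail")))
  print(x$contamination)
  invisible(x)
}
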