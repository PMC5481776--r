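#' Default pipeline configuration
#'
#' One flat list of every tunable the pipeline stages accept; entries are
#' overridden by a user config (YAML file or list), which is in turn
#' overridden by direct arguments to [run_pipeline()].
#'
#' @return named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(
    ct = NULL,              # path to Ct matrix CSV (NULL: simulate)
    panel = NULL,           # path to gene panel CSV (NULL: simulated panel)
    target = "smc",         # retained identity: "smc" or "ec"
    lod_ct = 24,
    k = 3,                  # cluster count ("auto" for data-driven choice)
    n_restarts = 50,
    seed = 1,
    alpha = 0.05,
    fc_up = 1.5,
    fc_down = 0.7,
    network_threshold = 0.3,
    network_mode = "positive_only",
    promoters = NULL,       # path to promoter FASTA (optional stage)
    pwms = NULL,            # path to JASPAR PFM file
    gene_sets = NULL,       # named list of gene-id vectors, or dir of .txt files
    nanostring = NULL,      # path to NanoString count table (optional stage)
    nanostring_floor = 20,
    sim_n_gpcr = 132,
    sim_contamination = 0.12
  )
}

read_gene_set_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  sets <- lapply(files, function(f) trimws(readLines(f)))
  names(sets) <- sub("\\.txt$", "", basename(files))
  lapply(sets, function(s) s[s != ""])
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- simulate or load inputs, gate,
#' LoD-transform, cluster with marker testing and t-SNE, build the Spearman
#' network, and (when inputs are configured) promoter TFBS enrichment and
#' NanoString normalization -- writing each stage's outputs as plain text
#' files plus a run manifest recording the full configuration, input digests
#' and package version. Deterministic stages are bit-reproducible for a
#' fixed config and seed.
#'
#' @param config named list or path to a YAML file; keys as in
#'   [default_pipeline_config()]. Unknown keys are an error.
#' @param out_dir output directory (created if needed).
#' @param ... direct overrides taking precedence over the config.
#' @return invisibly, a list of in-memory stage results plus `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir, ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  overrides <- list(...)
  cfg <- default_pipeline_config()
  for (src in list(config, overrides)) {
    unknown <- setdiff(names(src), names(cfg))
    if (length(unknown)) stop_config("unknown config keys: ",
                                     paste(unknown, collapse = ", "))
    cfg[names(src)] <- src
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage, paste0(...)))
  digests <- list()

  # --- inputs -----------------------------------------------------------
  if (is.null(cfg$ct)) {
    msg("simulate", "no Ct matrix supplied; generating synthetic data")
    sim <- simulate_ct_matrix(sim_config(
      n_gpcr = cfg$sim_n_gpcr,
      contamination_fraction = cfg$sim_contamination,
      lod_ct = cfg$lod_ct, seed = cfg$seed))
    m <- sim$ct; panel <- sim$panel
    write_ct_matrix(m, file.path(out_dir, "simulated_ct.csv"))
    write_gene_panel(panel, file.path(out_dir, "simulated_panel.csv"))
  } else {
    if (!file.exists(cfg$ct)) stop_config("gating input not found: ct = ", cfg$ct)
    if (is.null(cfg$panel) || !file.exists(cfg$panel)) {
      stop_config("gating input not found: panel = ", cfg$panel %||% "<missing>")
    }
    digests$ct <- unname(tools::md5sum(cfg$ct))
    digests$panel <- unname(tools::md5sum(cfg$panel))
    m <- read_ct_matrix(cfg$ct)
    panel <- read_gene_panel(cfg$panel)
  }

  # --- gate -------------------------------------------------------------
  msg("gate", "classifying ", nrow(m$ct), " cells (target: ", cfg$target, ")")
  gcfg <- gating_config(lod_ct = cfg$lod_ct)
  gr <- gate_cells(m, panel, gcfg, target = cfg$target)
  utils::write.table(data.frame(cell = names(gr$labels), label = gr$labels),
                     file.path(out_dir, "gating_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(gr$contamination, file.path(out_dir, "contamination.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(gr$retained)) stop_config("gating retained no cells; nothing to analyse")
  write_ct_matrix(gr$retained, file.path(out_dir, "retained_ct.csv"))

  # --- express ----------------------------------------------------------
  msg("express", "LoD transform at Ct ", cfg$lod_ct)
  e <- lod_transform(gr$retained, lod_ct = cfg$lod_ct)
  panel_is <- filter_intron_spanning(panel)
  freq <- expression_frequency(e)
  rpc <- receptors_per_cell(e, panel_is)
  utils::write.table(freq, file.path(out_dir, "frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(cell = names(rpc), n_gpcr = as.integer(rpc)),
                     file.path(out_dir, "receptors_per_cell.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_expression_csv(e, file.path(out_dir, "expression.csv"))

  # --- cluster ----------------------------------------------------------
  cp <- cluster_params(k = cfg$k, n_restarts = cfg$n_restarts,
                       seed = cfg$seed, alpha = cfg$alpha,
                       fc_up = cfg$fc_up, fc_down = cfg$fc_down,
                       tsne_seed = cfg$seed)
  msg("cluster", "k-means on correlation features (k = ", format(cfg$k), ")")
  feats <- correlation_features(normalize_cells(e))
  km <- kmeans_cluster(feats, cp)
  markers <- cluster_marker_genes(e, km$labels, cp)
  emb <- tsne_embed(feats, cp)
  utils::write.table(data.frame(cell = names(km$labels), cluster = km$labels),
                     file.path(out_dir, "cluster_labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(markers, file.path(out_dir, "cluster_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(emb, file.path(out_dir, "tsne.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # --- network ----------------------------------------------------------
  msg("network", "Spearman network at threshold ", cfg$network_threshold)
  gpcrs <- intersect(panel_is$gene[panel_is$category == "gpcr"], colnames(e))
  net <- build_network(e, genes = gpcrs, threshold = cfg$network_threshold,
                       mode = cfg$network_mode)
  write_edge_list(net, file.path(out_dir, "network_edges.tsv"))

  # --- tfbs (optional) --------------------------------------------------
  enrich <- NULL
  if (!is.null(cfg$promoters) && !is.null(cfg$pwms) && !is.null(cfg$gene_sets)) {
    msg("tfbs", "promoter scan + set enrichment")
    digests$promoters <- unname(tools::md5sum(cfg$promoters))
    digests$pwms <- unname(tools::md5sum(cfg$pwms))
    seqs <- read_promoter_fasta(cfg$promoters)
    pwms <- read_jaspar_pfms(cfg$pwms)
    sets <- if (is.character(cfg$gene_sets)) read_gene_set_files(cfg$gene_sets)
            else cfg$gene_sets
    enrich <- tfbs_enrichment(seqs, pwms, sets)
    utils::write.table(as.data.frame(enrich),
                       file.path(out_dir, "tfbs_enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    zt <- z_transform_table(enrich)
    utils::write.table(data.frame(tf = rownames(zt), zt, check.names = FALSE),
                       file.path(out_dir, "tfbs_z_matrix.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # --- nanostring (optional) --------------------------------------------
  ns <- NULL
  if (!is.null(cfg$nanostring)) {
    msg("nanostring", "normalizing bulk counts")
    digests$nanostring <- unname(tools::md5sum(cfg$nanostring))
    ns <- normalize_nanostring(read_nanostring_counts(cfg$nanostring),
                               floor = cfg$nanostring_floor)
    utils::write.table(
      data.frame(probe = rownames(ns$endogenous), ns$endogenous,
                 check.names = FALSE),
      file.path(out_dir, "nanostring_normalized.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(lane = names(ns$factors), factor = ns$factors,
                 background = ns$background),
      file.path(out_dir, "nanostring_lanes.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
  }

  # --- manifest ---------------------------------------------------------
  manifest <- list(config = cfg[!vapply(cfg, is.null, logical(1L))],
                   input_digests = digests,
                   package_version = as.character(utils::packageVersion("scgpcr")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  msg("done", "outputs in ", out_dir)

  invisible(list(gating = gr, expression = e, frequency = freq,
                 receptors_per_cell = rpc, clustering = km, markers = markers,
                 embedding = emb, network = net, enrichment = enrich,
                 nanostring = ns, manifest = manifest))
}

#' Write an expression matrix as CSV
#' @param e an `ExpressionMatrix`.
#' @param path output file path.
#' @export
write_expression_csv <- function(e, path) {
  df <- data.frame(cell = rownames(e),
                   matrix(sprintf("%.17g", e), nrow(e), dimnames = dimnames(e)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from CSV
#' @param path file written by [write_expression_csv()].
#' @param lod_ct LoD annotation to attach.
#' @return an `ExpressionMatrix`.
#' @export
read_expression_csv <- function(path, lod_ct = 24) {
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  expression_matrix(m, lod_ct = lod_ct)
}
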