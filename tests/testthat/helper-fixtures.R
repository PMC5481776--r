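# shared fixture builders; everything is generated in code, no stored data

tiny_panel <- function(n_gpcr = 4L) {
  lineage <- c("Ptprc", "Itgam", "Cd4", "Cd8", "Cd19", "Ly6g", "Cdh1", "Tnni2")
  gpcrs <- sprintf("Gpcr%03d", seq_len(n_gpcr))
  gene_panel(
    gene = c("Actb", "Gapdh", "Hprt", "Cdh5", "Myh11", lineage, gpcrs),
    category = c(rep("reference", 3), rep("identity", 2 + length(lineage)),
                 rep("gpcr", n_gpcr)),
    marker_role = c(rep("quality_control", 3), "target_ec", "target_smc",
                    rep("lineage_exclusion", length(lineage)),
                    rep("none", n_gpcr)),
    intron_spanning = TRUE)
}

# a cell row with every gating gene undetected except the ones given
cell_row <- function(detected = character(0), ct = 18, panel = tiny_panel()) {
  row <- rep(NA_real_, nrow(panel))
  names(row) <- panel$gene
  row[detected] <- ct
  row
}

random_ct_matrix <- function(n_cells = 6L, n_genes = 5L, p_na = 0.3) {
  ct <- matrix(round(stats::runif(n_cells * n_genes, 5, 30), 3), n_cells,
               dimnames = list(sprintf("cell%02d", seq_len(n_cells)),
                               sprintf("G%02d", seq_len(n_genes))))
  ct[stats::runif(length(ct)) < p_na] <- NA
  ct_matrix(ct)
}

random_pwm <- function(L = 5L, name = "TF1", concentration = 1) {
  counts <- matrix(stats::rgamma(4L * L, shape = concentration) * 10, 4L, L)
  pwm(name, counts)
}

# a sharply informative PWM whose consensus is essentially deterministic
informative_pwm <- function(consensus = "TGACGTCA", name = "PLANTED") {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4L, length(bases),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- 997
  pwm(name, counts)
}

random_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# planted three-subpopulation study design: each subpopulation expresses its
# own 20-receptor module at frequency 0.8 vs 0.2 elsewhere (4-fold mean)
planted_subpop_config <- function(seed = 11L, n_cells = c(60L, 57L, 29L)) {
  sets <- split(sprintf("Gpcr%03d", 1:60), rep(1:3, each = 20))
  mk <- function(i, n) {
    po <- rep(0.2, 60)
    names(po) <- sprintf("Gpcr%03d", 1:60)
    po[sets[[i]]] <- 0.8
    list(n_cells = n, target = "smc", prob_override = po)
  }
  list(cfg = sim_config(subpops = list(a = mk(1, n_cells[1]),
                                       b = mk(2, n_cells[2]),
                                       c = mk(3, n_cells[3])), seed = seed),
       marker_sets = sets)
}

# homogeneous count-scale population for binomial-test calibration: Poisson
# counts, no structure; labels are assigned at random by the caller
homogeneous_counts <- function(n_cells = 200L, n_genes = 100L,
                               lambda_range = c(2, 20)) {
  lam <- stats::runif(n_genes, lambda_range[1], lambda_range[2])
  x <- matrix(stats::rpois(n_cells * n_genes, rep(lam, each = n_cells)),
              n_cells,
              dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                              sprintf("g%03d", seq_len(n_genes))))
  expression_matrix(x)
}
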