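#' Default per-gene detection probabilities
#'
#' A deterministic frequency spectrum mimicking observed single-cell GPCR
#' detection: most receptors rare, a handful near-ubiquitous. Probabilities
#' are Beta(0.35, 2) quantiles over a regular grid, rescaled so their sum
#' (the expected number of receptors detected per cell) hits
#' `mean_per_cell`.
#'
#' @param n_genes number of GPCR genes.
#' @param mean_per_cell expected receptors detected per cell (default 20.3,
#'   matching healthy aortic smooth muscle cells over a 132-receptor panel).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
default_detection_profile <- function(n_genes = 132L, mean_per_cell = 20.3) {
  p <- stats::qbeta((seq_len(n_genes) - 0.5) / n_genes, 0.35, 2)
  p <- p * (mean_per_cell / sum(p))
  pmin(p, 1)
}

#' Simulation configuration
#'
#' Describes a mixture of cell subpopulations assayed on a GPCR qPCR panel.
#' Detected reactions draw a Ct from a normal distribution truncated to
#' `(0, lod_ct)` (so a detected gene is always below the limit of
#' detection); undetected reactions are no-amplification entries. Reference
#' genes are detected in every cell at low Ct; the subpopulation's target
#' marker is detected in every non-contaminant cell; lineage markers appear
#' only in planted contaminant cells.
#'
#' @param subpops named list; each element a list with `n_cells`, `target`
#'   (`"smc"` or `"ec"`), optional `detect_prob` (per-GPCR probabilities;
#'   default [default_detection_profile()]), optional `mu` (per-GPCR mean
#'   detected Ct; default 18), optional `mu_shift` (named Ct shifts for
#'   selected genes: -2 cycles = 4-fold up) and optional `prob_override`
#'   (named detection-probability overrides).
#' @param n_gpcr number of GPCR genes on the panel.
#' @param sigma s.d. of detected Ct values in cycles.
#' @param lod_ct limit-of-detection Ct.
#' @param contamination_fraction fraction of each subpopulation's cells that
#'   are contaminants, in `[0, 1)`.
#' @param contaminant_split proportions of contaminants that are
#'   lineage-marker positive (`other`) vs target-marker negative (`none`);
#'   must sum to 1.
#' @param ref_mu,marker_mu mean detected Ct of reference genes and identity
#'   markers.
#' @param seed RNG seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(subpops = list(
                         smc1 = list(n_cells = 60L, target = "smc"),
                         smc2 = list(n_cells = 57L, target = "smc"),
                         smc3 = list(n_cells = 29L, target = "smc")),
                       n_gpcr = 132L, sigma = 1.5, lod_ct = 24,
                       contamination_fraction = 0,
                       contaminant_split = c(other = 0.8, none = 0.2),
                       ref_mu = 12, marker_mu = 15, seed = 1L) {
  if (!(contamination_fraction >= 0 && contamination_fraction < 1)) {
    stop_input("contamination_fraction must be in [0, 1)")
  }
  assert_scalar_number(sigma, "sigma", positive = TRUE)
  if (abs(sum(contaminant_split) - 1) > 1e-8) {
    stop_input("contaminant_split must sum to 1")
  }
  gpcr_genes <- sprintf("Gpcr%03d", seq_len(n_gpcr))
  for (nm in names(subpops)) {
    sp <- subpops[[nm]]
    if (is.null(sp[["detect_prob"]])) sp$detect_prob <- default_detection_profile(n_gpcr)
    if (length(sp$detect_prob) != n_gpcr) stop_input("detect_prob length mismatch in ", nm)
    if (any(sp$detect_prob < 0 | sp$detect_prob > 1)) stop_input("detect_prob outside [0, 1]")
    if (is.null(sp[["mu"]])) sp$mu <- rep(18, n_gpcr)
    names(sp$detect_prob) <- gpcr_genes
    names(sp$mu) <- gpcr_genes
    if (!is.null(sp$prob_override)) {
      sp$detect_prob[names(sp$prob_override)] <- sp$prob_override
    }
    if (!is.null(sp$mu_shift)) {
      sp$mu[names(sp$mu_shift)] <- sp$mu[names(sp$mu_shift)] + sp$mu_shift
    }
    subpops[[nm]] <- sp
  }
  structure(list(subpops = subpops, n_gpcr = n_gpcr, gpcr_genes = gpcr_genes,
                 sigma = sigma, lod_ct = lod_ct,
                 contamination_fraction = contamination_fraction,
                 contaminant_split = contaminant_split,
                 ref_mu = ref_mu, marker_mu = marker_mu,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Gene panel matching a simulation configuration
#'
#' Reference genes Actb/Gapdh/Hprt (quality control), target markers
#' Cdh5/Myh11, the eight lineage-exclusion markers, and the configured
#' number of intron-spanning GPCR genes.
#'
#' @param cfg a [sim_config()].
#' @return a `GenePanel`.
#' @export
sim_gene_panel <- function(cfg) {
  lineage <- c("Ptprc", "Itgam", "Cd4", "Cd8", "Cd19", "Ly6g", "Cdh1", "Tnni2")
  gene_panel(
    gene = c("Actb", "Gapdh", "Hprt", "Cdh5", "Myh11", lineage, cfg$gpcr_genes),
    category = c(rep("reference", 3L), rep("identity", 2L + length(lineage)),
                 rep("gpcr", cfg$n_gpcr)),
    marker_role = c(rep("quality_control", 3L), "target_ec", "target_smc",
                    rep("lineage_exclusion", length(lineage)),
                    rep("none", cfg$n_gpcr)),
    intron_spanning = TRUE)
}

# normal variate truncated to (lo, hi), via inverse-CDF sampling
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(q, lo + 1e-9), hi - 1e-9)
}

#' Simulate a single-cell Ct matrix with planted truth
#'
#' Draws, for every cell and gene, a Bernoulli detection event and, if
#' detected, a truncated-normal Ct below the limit of detection. Contaminant
#' cells additionally express a random lineage marker (`other` type) or lack
#' the target marker (`none` type). Bit-reproducible given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `ct` (a `CtMatrix`; `metadata$group` holds the
#'   subpopulation), `panel` (the matching `GenePanel`) and `truth` (per-cell
#'   subpopulation and contaminant status, per-subpop detection
#'   probabilities and mean Cts).
#' @export
simulate_ct_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  panel <- sim_gene_panel(cfg)
  genes <- panel$gene
  lineage <- panel$gene[panel$marker_role == "lineage_exclusion"]
  withr::with_seed(cfg$seed, {
    rows <- list(); cell_groups <- character(0L); contam <- character(0L)
    for (nm in names(cfg$subpops)) {
      sp <- cfg$subpops[[nm]]
      n <- sp$n_cells
      marker <- if (sp$target == "smc") "Myh11" else "Cdh5"
      ct <- matrix(NA_real_, n, length(genes),
                   dimnames = list(sprintf("%s_c%03d", nm, seq_len(n)), genes))
      # reference genes: always detected at low Ct
      for (g in c("Actb", "Gapdh", "Hprt")) {
        ct[, g] <- rnorm_trunc(n, cfg$ref_mu, cfg$sigma, 0, cfg$lod_ct)
      }
      # contaminant assignment
      is_cont <- stats::runif(n) < cfg$contamination_fraction
      cont_type <- ifelse(is_cont,
                          ifelse(stats::runif(n) < cfg$contaminant_split[["other"]],
                                 "other", "none"),
                          "target")
      # target marker: detected in genuine target cells only
      has_marker <- cont_type == "target"
      ct[has_marker, marker] <- rnorm_trunc(sum(has_marker), cfg$marker_mu,
                                            cfg$sigma, 0, cfg$lod_ct)
      # lineage contaminants: one random exclusion marker detected
      idx_other <- which(cont_type == "other")
      if (length(idx_other)) {
        pick <- sample(lineage, length(idx_other), replace = TRUE)
        ct[cbind(idx_other, match(pick, genes))] <-
          rnorm_trunc(length(idx_other), cfg$marker_mu, cfg$sigma, 0, cfg$lod_ct)
      }
      # GPCRs: Bernoulli dropout then truncated-normal Ct
      det <- matrix(stats::runif(n * cfg$n_gpcr), n) <
        matrix(sp$detect_prob, n, cfg$n_gpcr, byrow = TRUE)
      mus <- matrix(sp$mu, n, cfg$n_gpcr, byrow = TRUE)
      vals <- matrix(NA_real_, n, cfg$n_gpcr)
      vals[det] <- rnorm_trunc(sum(det), mus[det], cfg$sigma, 0, cfg$lod_ct)
      ct[, cfg$gpcr_genes] <- vals
      rows[[nm]] <- ct
      cell_groups <- c(cell_groups, rep(nm, n))
      contam <- c(contam, cont_type)
    }
    full <- do.call(rbind, rows)
    names(cell_groups) <- rownames(full)
    names(contam) <- rownames(full)
    truth <- list(
      subpop = cell_groups,
      contaminant = contam,
      detect_prob = lapply(cfg$subpops, function(sp) sp$detect_prob),
      mu = lapply(cfg$subpops, function(sp) sp$mu),
      contamination_fraction = cfg$contamination_fraction)
    list(ct = ct_matrix(full, metadata = list(group = cell_groups)),
         panel = panel, truth = truth)
  })
}

#' Simulate a pair of co-expressed genes
#'
#' Draws a latent bivariate normal with correlation `rho_target` and pushes
#' it through the detection/expression model: values above the per-gene
#' dropout quantile are detected and mapped onto the LoD expression scale by
#' a monotone transform; the rest are 0. The Spearman correlation of the
#' output tracks the latent correlation (attenuated by ties at 0 when
#' `detect_prob < 1`).
#'
#' @param n number of cells.
#' @param rho_target latent correlation, `|rho_target| < 1`.
#' @param seed RNG seed.
#' @param detect_prob detection probability applied to both genes.
#' @param mu,sigma,lod_ct Ct model parameters for detected values.
#' @return list of numeric vectors `x` and `y`.
#' @export
simulate_correlated_pair <- function(n, rho_target, seed = 1L,
                                     detect_prob = 1, mu = 18, sigma = 1.5,
                                     lod_ct = 24) {
  if (abs(rho_target) >= 1) stop_input("|rho_target| must be < 1")
  withr::with_seed(seed, {
    z1 <- stats::rnorm(n)
    z2 <- rho_target * z1 + sqrt(1 - rho_target^2) * stats::rnorm(n)
    to_expr <- function(z) {
      det <- z > stats::qnorm(1 - detect_prob)
      ct <- pmin(pmax(mu - sigma * z, 1e-9), lod_ct - 1e-9)
      ifelse(det, 2^(lod_ct - ct), 0)
    }
    list(x = to_expr(z1), y = to_expr(z2))
  })
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background sequences are i.i.d. draws from `base_freq`; each gene in
#' `planted_set` receives one motif instance sampled from the PWM's column
#' frequencies, inserted at a uniformly chosen offset on a uniformly chosen
#' strand.
#'
#' @param n_genes number of promoters (ids `g001`, `g002`, ...).
#' @param length promoter length in bp (default 1000, the -950..+50 window).
#' @param motif a [pwm()] whose instances are planted, or `NULL` for pure
#'   background.
#' @param planted_set gene ids receiving a motif instance.
#' @param seed RNG seed.
#' @param base_freq background base frequencies (A, C, G, T).
#' @return list with `seqs` (named character vector) and `truth` (data frame
#'   gene/position/strand for planted instances).
#' @export
simulate_promoters <- function(n_genes, length = 1000L, motif = NULL,
                               planted_set = character(0L), seed = 1L,
                               base_freq = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25)) {
  ids <- sprintf("g%03d", seq_len(n_genes))
  bad <- setdiff(planted_set, ids)
  if (length(bad)) stop_input("planted_set outside gene ids: ",
                              paste(utils::head(bad, 5L), collapse = ", "))
  if (!is.null(motif) && ncol(motif$counts) >= length) {
    stop_input("motif longer than the promoter")
  }
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(ids, function(id) {
      paste(sample(bases, length, replace = TRUE, prob = base_freq),
            collapse = "")
    }, character(1L))
    truth <- data.frame(gene = character(0L), position = integer(0L),
                        strand = character(0L), stringsAsFactors = FALSE)
    if (!is.null(motif)) {
      L <- ncol(motif$counts)
      colfreq <- sweep(motif$counts, 2L, colSums(motif$counts), "/")
      for (g in planted_set) {
        inst <- paste(vapply(seq_len(L), function(j) {
          sample(bases, 1L, prob = colfreq[, j])
        }, character(1L)), collapse = "")
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") inst <- reverse_complement(inst)
        pos <- sample.int(length - L + 1L, 1L)
        seqs[[g]] <- paste0(substr(seqs[[g]], 1L, pos - 1L), inst,
                            substr(seqs[[g]], pos + L, length))
        truth <- rbind(truth, data.frame(gene = g, position = pos,
                                         strand = strand,
                                         stringsAsFactors = FALSE))
      }
    }
    list(seqs = seqs, truth = truth)
  })
}

#' Simulate a NanoString lane set with planted scale factors
#'
#' A shared true endogenous profile is scaled per lane by the reciprocal of
#' the planted correction factor (a bright lane needs a small correction)
#' and read out with optional Poisson noise. Positive controls follow a
#' fixed geometric ladder scaled identically; negatives are Poisson around
#' `background_level`.
#'
#' @param n_lanes number of lanes.
#' @param factors planted per-lane correction factors (> 0); recovered
#'   factors match these up to a common scale.
#' @param background_level mean negative-control count.
#' @param seed RNG seed.
#' @param n_endogenous number of endogenous probes.
#' @param noise add Poisson counting noise (`FALSE` gives expectations, for
#'   exact-recovery checks).
#' @return list with `lanes` (a [nanostring_lanes()]) and `truth` (planted
#'   factors, true profile, ladder, background level).
#' @export
simulate_nanostring <- function(n_lanes = 3L, factors = c(1, 0.5, 2),
                                background_level = 10, seed = 1L,
                                n_endogenous = 50L, noise = TRUE) {
  if (length(factors) != n_lanes) stop_input("need one factor per lane")
  if (any(factors <= 0)) stop_input("factors must be > 0")
  ladder <- c(8192, 2048, 512, 128, 32, 8)   # positive spike ladder
  withr::with_seed(seed, {
    profile <- round(stats::rlnorm(n_endogenous, meanlog = 5, sdlog = 1.2)) + 30
    lane_names <- sprintf("lane%02d", seq_len(n_lanes))
    expected <- function(base) outer(base, 1 / factors)
    emit <- function(base) {
      m <- expected(base)
      if (noise) m[] <- stats::rpois(base::length(m), m)
      m
    }
    endo <- emit(profile)
    pos <- emit(ladder)
    neg <- if (noise) {
      matrix(stats::rpois(8L * n_lanes, background_level), 8L)
    } else matrix(background_level, 8L, n_lanes)
    dimnames(endo) <- list(sprintf("endo%03d", seq_len(n_endogenous)), lane_names)
    dimnames(pos) <- list(sprintf("pos%d", seq_along(ladder)), lane_names)
    dimnames(neg) <- list(sprintf("neg%d", 1:8), lane_names)
    list(lanes = nanostring_lanes(endo, pos, neg),
         truth = list(factors = factors, profile = profile, ladder = ladder,
                      background_level = background_level))
  })
}
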